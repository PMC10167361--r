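#' Aggregate spine flow score
#'
#' Sums the per-junction ordinal hyperostosis scores (0 none … 3 complete
#' fusion, Kuperus-style) across the scored intervertebral junctions of a
#' spine, giving the participant's aggregate DISH score (0–42 at the full
#' 14 junctions).  Permutation-invariant in junction order.
#'
#' @param scores integer vector (or matrix, participants in rows) of
#'   junction scores in `{0, 1, 2, 3}`; up to 14 junctions.
#' @return integer aggregate score(s).
#' @export
aggregate_flow_score <- function(scores) {
  if (is.matrix(scores) || is.data.frame(scores)) {
    scores <- as.matrix(scores)
    if (ncol(scores) < 1L) stop("no junction scores supplied")
    if (ncol(scores) > 14L) stop("at most 14 junctions are scored")
    if (any(!scores %in% 0:3)) stop("junction scores must be in {0, 1, 2, 3}")
    return(as.integer(rowSums(scores)))
  }
  if (length(scores) < 1L) stop("no junction scores supplied")
  if (length(scores) > 14L) stop("at most 14 junctions are scored")
  if (any(!scores %in% 0:3)) stop("junction scores must be in {0, 1, 2, 3}")
  as.integer(sum(scores))
}

# Ridge-penalized logistic IRLS: label ~ intercept + slope * score.
# The small penalty keeps the fit finite under complete separation.
.ridge_logit <- function(score, label, penalty = 1e-3, max_iter = 100) {
  x <- cbind(1, score)
  beta <- c(0, 0)
  pen <- diag(c(0, penalty))  # intercept unpenalized
  for (i in seq_len(max_iter)) {
    eta <- as.vector(x %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(x, label - mu) - pen %*% beta
    hess <- crossprod(x * w, x) + pen
    step <- solve(hess, grad)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < 1e-10) break
  }
  beta
}

#' Fit the score-to-diagnosis curve
#'
#' Logistic regression of expert DISH diagnoses on the aggregate flow
#' score, with a weak ridge penalty on the slope so the fit stays finite
#' under complete separation (small validation sets sampled per score bin
#' invite separation).  The probability of diagnosis must be
#' non-decreasing in the score; a negative fitted slope is a fatal error.
#'
#' @param score aggregate flow scores of the labeled validation images.
#' @param label expert diagnosis (0/1 or logical).
#' @param penalty ridge penalty on the slope (default 1e-3).
#' @return a `diagnosis_curve` list: `intercept`, `slope`, `range` (score
#'   range of the fit).  Use [predict_diagnosis()] to evaluate it.
#' @export
fit_diagnosis_curve <- function(score, label, penalty = 1e-3) {
  label <- as.numeric(label)
  if (length(unique(label)) < 2L) {
    stop("both diagnosis classes must be present to fit the curve")
  }
  if (length(unique(score)) < 2L) stop("at least 2 distinct scores required")
  beta <- .ridge_logit(score, label, penalty)
  if (beta[2] < 0) {
    stop("fitted diagnosis probability decreases with score; ",
         "labels are inconsistent with the severity scale")
  }
  structure(list(intercept = beta[1], slope = beta[2],
                 range = range(score)),
            class = "diagnosis_curve")
}

#' @rdname fit_diagnosis_curve
#' @param curve a `diagnosis_curve`.
#' @param score scores at which to evaluate P(diagnosis | score).
#' @export
predict_diagnosis <- function(curve, score) {
  stats::plogis(curve$intercept + curve$slope * score)
}

#' @export
print.diagnosis_curve <- function(x, ...) {
  cat("Diagnosis curve: logit P(DISH) =", signif(x$intercept, 4), "+",
      signif(x$slope, 4), "* score  (fitted on scores",
      x$range[1], "to", x$range[2], ")\n")
  invisible(x)
}

#' Bin-based stratified prevalence projection
#'
#' Estimates DISH prevalence per stratum (typically sex, or sex by age
#' band) from the cohort's aggregate-score distribution and the
#' score-to-diagnosis curve: within each stratum, prevalence is
#' `sum_bins f_bin * p_bin`, where `f_bin` is the stratum's frequency in
#' each score bin and `p_bin` the curve's diagnosis probability at the
#' bin midpoint.  Projected counts scale the prevalence by stated
#' population stratum sizes.  Uncertainty is a seeded nonparametric
#' bootstrap resampling both the cohort (bin frequencies) and the labeled
#' validation set (curve refit).
#'
#' @param score cohort aggregate flow scores.
#' @param stratum factor/character stratum label per cohort participant.
#' @param curve a fitted [fit_diagnosis_curve()] object.
#' @param population_sizes named numeric vector of population sizes per
#'   stratum (names matching `stratum` levels); `NA` entries skip the
#'   projection for that stratum.
#' @param bin_width score-bin width (default 4: bins 0-3, 4-7, ...).
#' @param labels optional data frame (`score`, `label`) of the validation
#'   data; when supplied the bootstrap refits the curve per replicate.
#' @param n_boot bootstrap replicates (default 200).
#' @param seed bootstrap seed.
#' @return data frame with one row per stratum: `stratum`, `n_cohort`,
#'   `prevalence`, `prevalence_se`, `population`, `projected_count`,
#'   `projected_count_se`.  Strata present in `population_sizes` but
#'   empty in the cohort are reported with `NA` prevalence.
#' @export
estimate_prevalence <- function(score, stratum, curve, population_sizes,
                                bin_width = 4, labels = NULL,
                                n_boot = 200, seed = 1) {
  stratum <- as.character(stratum)
  strata <- union(names(population_sizes), unique(stratum))
  breaks <- seq(0, max(score, 42) + bin_width, by = bin_width)
  mids <- utils::head(breaks, -1L) + (bin_width - 1) / 2

  prev_one <- function(sc, cv) {
    f <- tabulate(findInterval(sc, breaks, rightmost.closed = TRUE),
                  nbins = length(mids))
    sum(f / length(sc) * predict_diagnosis(cv, mids))
  }

  rows <- lapply(strata, function(s) {
    sc <- score[stratum == s]
    popn <- if (s %in% names(population_sizes)) population_sizes[[s]] else NA_real_
    if (length(sc) == 0L) {
      return(data.frame(stratum = s, n_cohort = 0L, prevalence = NA_real_,
                        prevalence_se = NA_real_, population = popn,
                        projected_count = NA_real_,
                        projected_count_se = NA_real_,
                        stringsAsFactors = FALSE))
    }
    prev <- prev_one(sc, curve)
    boot <- with_seed(substream_seed(seed, match(s, strata)), {
      vapply(seq_len(n_boot), function(b) {
        cv <- curve
        if (!is.null(labels)) {
          bi <- sample.int(nrow(labels), replace = TRUE)
          cv <- tryCatch(fit_diagnosis_curve(labels$score[bi],
                                             labels$label[bi]),
                         error = function(e) curve)
        }
        prev_one(sample(sc, replace = TRUE), cv)
      }, numeric(1))
    })
    se <- stats::sd(boot)
    data.frame(stratum = s, n_cohort = length(sc), prevalence = prev,
               prevalence_se = se, population = popn,
               projected_count = prev * popn,
               projected_count_se = se * popn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
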