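#' Colocalization configuration
#'
#' Default per-variant priors of the ABF colocalization model: `p1`/`p2`
#' for a variant being causal for trait 1/2 only, `p12` for being causal
#' for both.
#'
#' @param p1,p2 per-variant prior probability of causality for each trait
#'   (default 1e-4).
#' @param p12 per-variant prior probability of shared causality (default
#'   1e-5); must not exceed `min(p1, p2)`.
#' @param window locus half-width in bp used when extracting variants
#'   around an index variant (default 500 kb).
#' @return a validated `coloc_config` list.
#' @export
coloc_config <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, window = 5e5) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, p12 > 0, p12 < 1,
            p12 <= min(p1, p2))
  structure(list(p1 = p1, p2 = p2, p12 = p12, window = window),
            class = "coloc_config")
}

.logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

# log(exp(a) - exp(b)) for a >= b, guarded against cancellation
.logdiff <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' ABF colocalization of two traits at a locus
#'
#' Assumes at most one causal variant per trait and computes the posterior
#' probabilities of the five hypotheses — H0 no association, H1/H2 one
#' trait only, H3 two distinct causal variants, H4 one shared causal
#' variant — by summing per-variant approximate Bayes factors over all
#' single-causal configurations, weighted by the per-variant priors, all
#' in log space.  Each trait's effect-prior variance is derived from its
#' own summary statistics (`omega = (omega_scale * sigma)^2` with sigma
#' from [estimate_sigma()]) unless supplied.
#'
#' The two tables must already be harmonized to the same variants in the
#' same order (see [harmonize_alleles()]).
#'
#' @param t1,t2 row-aligned locus `sumstats` for the two traits.
#' @param cfg a [coloc_config()].
#' @param omega1,omega2 optional effect-prior variances; default from each
#'   trait's sigma estimate with scale `omega_scale`.
#' @param omega_scale prior scale used when deriving omegas (default 0.15).
#' @return a `coloc_result` list: `pp` (named PP0..PP4, summing to 1),
#'   `classification` (`"strong"`, `"suggestive"` or `"none"`),
#'   `direction` (`"correlated"`, `"anti-correlated"`, `"undetermined"`,
#'   or `NA` when unclassified), `top_shared` (variant id maximizing the
#'   per-variant H4 contribution), `n_variants`, `lbf1`, `lbf2`.
#' @export
coloc_abf <- function(t1, t2, cfg = coloc_config(), omega1 = NULL,
                      omega2 = NULL, omega_scale = 0.15) {
  m <- nrow(t1)
  if (nrow(t2) != m || m < 2L) {
    stop("coloc needs at least 2 shared variants, row-aligned across traits")
  }
  if (!all(t1$pos == t2$pos)) stop("traits are not aligned on the same variants")
  if (is.null(omega1)) omega1 <- (omega_scale * estimate_sigma(t1))^2
  if (is.null(omega2)) omega2 <- (omega_scale * estimate_sigma(t2))^2
  lbf1 <- log_abf(t1$beta, t1$se^2, omega1)
  lbf2 <- log_abf(t2$beta, t2$se^2, omega2)

  l1 <- .logsumexp(lbf1)
  l2 <- .logsumexp(lbf2)
  lsum <- .logsumexp(lbf1 + lbf2)
  lh <- c(
    h0 = 0,
    h1 = log(cfg$p1) + l1,
    h2 = log(cfg$p2) + l2,
    h3 = log(cfg$p1) + log(cfg$p2) + .logdiff(l1 + l2, lsum),
    h4 = log(cfg$p12) + lsum
  )
  denom <- .logsumexp(lh)
  pp <- exp(lh - denom)
  names(pp) <- paste0("PP", 0:4)

  top <- which.max(lbf1 + lbf2)
  res <- list(pp = pp, n_variants = m,
              top_shared = variant_ids(t1)[top],
              top_index = top, lbf1 = lbf1, lbf2 = lbf2)
  res$classification <- classify_coloc(res)
  res$direction <- if (res$classification == "none") {
    NA_character_
  } else {
    effect_direction(t1, t2, res)
  }
  class(res) <- "coloc_result"
  res
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization over", x$n_variants, "shared variants\n")
  print(round(x$pp, 4))
  cat("classification:", x$classification,
      if (!is.na(x$direction)) paste0("(", x$direction, ")"), "\n")
  invisible(x)
}

#' Classify colocalization evidence
#'
#' Decision rules on the hypothesis posteriors: strong evidence when
#' `PP3 + PP4 >= 0.99` and `PP4/PP3 >= 5`; suggestive when
#' `PP3 + PP4 >= 0.8` and `PP4/PP3 >= 3`; otherwise none.  A numerically
#' zero PP3 is treated as an infinite ratio, which passes the ratio
#' condition.
#'
#' @param r a `coloc_result` (or any list with a `pp` element).
#' @return `"strong"`, `"suggestive"` or `"none"`.
#' @export
classify_coloc <- function(r) {
  pp3 <- r$pp[["PP3"]]
  pp4 <- r$pp[["PP4"]]
  ratio <- if (pp3 == 0) Inf else pp4 / pp3
  if (pp3 + pp4 >= 0.99 && ratio >= 5) return("strong")
  if (pp3 + pp4 >= 0.8 && ratio >= 3) return("suggestive")
  "none"
}

#' Direction of the shared genetic effect
#'
#' At the variant maximizing the per-variant H4 contribution (the product
#' of the two traits' Bayes factors), the sign of `beta1 * beta2`
#' determines whether the risk allele moves the two traits in the same
#' direction (`"correlated"`) or in opposite directions
#' (`"anti-correlated"`).  A zero effect at the top variant yields
#' `"undetermined"`.
#'
#' @param t1,t2 the row-aligned locus tables passed to [coloc_abf()].
#' @param r the `coloc_result`.
#' @return `"correlated"`, `"anti-correlated"` or `"undetermined"`.
#' @export
effect_direction <- function(t1, t2, r) {
  i <- r$top_index
  s <- t1$beta[i] * t2$beta[i]
  if (s > 0) "correlated" else if (s < 0) "anti-correlated" else "undetermined"
}
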