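#' Select independent genetic instruments by LD pruning
#'
#' Greedy p-value pruning of genome-wide-significant exposure variants:
#' repeatedly keep the smallest-p remaining variant and remove all
#' remaining variants with `r^2 >= r2_threshold` within `window` bp of it.
#'
#' @param exposure a `sumstats` object for the exposure trait.
#' @param ld LD matrix covering (at least) the significant exposure
#'   variants; pairs absent from it are treated as unlinked.
#' @param p_threshold instrument significance threshold (default 5e-8).
#' @param r2_threshold pruning threshold (default 0.01).
#' @param window pruning window in bp (default 250 kb).
#' @return character vector of selected instrument ids (possibly empty,
#'   with a warning).
#' @export
select_instruments <- function(exposure, ld, p_threshold = 5e-8,
                               r2_threshold = 0.01, window = 2.5e5) {
  df <- as.data.frame(exposure)
  df$id <- variant_ids(df)
  cand <- df[df$pval < p_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) {
    warning("no variant reaches the instrument significance threshold")
    return(character())
  }
  cand <- cand[order(cand$pval), , drop = FALSE]
  kept <- character()
  while (nrow(cand) > 0L) {
    top <- cand[1L, ]
    kept <- c(kept, top$id)
    near <- cand$chrom == top$chrom & abs(cand$pos - top$pos) <= window
    r2 <- rep(0, nrow(cand))
    in_ld <- near & cand$id %in% colnames(ld) & top$id %in% colnames(ld)
    if (any(in_ld)) r2[in_ld] <- ld[top$id, cand$id[in_ld]]^2
    drop <- (near & r2 >= r2_threshold) | cand$id == top$id
    cand <- cand[!drop, , drop = FALSE]
  }
  kept
}

#' Build an instrument table from harmonized exposure/outcome statistics
#'
#' Pairs the selected variants' exposure and outcome effects (tables must
#' already be row-aligned, e.g. by [harmonize_alleles()]) and aligns every
#' instrument to its exposure-increasing allele, flipping the sign of both
#' betas where the exposure effect is negative — the orientation the
#' median/mode estimators require.  Estimates are invariant to the
#' original allele coding.
#'
#' @param exposure,outcome row-aligned `sumstats`.
#' @param ids instrument variant ids (default: all rows).
#' @return data frame: `id`, `beta_exp`, `se_exp`, `beta_out`, `se_out`,
#'   with `beta_exp > 0`.
#' @export
instruments <- function(exposure, outcome, ids = NULL) {
  ie <- variant_ids(exposure)
  if (!identical(ie, variant_ids(outcome))) {
    stop("exposure and outcome tables are not row-aligned; harmonize first")
  }
  if (is.null(ids)) ids <- ie
  idx <- match(ids, ie)
  if (anyNA(idx)) stop("instrument(s) absent: ", paste(ids[is.na(idx)], collapse = ", "))
  out <- data.frame(id = ids,
                    beta_exp = exposure$beta[idx], se_exp = exposure$se[idx],
                    beta_out = outcome$beta[idx], se_out = outcome$se[idx],
                    stringsAsFactors = FALSE)
  flip <- out$beta_exp < 0
  out$beta_exp[flip] <- -out$beta_exp[flip]
  out$beta_out[flip] <- -out$beta_out[flip]
  if (any(out$beta_exp == 0)) stop("instrument with zero exposure effect")
  out
}

.mr_estimate <- function(method, beta, se, pval, n, intercept = NA_real_,
                         intercept_p = NA_real_) {
  data.frame(method = method, beta = beta, se = se, pval = pval,
             n_instruments = n, egger_intercept = intercept,
             egger_intercept_p = intercept_p, stringsAsFactors = FALSE)
}

#' Wald ratio estimator
#'
#' Single-instrument causal estimate `beta_out / beta_exp`, with a
#' first-order delta-method standard error `se_out / |beta_exp|` and a
#' two-sided normal p-value.
#'
#' @param instr one-row instrument table (see [instruments()]).
#' @return one-row MR estimate data frame.
#' @export
wald_ratio <- function(instr) {
  if (nrow(instr) != 1L) stop("wald_ratio takes exactly one instrument")
  if (instr$beta_exp == 0) stop("zero exposure effect")
  b <- instr$beta_out / instr$beta_exp
  se <- instr$se_out / abs(instr$beta_exp)
  .mr_estimate("wald", b, se, 2 * stats::pnorm(-abs(b / se)), 1L)
}

#' Inverse-variance-weighted estimator
#'
#' Fixed-effect inverse-variance-weighted combination of per-instrument
#' Wald ratios with first-order weights `beta_exp^2 / se_out^2` —
#' algebraically identical to the zero-intercept weighted regression of
#' `beta_out` on `beta_exp` with weights `1 / se_out^2`.
#'
#' @param instr instrument table with at least 2 rows.
#' @return one-row MR estimate data frame.
#' @export
mr_ivw <- function(instr) {
  if (nrow(instr) < 2L) stop("IVW needs at least 2 instruments; use wald_ratio")
  ratio <- instr$beta_out / instr$beta_exp
  w <- instr$beta_exp^2 / instr$se_out^2
  b <- sum(w * ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  .mr_estimate("ivw", b, se, 2 * stats::pnorm(-abs(b / se)), nrow(instr))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with
#' a free intercept (weights `1 / se_out^2`): the slope estimates the
#' causal effect allowing each instrument an average direct (pleiotropic)
#' effect, and a nonzero intercept flags directional pleiotropy.
#' Standard errors are inflated by the regression dispersion when it
#' exceeds 1 (the usual MR-Egger convention); p-values use the
#' t-distribution with `k - 2` degrees of freedom.
#'
#' @param instr instrument table with at least 3 rows, aligned to the
#'   exposure-increasing allele.
#' @return one-row MR estimate data frame including the intercept and its
#'   p-value.
#' @export
mr_egger <- function(instr) {
  k <- nrow(instr)
  if (k < 3L) stop("MR-Egger needs at least 3 instruments")
  fit <- stats::lm(beta_out ~ beta_exp, data = instr,
                   weights = 1 / instr$se_out^2)
  cf <- summary(fit)$coefficients
  disp <- max(1, summary(fit)$sigma)  # no shrinkage below 1
  slope_se <- cf["beta_exp", "Std. Error"] / summary(fit)$sigma * disp
  int_se <- cf["(Intercept)", "Std. Error"] / summary(fit)$sigma * disp
  slope <- cf["beta_exp", "Estimate"]
  int <- cf["(Intercept)", "Estimate"]
  .mr_estimate("egger", slope, slope_se,
               2 * stats::pt(-abs(slope / slope_se), df = k - 2), k,
               intercept = int,
               intercept_p = 2 * stats::pt(-abs(int / int_se), df = k - 2))
}

.wmedian <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  ww <- w[ord] / sum(w)
  p <- cumsum(ww) - ww / 2
  if (0.5 <= p[1L]) return(r[1L])
  k <- length(r)
  if (0.5 >= p[k]) return(r[k])
  i <- max(which(p < 0.5))
  r[i] + (r[i + 1L] - r[i]) * (0.5 - p[i]) / (p[i + 1L] - p[i])
}

# parametric bootstrap over instrument estimates for median/mode SEs
.mr_boot_se <- function(instr, statistic, n_boot, seed) {
  with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(nrow(instr), instr$beta_exp, instr$se_exp)
      by <- stats::rnorm(nrow(instr), instr$beta_out, instr$se_out)
      statistic(by / bx, bx^2 / instr$se_out^2)
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted median estimator
#'
#' Orders the per-instrument Wald ratios and takes the value at cumulative
#' inverse-variance weight one half (linear interpolation between the
#' bracketing ratio percentiles).  Consistent when instruments carrying at
#' least half the weight are valid.  The standard error is a seeded
#' parametric bootstrap over the instrument estimates.
#'
#' @param instr instrument table with at least 3 rows.
#' @param n_boot bootstrap replicates for the standard error.
#' @param seed bootstrap seed.
#' @return one-row MR estimate data frame.
#' @export
mr_weighted_median <- function(instr, n_boot = 1000, seed = 1) {
  if (nrow(instr) < 3L) stop("weighted median needs at least 3 instruments")
  ratio <- instr$beta_out / instr$beta_exp
  w <- instr$beta_exp^2 / instr$se_out^2
  b <- .wmedian(ratio, w)
  se <- .mr_boot_se(instr, function(r, w) .wmedian(r, w), n_boot, seed)
  .mr_estimate("weighted_median", b, se, 2 * stats::pnorm(-abs(b / se)),
               nrow(instr))
}

.wmode <- function(ratio, w, bw_factor = 1) {
  w <- w / sum(w)
  mu <- sum(w * ratio)
  s <- sqrt(sum(w * (ratio - mu)^2))
  if (s == 0) return(ratio[1L])
  h <- bw_factor * 0.9 * s * length(ratio)^(-1 / 5)
  dens <- function(x) {
    vapply(x, function(xi) sum(w * stats::dnorm(xi, ratio, h)), numeric(1))
  }
  # coarse grid to bracket the global mode, then local refinement
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 512)
  i <- which.max(dens(grid))
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  stats::optimize(dens, c(lo, hi), maximum = TRUE)$maximum
}

#' Weighted mode estimator
#'
#' Mode of the inverse-variance-weighted kernel density of the Wald
#' ratios (Gaussian kernel; weighted-Silverman bandwidth scaled by
#' `bw_factor`).  Consistent when the largest group of instruments sharing
#' a ratio value is valid.  As the bandwidth grows the estimate approaches
#' the weighted mean.  Standard error by seeded parametric bootstrap.
#'
#' @param instr instrument table with at least 3 rows.
#' @param bw_factor multiplicative bandwidth scale (default 1).
#' @param n_boot,seed bootstrap settings.
#' @return one-row MR estimate data frame.
#' @export
mr_weighted_mode <- function(instr, bw_factor = 1, n_boot = 1000, seed = 1) {
  if (nrow(instr) < 3L) stop("weighted mode needs at least 3 instruments")
  ratio <- instr$beta_out / instr$beta_exp
  w <- instr$beta_exp^2 / instr$se_out^2
  b <- .wmode(ratio, w, bw_factor)
  se <- .mr_boot_se(instr, function(r, w) .wmode(r, w, bw_factor), n_boot, seed)
  .mr_estimate("weighted_mode", b, se, 2 * stats::pnorm(-abs(b / se)),
               nrow(instr))
}

#' Gene-by-gene two-sample MR screen
#'
#' For each gene's exposure statistics: harmonize against the outcome,
#' select independent instruments, and dispatch — the Wald ratio when a
#' single instrument remains, IVW when two or more, plus Egger, weighted
#' median and weighted mode sensitivity estimates where the instrument
#' count allows (3 or more).  Primary p-values (Wald/IVW) are adjusted
#' across genes by Benjamini-Hochberg (with Bonferroni also reported), and
#' a concordance flag marks whether all available estimators agree in
#' sign.
#'
#' @param exposures named list of `sumstats`, one per gene.
#' @param outcome outcome `sumstats`.
#' @param ld LD matrix, or a named list of per-gene LD matrices.
#' @param fdr false-discovery-rate cutoff applied to the BH-adjusted
#'   primary p-values (default 0.1).
#' @param p_threshold,r2_threshold,window instrument selection settings,
#'   see [select_instruments()].
#' @param n_boot,seed bootstrap settings for the sensitivity estimators.
#' @return data frame with one row per gene and estimator: `gene`,
#'   `method`, `beta`, `se`, `pval`, `n_instruments`, `egger_intercept`,
#'   `egger_intercept_p`, `concordant`, and for the primary estimator
#'   `p_adj_bh`, `p_adj_bonferroni`, `significant`.
#' @export
mr_pipeline <- function(exposures, outcome, ld, fdr = 0.1,
                        p_threshold = 5e-8, r2_threshold = 0.01,
                        window = 2.5e5, n_boot = 1000, seed = 1) {
  rows <- list()
  for (gene in names(exposures)) {
    gld <- if (is.list(ld) && !is.matrix(ld)) ld[[gene]] else ld
    h <- tryCatch(harmonize_alleles(exposures[[gene]], outcome),
                  error = function(e) NULL)
    if (is.null(h)) {
      warning("gene ", gene, ": no shared variants with outcome; skipped")
      next
    }
    sel <- suppressWarnings(
      select_instruments(h$a, gld, p_threshold, r2_threshold, window))
    if (length(sel) == 0L) {
      warning("gene ", gene, ": no instruments; skipped")
      next
    }
    instr <- instruments(h$a, h$b, sel)
    primary <- if (nrow(instr) == 1L) wald_ratio(instr) else mr_ivw(instr)
    ests <- primary
    if (nrow(instr) >= 3L) {
      gseed <- substream_seed(seed, match(gene, names(exposures)))
      ests <- rbind(ests,
                    mr_egger(instr),
                    mr_weighted_median(instr, n_boot, gseed),
                    mr_weighted_mode(instr, n_boot = n_boot, seed = gseed))
    }
    ests$gene <- gene
    ests$primary <- ests$method == primary$method
    signs <- sign(ests$beta)
    ests$concordant <- all(signs == signs[1L]) || any(signs == 0)
    rows[[gene]] <- ests
  }
  if (length(rows) == 0L) stop("no gene yielded instruments")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj_bh <- NA_real_
  out$p_adj_bonferroni <- NA_real_
  prim <- out$primary
  out$p_adj_bh[prim] <- stats::p.adjust(out$pval[prim], method = "BH")
  out$p_adj_bonferroni[prim] <- stats::p.adjust(out$pval[prim],
                                                method = "bonferroni")
  out$significant <- !is.na(out$p_adj_bh) & out$p_adj_bh < fdr
  out[c("gene", "method", "primary", "beta", "se", "pval", "n_instruments",
        "egger_intercept", "egger_intercept_p", "concordant",
        "p_adj_bh", "p_adj_bonferroni", "significant")]
}
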