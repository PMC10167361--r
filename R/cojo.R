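#' Approximate joint effects from marginal summary statistics
#'
#' Reconstructs the multiple-regression solution for a set of selected
#' variants from their marginal effects, per-variant genotype variances and
#' a reference LD matrix — the summary-level joint/conditional analysis
#' popularized by GCTA-COJO.  With centered cross-products
#' `X'X = D^{1/2} R D^{1/2}` (R the LD correlations, `D_j` the genotype
#' sum of squares) and `X'y_j = beta_j D_j`, the joint coefficients are
#' `(X'X)^{-1} X'y` and their covariance `s^2 (X'X)^{-1}`, with the
#' residual variance recomputed from the phenotypic variance `sigma2` and
#' the current fit.  Genotype variances default to the Hardy-Weinberg
#' value `2 f (1 - f)`; supplying the realized dosage variances of an
#' in-sample panel makes the algebra exact.
#'
#' @param ss `sumstats` restricted to the locus.
#' @param ld [compute_ld()]-style matrix covering the locus variants
#'   (dimnames are `chrom:pos` ids).
#' @param selected character ids of the variants to fit jointly.
#' @param sigma2 phenotypic variance (see [estimate_sigma()]; 1 for a
#'   standardized phenotype).
#' @param var_x optional named per-variant genotype variances; default
#'   `2 f (1 - f)` from the summary statistics.
#' @param ridge value added to the diagonal of `X'X` (relative to its
#'   mean diagonal) to absorb finite-reference-panel noise.
#' @param max_r2 collinearity guard: pairwise `r^2` among selected
#'   variants above this is a fatal error naming the pair.
#' @return data frame: `id`, `beta_joint`, `se_joint`, `pval_joint`.
#' @export
joint_effects <- function(ss, ld, selected, sigma2 = 1, var_x = NULL,
                          ridge = 1e-8, max_r2 = 0.9) {
  ids <- variant_ids(ss)
  sel <- match(selected, ids)
  if (anyNA(sel)) {
    stop("selected variant(s) absent from summary statistics: ",
         paste(selected[is.na(sel)], collapse = ", "))
  }
  lsel <- match(selected, colnames(ld))
  if (anyNA(lsel)) {
    stop("selected variant(s) absent from LD matrix: ",
         paste(selected[is.na(lsel)], collapse = ", "))
  }
  k <- length(sel)
  r <- ld[lsel, lsel, drop = FALSE]
  if (k > 1L) {
    r2 <- r^2
    diag(r2) <- 0
    if (any(r2 > max_r2)) {
      w <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
      stop("collinear selected variants (r^2 = ",
           signif(max(r2), 3), "): ", selected[w[1]], " and ", selected[w[2]])
    }
  }
  n_eff <- stats::median(ss$n[sel])
  vx <- if (is.null(var_x)) {
    2 * ss$freq[sel] * (1 - ss$freq[sel])
  } else {
    unname(var_x[selected])
  }
  d <- vx * (n_eff - 1)
  b_marg <- ss$beta[sel]
  xtx <- sqrt(d) * t(sqrt(d) * t(r))   # D^{1/2} R D^{1/2}, symmetric
  diag(xtx) <- diag(xtx) + ridge * mean(diag(xtx))
  xty <- b_marg * d
  beta_j <- solve(xtx, xty)
  yty <- sigma2 * (n_eff - 1)
  rss <- max(yty - sum(beta_j * xty), 0)
  s2 <- max(rss / (n_eff - k - 1), 1e-12)
  cov_j <- s2 * solve(xtx)
  se_j <- sqrt(diag(cov_j))
  z <- beta_j / se_j
  data.frame(id = selected, beta_joint = unname(beta_j),
             se_joint = unname(se_j),
             pval_joint = pmax(2 * stats::pnorm(-abs(z)),
                               .Machine$double.xmin),
             stringsAsFactors = FALSE)
}

#' Conditional summary statistics given a set of index variants
#'
#' For every variant in the locus, refits the joint model of that variant
#' together with the conditioning set and reports the variant's joint
#' coefficient as its conditional effect — the summary-level analogue of
#' exact conditional analysis.  Conditioning variants themselves get a
#' conditional effect of zero (p = 1).  An empty conditioning set returns
#' the marginal statistics unchanged.
#'
#' @inheritParams joint_effects
#' @param conditioning character ids of the variants conditioned on.
#' @return a `sumstats` object with `beta`, `se`, `pval` replaced by their
#'   conditional counterparts.
#' @export
conditional_sumstats <- function(ss, ld, conditioning, sigma2 = 1,
                                 var_x = NULL, ridge = 1e-8, max_r2 = 0.9) {
  if (length(conditioning) == 0L) return(ss)
  ids <- variant_ids(ss)
  out <- as.data.frame(ss)
  for (i in seq_along(ids)) {
    if (ids[i] %in% conditioning) {
      out$beta[i] <- 0
      out$pval[i] <- 1
      next
    }
    r2max <- max(ld[ids[i], conditioning]^2)
    if (r2max > max_r2) {
      # indistinguishable from a conditioning variant at this LD; treat as
      # fully explained rather than erroring per-variant
      out$beta[i] <- 0
      out$pval[i] <- 1
      next
    }
    fit <- joint_effects(ss, ld, c(ids[i], conditioning), sigma2 = sigma2,
                         var_x = var_x, ridge = ridge, max_r2 = Inf)
    out$beta[i] <- fit$beta_joint[1L]
    out$se[i] <- fit$se_joint[1L]
    out$pval[i] <- fit$pval_joint[1L]
  }
  sumstats(out, trait = attr(ss, "trait"), build = attr(ss, "build"),
           validate = FALSE)
}

#' Stepwise selection of conditionally independent signals in a locus
#'
#' COJO-style forward selection with a backward check.  Starting from the
#' locus index variant, the variant with the smallest conditional p-value
#' is added whenever its joint p-value stays below `p_joint`; candidates
#' collinear (`r^2 >` `max_r2`) with any selected variant are skipped.
#' After each addition, any selected variant whose joint p-value has risen
#' above `p_joint` is dropped.  At termination every selected variant
#' retains joint p < `p_joint`.
#'
#' @param locus one row of the [define_loci()] result; its index variant
#'   must be genome-wide significant (p < 5e-8) — the precondition for
#'   running conditional analysis.
#' @param ss genome-wide (or locus-wide) `sumstats`.
#' @param ld LD matrix covering the locus variants.
#' @param sigma2,var_x,ridge,max_r2 passed to [joint_effects()].
#' @param p_joint locus-wide joint significance threshold for a signal
#'   (default 1e-6).
#' @param max_signals safety cap on the number of signals.
#' @return data frame with one row per signal: `id`, `beta_joint`,
#'   `se_joint`, `pval_joint` and a list column `conditioned_on` of the
#'   co-selected index ids.
#' @export
stepwise_selection <- function(locus, ss, ld, sigma2 = 1, var_x = NULL,
                               ridge = 1e-8, max_r2 = 0.9, p_joint = 1e-6,
                               max_signals = 10L) {
  if (locus$index_pval >= 5e-8) {
    stop("locus index variant is not genome-wide significant (p = ",
         signif(locus$index_pval, 3), "); loci must come from define_loci")
  }
  lss <- locus_variants(ss, locus)
  ids <- variant_ids(lss)
  selected <- locus$index_id
  repeat {
    if (length(selected) >= max_signals) break
    cond <- conditional_sumstats(lss, ld, selected, sigma2 = sigma2,
                                 var_x = var_x, ridge = ridge,
                                 max_r2 = max_r2)
    cand <- setdiff(ids, selected)
    # skip candidates collinear with the selected set
    ok <- vapply(cand, function(v) {
      max(ld[v, selected]^2) <= max_r2
    }, logical(1))
    cand <- cand[ok]
    if (length(cand) == 0L) break
    cp <- cond$pval[match(cand, ids)]
    best <- cand[which.min(cp)]
    if (min(cp) >= p_joint) break
    trial <- c(selected, best)
    fit <- joint_effects(lss, ld, trial, sigma2 = sigma2, var_x = var_x,
                         ridge = ridge, max_r2 = max_r2)
    if (fit$pval_joint[match(best, fit$id)] >= p_joint) break
    selected <- trial
    # backward check: drop signals that lost locus-wide significance,
    # but never the variant just added
    drop <- fit$id[fit$pval_joint >= p_joint & fit$id != best]
    if (length(drop) > 0L) selected <- setdiff(selected, drop)
  }
  fit <- joint_effects(lss, ld, selected, sigma2 = sigma2, var_x = var_x,
                       ridge = ridge, max_r2 = max_r2)
  fit$conditioned_on <- I(lapply(fit$id, function(v) setdiff(selected, v)))
  fit
}
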