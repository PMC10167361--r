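#' Fine-mapping configuration
#'
#' @param omega_scale scale of the Gaussian effect prior: the prior
#'   variance is `omega = (omega_scale * sigma)^2`, with `sigma` the
#'   phenotype standard deviation (default 0.15).
#' @param gamma prior probability that the region harbors no association
#'   (default 0.05, controlling the expected false discovery rate at 5%
#'   given genome-wide-significant loci).
#' @param credible_mass cumulative posterior mass the ranked credible set
#'   must attain (default 0.99).
#' @return a validated `finemap_config` list.
#' @export
finemap_config <- function(omega_scale = 0.15, gamma = 0.05,
                           credible_mass = 0.99) {
  stopifnot(omega_scale > 0, gamma >= 0, gamma < 1,
            credible_mass > 0, credible_mass <= 1)
  structure(list(omega_scale = omega_scale, gamma = gamma,
                 credible_mass = credible_mass), class = "finemap_config")
}

#' Estimate the phenotype standard deviation from summary statistics
#'
#' For a quantitative trait analyzed by per-variant linear regression,
#' `2 n_j f_j (1 - f_j)` is approximately
#' `sigma^2 (1 / Var(beta_j) - 1)`, so `sigma^2` is recovered as the
#' no-intercept least-squares slope of `2 n f (1 - f)` on
#' `1 / Var(beta) - 1` across variants (the `- 1` is numerically
#' negligible whenever `Var(beta)` is small).  This is a global property
#' of the trait, estimated once from all available variants, not per
#' locus.
#'
#' @param ss a `sumstats` object with at least 10 variants.
#' @return `sigma`, the estimated phenotype standard deviation.
#' @export
estimate_sigma <- function(ss) {
  if (nrow(ss) < 10L) stop("sigma estimation needs at least 10 variants")
  x <- 1 / ss$se^2 - 1
  y <- 2 * ss$n * ss$freq * (1 - ss$freq)
  slope <- sum(x * y) / sum(x * x)
  if (!is.finite(slope) || slope <= 0) {
    stop("non-positive sigma^2 slope; summary statistics are inconsistent")
  }
  sqrt(slope)
}

#' Natural-log approximate Bayes factor for a single variant
#'
#' Wakefield's closed-form Bayes factor comparing a Gaussian effect prior
#' `b ~ N(0, omega)` against the point null `b = 0` for an estimated
#' effect `beta` with sampling variance `V`:
#' `Lambda = 1/2 log(V / (V + omega)) + omega beta^2 / (2 V (V + omega))`.
#' With `omega = 0` the prior collapses onto the null and `Lambda = 0`.
#'
#' @param beta estimated effect size(s).
#' @param V sampling variance(s) (`se^2`), strictly positive.
#' @param omega prior variance of the effect, non-negative.
#' @return log approximate Bayes factor(s), vectorized over the inputs.
#' @export
log_abf <- function(beta, V, omega) {
  if (any(V <= 0)) stop("V must be strictly positive")
  if (any(omega < 0)) stop("omega must be non-negative")
  0.5 * log(V / (V + omega)) + omega * beta^2 / (2 * V * (V + omega))
}

#' Per-variant posterior probabilities of driving the association
#'
#' Single-causal-variant posteriors over the `l` variants of a region plus
#' an explicit no-association model: the null (index 0) has Bayes factor 1
#' and prior mass `gamma`, each variant has prior mass `(1 - gamma) / l`,
#' so `pi_j = ((1-gamma)/l) ABF_j / (gamma + ((1-gamma)/l) sum_k ABF_k)`
#' and `pi_0` is the complementary null mass.  Computed in log space so
#' extreme log-Bayes-factors (|Lambda| in the hundreds) cannot overflow.
#'
#' @param lambdas per-variant log approximate Bayes factors.
#' @param cfg a [finemap_config()].
#' @return list with `pi` (per-variant posteriors), `pi0` (null
#'   posterior), `lambdas`, `l`, and `gamma`; `pi0 + sum(pi) = 1`.
#' @export
posteriors <- function(lambdas, cfg = finemap_config()) {
  l <- length(lambdas)
  if (l < 1L) stop("at least one variant is required")
  gamma <- cfg$gamma
  log_terms <- c(log(gamma), log1p(-gamma) - log(l) + lambdas)
  if (gamma == 0) log_terms <- log_terms[-1L]
  mx <- max(log_terms)
  lse <- mx + log(sum(exp(log_terms - mx)))
  pi_j <- exp(log1p(-gamma) - log(l) + lambdas - lse)
  pi0 <- if (gamma == 0) 0 else exp(log(gamma) - lse)
  list(pi = pi_j, pi0 = pi0, lambdas = lambdas, l = l, gamma = gamma)
}

#' Ranked cumulative credible set
#'
#' Ranks variants by descending log approximate Bayes factor (ties broken
#' by genomic position for determinism), renormalizes the posteriors over
#' the variants only (excluding the null mass, since the set is defined
#' conditional on the region containing a signal), and accumulates ranked
#' variants until the cumulative posterior mass attains or exceeds the
#' configured threshold.
#'
#' @param post result of [posteriors()].
#' @param cfg a [finemap_config()]; `credible_mass` is the threshold.
#' @param ids optional variant identifiers (default: indices).
#' @param pos optional genomic positions used to break ties.
#' @return data frame of the credible-set members in rank order: `id`,
#'   `lambda`, `pi` (renormalized), `cum_mass`.
#' @export
credible_set <- function(post, cfg = finemap_config(), ids = NULL,
                         pos = NULL) {
  l <- post$l
  if (is.null(ids)) ids <- as.character(seq_len(l))
  if (is.null(pos)) pos <- seq_len(l)
  ord <- order(-post$lambdas, pos)
  pi_renorm <- post$pi / sum(post$pi)
  cum <- cumsum(pi_renorm[ord])
  keep <- seq_len(which(cum >= cfg$credible_mass - 1e-12)[1L])
  data.frame(id = ids[ord][keep], lambda = post$lambdas[ord][keep],
             pi = pi_renorm[ord][keep], cum_mass = cum[keep],
             stringsAsFactors = FALSE)
}

#' Fine-map one association signal
#'
#' Full per-signal chain: prior variance `omega = (omega_scale * sigma)^2`
#' from the trait-wide sigma estimate, per-variant log approximate Bayes
#' factors, null-inclusive posteriors, and the ranked cumulative credible
#' set — run on the marginal statistics and, when a conditioning set is
#' given, also on the conditional statistics that isolate this signal from
#' the locus's other index variants.  Variants with posterior probability
#' above `pip_threshold` are flagged as potential causal variants.
#'
#' @param lss locus `sumstats` (marginal scale).
#' @param ld LD matrix covering the locus (needed only when conditioning).
#' @param conditioning character ids of the other index variants in the
#'   locus; empty for a single-signal locus.
#' @param cfg a [finemap_config()].
#' @param sigma trait-wide phenotype sd (see [estimate_sigma()]); default
#'   re-estimated from `lss`.
#' @param var_x optional realized genotype variances for the conditional
#'   algebra.
#' @param pip_threshold posterior-probability threshold for reporting a
#'   variant as potentially causal (default 0.01).
#' @return list with elements `marginal` and `conditional` (identical when
#'   `conditioning` is empty), each containing `table` (per-variant id,
#'   lambda, pi, credible-set flag, potential-causal flag), `credible_set`,
#'   `pi0`; plus `sigma` and `omega`.
#' @export
finemap_signal <- function(lss, ld = NULL, conditioning = character(),
                           cfg = finemap_config(), sigma = NULL,
                           var_x = NULL, pip_threshold = 0.01) {
  if (is.null(sigma)) sigma <- estimate_sigma(lss)
  omega <- (cfg$omega_scale * sigma)^2
  run <- function(ss) {
    lam <- log_abf(ss$beta, ss$se^2, omega)
    post <- posteriors(lam, cfg)
    cs <- credible_set(post, cfg, ids = variant_ids(ss), pos = ss$pos)
    tab <- data.frame(id = variant_ids(ss), lambda = lam, pi = post$pi,
                      in_credible_set = variant_ids(ss) %in% cs$id,
                      potential_causal = post$pi > pip_threshold,
                      stringsAsFactors = FALSE)
    list(table = tab, credible_set = cs, pi0 = post$pi0)
  }
  marginal <- run(lss)
  conditional <- if (length(conditioning) > 0L) {
    if (is.null(ld)) stop("conditioning requires an LD matrix")
    run(conditional_sumstats(lss, ld, conditioning, sigma2 = sigma^2,
                             var_x = var_x))
  } else {
    marginal
  }
  list(marginal = marginal, conditional = conditional,
       sigma = sigma, omega = omega)
}
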