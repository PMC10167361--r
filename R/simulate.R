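#' Deterministic substream seeds
#'
#' Every generator in the package derives its randomness from a single
#' integer seed expanded into per-stage substreams by a counter scheme, so
#' that adding a stage never perturbs the draws of earlier stages.
#'
#' @param seed integer master seed.
#' @param stage integer stage counter.
#' @return an integer seed for the substream.
#' @export
substream_seed <- function(seed, stage) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + stage * 9973) %% 2147483647)
}

# Evaluate expr under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulation configuration for an LD-structured genotype panel
#'
#' Bundles and validates the parameters of the synthetic cohort: sample
#' size, variants arranged in AR(1) LD blocks, the within-block latent
#' correlation, the minor-allele-frequency range, and the causal model
#' (indices, per-allele joint effects, target heritability).
#'
#' @param n_samples number of diploid samples.
#' @param block_sizes integer vector of variants per LD block; their sum is
#'   the total variant count.
#' @param rho target correlation between adjacent variants within a block,
#'   in \[0, 1); correlation decays approximately geometrically with
#'   variant distance (AR(1)-style blocks).  Adjacent allele frequencies
#'   are kept locally similar (a bounded logit-scale random walk) because
#'   the attainable correlation between binary alleles shrinks as their
#'   frequencies diverge; analyses nevertheless always use realized LD.
#' @param maf_range minor-allele-frequency sampling interval within
#'   (0.01, 0.5).
#' @param causal_index integer indices (into the concatenated variant
#'   vector) of causal variants.
#' @param causal_betas per-allele joint effects at the causal variants.
#' @param h2 target narrow-sense heritability in \[0, 1).
#' @param pos_step base-pair spacing between adjacent variants in a block
#'   (blocks are separated by 2 Mb so each block forms its own locus).
#' @param seed integer master seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 5000, block_sizes = 200, rho = 0.9,
                       maf_range = c(0.05, 0.5), causal_index = integer(),
                       causal_betas = numeric(), h2 = 0.3,
                       pos_step = 2000, seed = 1) {
  n_variants <- sum(block_sizes)
  stopifnot(n_samples >= 2, all(block_sizes >= 1), rho >= 0, rho < 1,
            length(maf_range) == 2, maf_range[1] > 0.01 - 1e-12,
            maf_range[2] <= 0.5, h2 >= 0, h2 < 1,
            length(causal_index) == length(causal_betas))
  if (length(causal_index) > 0 &&
      (min(causal_index) < 1 || max(causal_index) > n_variants)) {
    stop("causal_index out of range 1..", n_variants)
  }
  structure(list(n_samples = as.integer(n_samples),
                 block_sizes = as.integer(block_sizes),
                 n_variants = as.integer(n_variants),
                 rho = rho, maf_range = maf_range,
                 causal_index = as.integer(causal_index),
                 causal_betas = as.numeric(causal_betas),
                 h2 = h2, pos_step = as.integer(pos_step),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Allele-frequency series for one block: bounded random walk on the logit
# scale, so adjacent variants have similar frequencies and the target
# adjacent correlation stays attainable.
.block_mafs <- function(m, maf_range, step_sd = 0.15) {
  lo <- stats::qlogis(maf_range[1])
  hi <- stats::qlogis(maf_range[2])
  t <- numeric(m)
  t[1] <- stats::runif(1, lo, hi)
  if (m > 1) {
    steps <- stats::rnorm(m - 1, 0, step_sd)
    for (j in 2:m) {
      v <- t[j - 1] + steps[j - 1]
      # reflect into [lo, hi]
      while (v < lo || v > hi) {
        if (v < lo) v <- 2 * lo - v
        if (v > hi) v <- 2 * hi - v
      }
      t[j] <- v
    }
  }
  stats::plogis(t)
}

# One block of haplotypes: first-order Markov chain over binary alleles
# whose adjacent-pair correlation targets rho (clamped to the Frechet
# bounds where allele frequencies diverge).
.markov_haplotypes <- function(n_hap, f, rho) {
  m <- length(f)
  x <- matrix(0L, n_hap, m)
  x[, 1L] <- (stats::runif(n_hap) < f[1L])
  if (m > 1) {
    s <- sqrt(f * (1 - f))
    for (j in 2:m) {
      p11 <- f[j - 1] * f[j] + rho * s[j - 1] * s[j]
      p11 <- min(max(p11, max(0, f[j - 1] + f[j] - 1) + 1e-9),
                 min(f[j - 1], f[j]) - 1e-9)
      p_given1 <- p11 / f[j - 1]
      p_given0 <- (f[j] - p11) / (1 - f[j - 1])
      prob <- p_given0 + (p_given1 - p_given0) * x[, j - 1L]
      x[, j] <- (stats::runif(n_hap) < prob)
    }
  }
  x
}

#' Simulate an LD-structured genotype panel
#'
#' Each sample is the sum of two independent haplotypes; within a block,
#' a haplotype is a first-order Markov chain over binary alleles whose
#' adjacent-pair correlation targets `rho` and whose allele frequencies
#' follow a bounded random walk inside `maf_range`.  Dosages are in
#' {0, 1, 2}, in Hardy-Weinberg proportions by construction, with
#' correlation decaying approximately geometrically within a block and
#' zero across blocks.
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_panel()]; per-variant allele frequencies are stored
#'   in the `variants` annotation as `maf`.
#' @export
simulate_panel <- function(cfg) {
  if (any(cfg$block_sizes > cfg$n_variants)) stop("infeasible block sizes")
  with_seed(substream_seed(cfg$seed, 1L), {
    maf <- numeric(cfg$n_variants)
    dosage <- matrix(0L, cfg$n_samples, cfg$n_variants)
    off <- 0L
    for (b in seq_along(cfg$block_sizes)) {
      m <- cfg$block_sizes[b]
      cols <- off + seq_len(m)
      maf[cols] <- .block_mafs(m, cfg$maf_range)
      h1 <- .markov_haplotypes(cfg$n_samples, maf[cols], cfg$rho)
      h2 <- .markov_haplotypes(cfg$n_samples, maf[cols], cfg$rho)
      dosage[, cols] <- h1 + h2
      off <- off + m
    }
    pos <- integer(cfg$n_variants)
    off <- 0L
    base <- 1e6
    for (b in seq_along(cfg$block_sizes)) {
      m <- cfg$block_sizes[b]
      pos[off + seq_len(m)] <- as.integer(base + seq_len(m) * cfg$pos_step)
      base <- base + m * cfg$pos_step + 2e6
      off <- off + m
    }
    variants <- data.frame(chrom = "1", pos = pos, a1 = "A", a2 = "G",
                           maf = maf, block = rep(seq_along(cfg$block_sizes),
                                                  cfg$block_sizes),
                           stringsAsFactors = FALSE)
    genotype_panel(dosage, variants)
  })
}

#' Simulate an additive polygenic phenotype
#'
#' Builds `y = sum_c beta_c g_c + e`, with the environmental variance set
#' from the realized genetic variance so that the realized heritability
#' matches `h2`, then standardizes `y` to zero mean and unit variance.
#' The standardization scale is returned as an attribute so that true
#' joint effects on the analysis scale are `causal_betas / scale`.
#'
#' @param panel a [genotype_panel()].
#' @param causal_index,causal_betas causal variant columns and their
#'   per-allele effects (raw scale).
#' @param h2 target heritability; with a nonempty causal set, `h2 = 0` is
#'   refused (effects kept, a warning is issued and `h2` recomputed from a
#'   unit-variance noise term instead).
#' @param seed integer seed for the noise draw.
#' @return numeric phenotype vector with attributes `scale` (the sd the
#'   raw phenotype was divided by) and `h2_realized`.
#' @export
simulate_phenotype <- function(panel, causal_index, causal_betas, h2, seed) {
  stopifnot(length(causal_index) == length(causal_betas))
  n <- nrow(panel$dosage)
  g <- if (length(causal_index) > 0) {
    as.vector(panel$dosage[, causal_index, drop = FALSE] %*% causal_betas)
  } else {
    rep(0, n)
  }
  var_g <- stats::var(g)
  if (length(causal_index) > 0 && h2 <= 0) {
    warning("h2 = 0 with a nonempty causal set: effects kept, noise variance ",
            "set to 1 and h2 recomputed")
    var_e <- 1
  } else if (var_g == 0) {
    var_e <- 1
  } else {
    var_e <- var_g * (1 - h2) / h2
  }
  y <- with_seed(seed, g + stats::rnorm(n, sd = sqrt(var_e)))
  sc <- stats::sd(y)
  y <- (y - mean(y)) / sc
  attr(y, "scale") <- sc
  attr(y, "h2_realized") <- var_g / (var_g + var_e)
  y
}

#' Marginal per-variant association scan
#'
#' Simple linear regression of the phenotype on each variant's dosage
#' (slope, standard error, two-sided t-test p-value), the per-variant
#' summary statistics that feed locus definition, conditional analysis and
#' fine-mapping.
#'
#' @param panel a [genotype_panel()].
#' @param y phenotype vector, one value per panel sample.
#' @param trait trait label for the output table.
#' @return a `sumstats` object with one row per panel variant; effect
#'   allele is the counted allele `a1`, `freq` its sample frequency.
#' @export
compute_marginal_sumstats <- function(panel, y, trait = "simulated") {
  g <- panel$dosage
  n <- nrow(g)
  if (length(y) != n) stop("phenotype length must equal the sample count")
  yc <- y - mean(y)
  gc_mean <- colMeans(g)
  sxy <- as.vector(crossprod(g, yc))          # = crossprod(gc, yc) since sum(yc)=0
  sxx <- colSums(g^2) - n * gc_mean^2
  syy <- sum(yc^2)
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 0)
  s2 <- rss / (n - 2)
  se <- sqrt(s2 / sxx)
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pval <- pmax(pval, .Machine$double.xmin)    # keep within (0, 1]
  df <- data.frame(chrom = panel$variants$chrom, pos = panel$variants$pos,
                   a1 = panel$variants$a1, a2 = panel$variants$a2,
                   freq = gc_mean / 2, beta = beta, se = se, pval = pval,
                   n = n, stringsAsFactors = FALSE)
  sumstats(df, trait = trait, validate = FALSE)
}

#' Simulate a GWAS (panel, phenotype, marginal scan) in one call
#'
#' Convenience wrapper chaining [simulate_panel()],
#' [simulate_phenotype()] and [compute_marginal_sumstats()], returning the
#' components plus the ground truth on the analysis (standardized) scale.
#'
#' @param cfg a [sim_config()].
#' @return list with `panel`, `y`, `sumstats`, and `truth` (causal
#'   indices/ids, true joint betas on the standardized scale, realized h2).
#' @export
simulate_gwas <- function(cfg) {
  panel <- simulate_panel(cfg)
  y <- simulate_phenotype(panel, cfg$causal_index, cfg$causal_betas,
                          cfg$h2, seed = substream_seed(cfg$seed, 2L))
  ss <- compute_marginal_sumstats(panel, y)
  truth <- list(causal_index = cfg$causal_index,
                causal_ids = variant_ids(panel$variants)[cfg$causal_index],
                joint_betas = cfg$causal_betas / attr(y, "scale"),
                h2_realized = attr(y, "h2_realized"),
                seed = cfg$seed)
  list(panel = panel, y = y, sumstats = ss, truth = truth)
}

#' Simulate a colocalization trait pair
#'
#' Generates two traits measured in two independent cohorts drawn from the
#' same LD structure (one AR(1) block).  With `shared = TRUE` both traits
#' are driven by the same causal variant; with `shared = FALSE` each trait
#' has its own causal variant, with realized `r^2` between the two causals
#' below `max_r2` (re-drawn among eligible pairs; fatal if no eligible pair
#' exists).
#'
#' @param cfg a [sim_config()] describing one block (its causal fields are
#'   ignored; the pair's causal model is set here).
#' @param shared logical: one shared causal variant, or two distinct ones.
#' @param beta raw per-allele effect size at the causal variant(s)
#'   (trait 2 uses `beta2_sign` times it).
#' @param beta2_sign +1 or -1; sign of trait 2's effect relative to trait 1.
#' @param max_r2 upper bound on realized r^2 between distinct causal
#'   variants (default 0.3).
#' @param seed master seed (defaults to `cfg$seed`).
#' @return list with `t1`, `t2` (`sumstats`), `panel` (trait 1's cohort
#'   panel, usable as an LD reference), and `truth` (`causal1`, `causal2`
#'   column indices and ids, `shared` flag).
#' @export
simulate_trait_pair <- function(cfg, shared = TRUE, beta = 0.15,
                                beta2_sign = 1, max_r2 = 0.3,
                                seed = cfg$seed) {
  if (length(cfg$block_sizes) != 1L) {
    stop("trait pairs are simulated on a single LD block")
  }
  b <- beta
  cfg1 <- sim_config(cfg$n_samples, cfg$block_sizes, cfg$rho, cfg$maf_range,
                     h2 = cfg$h2, pos_step = cfg$pos_step,
                     seed = substream_seed(seed, 11L))
  cfg2 <- sim_config(cfg$n_samples, cfg$block_sizes, cfg$rho, cfg$maf_range,
                     h2 = cfg$h2, pos_step = cfg$pos_step,
                     seed = substream_seed(seed, 12L))
  panel1 <- simulate_panel(cfg1)
  panel2 <- simulate_panel(cfg2)
  panel2$variants <- panel1$variants
  colnames(panel2$dosage) <- colnames(panel1$dosage)

  m <- cfg$n_variants
  with_seed(substream_seed(seed, 13L), {
    c1 <- sample(seq(m %/% 4, 3 * m %/% 4), 1L)
    if (shared) {
      c2 <- c1
    } else {
      r <- as.vector(stats::cor(panel1$dosage[, c1], panel1$dosage))
      eligible <- which(r^2 < max_r2 & seq_len(m) != c1)
      if (length(eligible) == 0L) {
        stop("cannot place a distinct causal variant under the r^2 constraint")
      }
      c2 <- sample(eligible, 1L)
    }
  })
  y1 <- simulate_phenotype(panel1, c1, b, cfg$h2,
                           seed = substream_seed(seed, 14L))
  y2 <- simulate_phenotype(panel2, c2, beta2_sign * b, cfg$h2,
                           seed = substream_seed(seed, 15L))
  t1 <- compute_marginal_sumstats(panel1, y1, trait = "trait1")
  t2 <- compute_marginal_sumstats(panel2, y2, trait = "trait2")
  list(t1 = t1, t2 = t2, panel = panel1,
       truth = list(causal1 = c1, causal2 = c2,
                    causal1_id = variant_ids(panel1$variants)[c1],
                    causal2_id = variant_ids(panel1$variants)[c2],
                    shared = shared))
}

#' Configuration for a two-sample Mendelian randomization scenario
#'
#' @param n_instruments number of mutually independent instruments.
#' @param beta_exp_mean,beta_exp_sd distribution of true instrument effects
#'   on the exposure (absolute values are used so instruments are
#'   exposure-increasing on average).  The default spread matters: the
#'   MR-Egger intercept is identified by variation in instrument strength,
#'   so near-equal instrument effects leave directional pleiotropy
#'   undetectable.
#' @param theta true causal effect of the exposure on the outcome.
#' @param pleiotropy `"none"`, `"balanced"` (zero-mean direct effects) or
#'   `"directional"` (positive-mean direct effects).
#' @param pleiotropy_sd,pleiotropy_mean magnitude of the direct instrument
#'   to outcome effects (`pleiotropy_mean` applies to the directional mode).
#' @param prop_invalid fraction of instruments carrying pleiotropic
#'   effects (default 1: all, for the balanced/directional modes).
#' @param n_exposure,n_outcome sample sizes of the two (non-overlapping)
#'   studies, which set the estimation-noise scale.
#' @param seed master seed.
#' @return a validated `mr_config` list.
#' @export
mr_config <- function(n_instruments = 10, beta_exp_mean = 0.2,
                      beta_exp_sd = 0.1, theta = 0.2,
                      pleiotropy = c("none", "balanced", "directional"),
                      pleiotropy_sd = 0.01, pleiotropy_mean = 0.02,
                      prop_invalid = 1, n_exposure = 30000,
                      n_outcome = 30000, seed = 1) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(n_instruments >= 1, n_exposure > 1, n_outcome > 1,
            prop_invalid >= 0, prop_invalid <= 1)
  structure(list(n_instruments = as.integer(n_instruments),
                 beta_exp_mean = beta_exp_mean, beta_exp_sd = beta_exp_sd,
                 theta = theta, pleiotropy = pleiotropy,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 prop_invalid = prop_invalid,
                 n_exposure = as.integer(n_exposure),
                 n_outcome = as.integer(n_outcome),
                 seed = as.integer(seed)),
            class = "mr_config")
}

#' Simulate a two-sample Mendelian randomization scenario
#'
#' Instruments are mutually independent variants (2 Mb apart, so LD
#' pruning keeps them all).  True instrument effects on the exposure are
#' drawn once; the outcome effect of instrument *i* is
#' `theta * beta_exp_i + alpha_i`, where `alpha_i` is zero (no
#' pleiotropy), zero-mean (balanced) or positive-mean (directional) on the
#' configured fraction of invalid instruments.  Estimation noise is added
#' independently in the exposure and outcome studies (two-sample design),
#' with standard errors on the `1/sqrt(2 f (1-f) n)` scale of a
#' unit-variance phenotype.
#'
#' @param cfg an [mr_config()].
#' @return list with `exposure`, `outcome` (`sumstats` over the same
#'   instruments), `ld` (identity [compute_ld()]-style matrix), and
#'   `truth` (`theta`, per-instrument `alpha`, true `beta_exp`).
#' @export
simulate_mr_scenario <- function(cfg) {
  k <- cfg$n_instruments
  with_seed(substream_seed(cfg$seed, 21L), {
    f <- stats::runif(k, 0.1, 0.5)
    beta_exp <- abs(stats::rnorm(k, cfg$beta_exp_mean, cfg$beta_exp_sd))
    alpha <- rep(0, k)
    invalid <- seq_len(floor(cfg$prop_invalid * k))
    if (cfg$pleiotropy == "balanced" && length(invalid) > 0) {
      alpha[invalid] <- stats::rnorm(length(invalid), 0, cfg$pleiotropy_sd)
    } else if (cfg$pleiotropy == "directional" && length(invalid) > 0) {
      alpha[invalid] <- stats::rnorm(length(invalid), cfg$pleiotropy_mean,
                                     cfg$pleiotropy_sd)
    }
    se_exp <- 1 / sqrt(2 * f * (1 - f) * cfg$n_exposure)
    se_out <- 1 / sqrt(2 * f * (1 - f) * cfg$n_outcome)
    bx <- stats::rnorm(k, beta_exp, se_exp)
    by <- stats::rnorm(k, cfg$theta * beta_exp + alpha, se_out)
    pos <- as.integer(seq_len(k) * 2e6)
    mk <- function(b, se, n, trait) {
      sumstats(data.frame(chrom = "2", pos = pos, a1 = "A", a2 = "G",
                          freq = f, beta = b, se = se,
                          pval = pmax(2 * stats::pnorm(-abs(b / se)),
                                      .Machine$double.xmin),
                          n = n, stringsAsFactors = FALSE),
               trait = trait, validate = FALSE)
    }
    exposure <- mk(bx, se_exp, cfg$n_exposure, "exposure")
    outcome <- mk(by, se_out, cfg$n_outcome, "outcome")
    ld <- diag(1, k)
    dimnames(ld) <- list(variant_ids(exposure), variant_ids(exposure))
    class(ld) <- c("ld_matrix", "matrix")
    list(exposure = exposure, outcome = outcome, ld = ld,
         truth = list(theta = cfg$theta, alpha = alpha, beta_exp = beta_exp))
  })
}

#' Simulate a spine flow-score cohort with known diagnosis model
#'
#' Emulates the imaging cohort consumed by the prevalence projection: ages
#' in \[45, 85\], both sexes, 14 intervertebral-junction scores in
#' {0, 1, 2, 3} with an age- and sex-dependent ordinal model (severity
#' rises with age and is higher in men), and a known logistic
#' P(diagnosis | aggregate score) used to draw expert labels.
#'
#' @param n cohort size.
#' @param curve named vector `c(intercept, slope)` of the true logistic
#'   diagnosis model on the aggregate score.
#' @param seed integer seed.
#' @return list with `cohort` (data frame: `id`, `sex`, `age`, `j1..j14`,
#'   `score`), `labels` (validation subset with expert `dish` label), and
#'   `truth` (the generating curve).
#' @export
simulate_spine_cohort <- function(n = 2000, curve = c(intercept = -6, slope = 0.5),
                                  seed = 1) {
  with_seed(substream_seed(seed, 31L), {
    age <- stats::runif(n, 45, 85)
    sex <- sample(c("M", "F"), n, replace = TRUE)
    frailty <- stats::rnorm(n, 0, 0.8)
    # per-junction ordinal severity via a thresholded latent intensity
    lin <- -2.2 + 0.045 * (age - 45) + 0.7 * (sex == "M") + frailty
    scores <- matrix(0L, n, 14L)
    for (j in 1:14) {
      z <- lin + stats::rnorm(n, 0, 1.2)
      scores[, j] <- pmin(3L, pmax(0L, as.integer(floor(z))))
    }
    colnames(scores) <- paste0("j", 1:14)
    score <- rowSums(scores)
    cohort <- data.frame(id = seq_len(n), sex = sex, age = age, scores,
                         score = score, stringsAsFactors = FALSE)
    p <- stats::plogis(curve[["intercept"]] + curve[["slope"]] * score)
    labels <- cohort[, c("id", "score")]
    labels$dish <- stats::rbinom(n, 1, p)
    list(cohort = cohort, labels = labels, truth = list(curve = curve))
  })
}
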