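test_that("sigma is recovered from constructed and simulated statistics", {
  expect_equal(estimate_sigma(sigma_construction(1)), 1, tolerance = 1e-3)
  expect_equal(estimate_sigma(sigma_construction(2)), 2, tolerance = 2e-3)

  g <- simulate_gwas(sim_config(n_samples = 5000, block_sizes = 500,
                                rho = 0.3, h2 = 0, seed = 4))
  s <- estimate_sigma(g$sumstats)
  expect_gt(s, 0.95); expect_lt(s, 1.05)

  expect_error(estimate_sigma(toy_sumstats()), "at least 10")
})

test_that("log-ABF closed form matches trivial cases and quadrature", {
  expect_equal(log_abf(0.3, 0.01, 0), 0)
  expect_equal(log_abf(0, 0.01, 0.0009), 0.5 * log(0.01 / 0.0109))
  expect_error(log_abf(0.1, -1, 0.01), "positive")

  quad_labf <- function(beta, V, omega) {
    if (omega == 0) return(0)
    # the integrand is a sharp Gaussian spike at the posterior mean;
    # integrate over mean +/- 15 posterior sds to keep quadrature honest
    pm <- beta * omega / (V + omega)
    psd <- sqrt(V * omega / (V + omega))
    num <- stats::integrate(function(b)
      stats::dnorm(beta, b, sqrt(V)) * stats::dnorm(b, 0, sqrt(omega)),
      pm - 15 * psd, pm + 15 * psd, rel.tol = 1e-12)$value
    log(num) - stats::dnorm(beta, 0, sqrt(V), log = TRUE)
  }
  set.seed(5)
  for (i in 1:25) {
    beta <- runif(1, -0.5, 0.5)
    V <- runif(1, 1e-4, 1e-2)
    omega <- sample(c(0, 9e-4, 0.0225), 1)
    expect_equal(log_abf(beta, V, omega), quad_labf(beta, V, omega),
                 tolerance = 1e-8)
  }
})

test_that("log-ABF grows with evidence strength", {
  b <- seq(0, 1, by = 0.05)
  lam <- log_abf(b, 0.01, 0.0225)
  expect_true(all(diff(lam) > 0))
  expect_true(all(diff(log_abf(-b, 0.01, 0.0225)) > 0))
})

test_that("posteriors include the null and normalize, flat case closed form", {
  flat <- posteriors(rep(0, 10), finemap_config(gamma = 0.05))
  expect_equal(flat$pi, rep(0.095, 10), tolerance = 1e-12)
  expect_equal(flat$pi0, 0.05, tolerance = 1e-12)

  dominant <- posteriors(c(700, 0, 0), finemap_config())
  expect_gt(dominant$pi[1], 1 - 1e-10)

  set.seed(6)
  for (i in 1:20) {
    lam <- rnorm(50, 0, sample(c(1, 100, 400), 1))
    p <- posteriors(lam, finemap_config())
    expect_equal(p$pi0 + sum(p$pi), 1, tolerance = 1e-10)
    expect_true(all(p$pi >= 0))
    if (max(lam) < 600) {
      # direct (non-log-space) oracle
      abf <- exp(lam)
      denom <- 0.05 + 0.95 / 50 * sum(abf)
      expect_equal(p$pi, 0.95 / 50 * abf / denom, tolerance = 1e-10)
    }
  }
})

test_that("credible sets accumulate ranked mass and respect the threshold", {
  post <- list(pi = c(0.6, 0.3, 0.07, 0.03) * 0.95,
               pi0 = 0.05, lambdas = log(c(0.6, 0.3, 0.07, 0.03)), l = 4,
               gamma = 0.05)
  cs <- credible_set(post, finemap_config(credible_mass = 0.9))
  expect_equal(cs$id, c("1", "2"))
  expect_equal(cs$cum_mass[2], 0.9, tolerance = 1e-12)

  unif <- posteriors(rep(0, 200), finemap_config())
  cs2 <- credible_set(unif, finemap_config(credible_mass = 0.99))
  expect_equal(nrow(cs2), 198)

  # removing the last member drops below the threshold
  expect_lt(cs2$cum_mass[nrow(cs2) - 1], 0.99)
})

test_that("single-signal finemapping is conditioning-invariant and nested", {
  g <- simulate_gwas(sim_config(n_samples = 4000, block_sizes = 100,
                                rho = 0.8, causal_index = 50L,
                                causal_betas = 0.25, h2 = 0.015, seed = 12))
  loci <- define_loci(g$sumstats)
  lss <- locus_variants(g$sumstats, loci[1, ])
  fm <- finemap_signal(lss, cfg = finemap_config())
  expect_identical(fm$marginal, fm$conditional)
  expect_equal(fm$omega, (0.15 * fm$sigma)^2)

  # potential causal variants (pi > 1%) are inside the credible set
  tab <- fm$marginal$table
  expect_true(all(tab$id[tab$potential_causal] %in%
                    fm$marginal$credible_set$id))
  expect_true(g$truth$causal_ids %in% fm$marginal$credible_set$id)
})

test_that("stronger evidence shrinks the credible set", {
  g <- simulate_gwas(sim_config(n_samples = 4000, block_sizes = 100,
                                rho = 0.8, causal_index = 50L,
                                causal_betas = 0.25, h2 = 0.01, seed = 13))
  loci <- define_loci(g$sumstats, p_threshold = 1e-4)
  lss <- locus_variants(g$sumstats, loci[1, ])
  fm1 <- finemap_signal(lss, cfg = finemap_config())
  boosted <- as.data.frame(lss)
  boosted$beta <- boosted$beta * 2
  fm2 <- finemap_signal(sumstats(boosted, validate = FALSE), sigma = fm1$sigma,
                        cfg = finemap_config())
  expect_lte(nrow(fm2$marginal$credible_set), nrow(fm1$marginal$credible_set))
})

test_that("two-signal loci are isolated by conditional finemapping", {
  fx_seed <- 31
  g <- simulate_gwas(sim_config(n_samples = 4000, block_sizes = 80, rho = 0.8,
                                causal_index = c(15L, 65L),
                                causal_betas = c(0.3, 0.3), h2 = 0.04,
                                seed = fx_seed))
  ld <- compute_ld(g$panel)
  vx <- apply(g$panel$dosage, 2, stats::var)
  loci <- define_loci(g$sumstats)
  sig <- stepwise_selection(loci[1, ], g$sumstats, ld, sigma2 = 1, var_x = vx)
  expect_equal(nrow(sig), 2)
  lss <- locus_variants(g$sumstats, loci[1, ])
  for (j in 1:2) {
    fm <- finemap_signal(lss, ld, conditioning = sig$conditioned_on[[j]],
                         sigma = 1, var_x = vx)
    near <- abs(match(sig$id[j], variant_ids(lss)) -
                  match(fm$conditional$credible_set$id, variant_ids(lss)))
    expect_true(any(near <= 10))   # the set concentrates around its signal
  }
})
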