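test_that("instrument selection keeps independent hits and prunes by LD", {
  ss <- sumstats(data.frame(
    chrom = "1", pos = c(1e6, 1.1e6, 5e6, 9e6), a1 = "A", a2 = "G",
    freq = 0.3, beta = 0.1, se = 0.01,
    pval = c(1e-12, 1e-9, 1e-10, 0.5), n = 10000))
  ids <- variant_ids(ss)
  ld <- diag(4); dimnames(ld) <- list(ids, ids)
  ld["1:1000000", "1:1100000"] <- ld["1:1100000", "1:1000000"] <- sqrt(0.5)
  sel <- select_instruments(ss, ld)
  # the r^2 = 0.5 pair 100 kb apart collapses to the smaller-p variant
  expect_equal(sort(sel), c("1:1000000", "1:5000000"))

  # mutually uncorrelated significant variants are all kept
  ld0 <- diag(4); dimnames(ld0) <- list(ids, ids)
  expect_equal(sort(select_instruments(ss, ld0)),
               c("1:1000000", "1:1100000", "1:5000000"))

  expect_warning(sel0 <- select_instruments(
    sumstats(as.data.frame(ss)[4, , drop = FALSE], validate = FALSE), ld),
    "no variant")
  expect_length(sel0, 0)
})

test_that("Wald ratio follows the closed form", {
  i1 <- data.frame(id = "v", beta_exp = 0.1, se_exp = 0.01, beta_out = 0.05,
                   se_out = 0.01)
  est <- wald_ratio(i1)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)
  i2 <- i1; i2$beta_out <- 0
  expect_equal(wald_ratio(i2)$beta, 0)
})

test_that("IVW equals the weighted-least-squares closed form", {
  set.seed(41)
  instr <- data.frame(id = paste0("v", 1:8),
                      beta_exp = runif(8, 0.05, 0.3), se_exp = 0.01,
                      beta_out = rnorm(8, 0.05, 0.02),
                      se_out = runif(8, 0.01, 0.05))
  est <- mr_ivw(instr)
  wls <- stats::lm(beta_out ~ 0 + beta_exp, data = instr,
                   weights = 1 / instr$se_out^2)
  expect_equal(est$beta, unname(coef(wls)), tolerance = 1e-10)

  # duplicating a single ratio k times keeps beta, scales se by 1/sqrt(k)
  one <- instr[1, ]
  four <- instr[rep(1, 4), ]
  expect_equal(mr_ivw(four)$beta, wald_ratio(one)$beta, tolerance = 1e-12)
  expect_equal(mr_ivw(four)$se, wald_ratio(one)$se / 2, tolerance = 1e-12)

  expect_error(mr_ivw(one), "at least 2")
})

test_that("Egger regression recovers an exact linear pleiotropy model", {
  instr <- exact_instruments(k = 6, intercept = 0.04, slope = 0.25)
  est <- mr_egger(instr)
  expect_equal(est$beta, 0.25, tolerance = 1e-10)
  expect_equal(est$egger_intercept, 0.04, tolerance = 1e-10)
  expect_error(mr_egger(instr[1:2, ]), "at least 3")
})

test_that("weighted median interpolates percentiles correctly", {
  # equal weights, odd count: the middle ratio
  instr <- data.frame(id = paste0("v", 1:5), beta_exp = 1, se_exp = 0.01,
                      beta_out = c(0.1, 0.3, 0.2, 0.5, 0.4), se_out = 1)
  est <- mr_weighted_median(instr, n_boot = 50, seed = 1)
  expect_equal(est$beta, 0.3)

  # a dominant weight pins the estimate at (or next to) its ratio
  instr2 <- data.frame(id = paste0("v", 1:3), beta_exp = 1, se_exp = 0.01,
                       beta_out = c(0.2, 0.8, 1.4),
                       se_out = c(0.01, 1, 1) / sqrt(c(98, 1, 1)))
  est2 <- mr_weighted_median(instr2, n_boot = 50, seed = 1)
  expect_equal(est2$beta, 0.2, tolerance = 0.05)
  expect_error(mr_weighted_median(instr2[1:2, ]), "at least 3")
})

test_that("weighted mode tracks the majority cluster and its limits", {
  instr <- data.frame(id = paste0("v", 1:5), beta_exp = 1, se_exp = 0.01,
                      beta_out = rep(0.25, 5), se_out = 0.02)
  expect_equal(mr_weighted_mode(instr, n_boot = 20, seed = 1)$beta, 0.25,
               tolerance = 1e-9)

  # majority cluster with outliers
  instr2 <- data.frame(id = paste0("v", 1:7), beta_exp = 1, se_exp = 0.01,
                       beta_out = c(0.2, 0.21, 0.19, 0.2, 0.22, 0.9, -0.5),
                       se_out = 0.02)
  est2 <- mr_weighted_mode(instr2, n_boot = 20, seed = 1)
  expect_lt(abs(est2$beta - 0.2), 0.05)

  # bandwidth -> infinity approaches the weighted mean
  est3 <- mr_weighted_mode(instr2, bw_factor = 2000, n_boot = 20, seed = 1)
  w <- instr2$beta_exp^2 / instr2$se_out^2
  wmean <- sum(w * instr2$beta_out / instr2$beta_exp) / sum(w)
  expect_equal(est3$beta, wmean, tolerance = 0.02)
})

test_that("estimators are equivariant to exposure rescaling and allele flips", {
  set.seed(43)
  instr <- data.frame(id = paste0("v", 1:6),
                      beta_exp = runif(6, 0.1, 0.4), se_exp = 0.02,
                      beta_out = rnorm(6, 0.08, 0.03), se_out = 0.03)
  for (fn in list(mr_ivw, mr_egger,
                  function(x) mr_weighted_median(x, n_boot = 20, seed = 2),
                  function(x) mr_weighted_mode(x, n_boot = 20, seed = 2))) {
    base <- fn(instr)
    scaled <- instr; scaled$beta_exp <- 2 * scaled$beta_exp
    scaled$se_exp <- 2 * scaled$se_exp
    expect_equal(fn(scaled)$beta, base$beta / 2, tolerance = 1e-6)
  }

  # flipping an instrument's allele coding leaves estimates unchanged once
  # re-aligned to the exposure-increasing allele
  mk_ss <- function(b, se, flip_first = FALSE) {
    df <- data.frame(chrom = "1", pos = (1:6) * 1e6,
                     a1 = "A", a2 = "G", freq = 0.3, beta = b, se = se,
                     pval = pmax(2 * pnorm(-abs(b / se)), 1e-300), n = 1e4)
    if (flip_first) {
      df$a1[1] <- "G"; df$a2[1] <- "A"
      df$beta[1] <- -df$beta[1]; df$freq[1] <- 0.7
    }
    sumstats(df, validate = FALSE)
  }
  exp1 <- mk_ss(instr$beta_exp, instr$se_exp)
  out1 <- mk_ss(instr$beta_out, instr$se_out)
  exp2 <- mk_ss(instr$beta_exp, instr$se_exp, flip_first = TRUE)
  h1 <- harmonize_alleles(exp1, out1)
  h2 <- harmonize_alleles(exp2, out1)
  i1 <- instruments(h1$a, h1$b)
  i2 <- instruments(h2$a, h2$b)
  expect_equal(mr_ivw(i2)$beta, mr_ivw(i1)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(i2)$beta, mr_egger(i1)$beta, tolerance = 1e-12)
})

test_that("the gene screen dispatches Wald vs IVW and adjusts across genes", {
  sc1 <- simulate_mr_scenario(mr_config(n_instruments = 8, theta = 0.3,
                                        seed = 51))
  sc2 <- simulate_mr_scenario(mr_config(n_instruments = 1, theta = 0.3,
                                        seed = 52))
  sc3 <- simulate_mr_scenario(mr_config(n_instruments = 8, theta = 0,
                                        seed = 53))
  res <- suppressWarnings(mr_pipeline(
    list(geneA = sc1$exposure, geneB = sc2$exposure, geneC = sc3$exposure),
    sc1$outcome, list(geneA = sc1$ld, geneB = sc2$ld, geneC = sc3$ld),
    n_boot = 50, seed = 3))
  expect_equal(res$method[res$gene == "geneB" & res$primary], "wald")
  expect_equal(res$method[res$gene == "geneA" & res$primary], "ivw")
  # sensitivity estimators present for the multi-instrument genes
  expect_setequal(res$method[res$gene == "geneA"],
                  c("ivw", "egger", "weighted_median", "weighted_mode"))
  prim <- res[res$primary, ]
  expect_true(all(!is.na(prim$p_adj_bh)))
  expect_true(all(prim$p_adj_bh >= prim$pval - 1e-15))
})
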