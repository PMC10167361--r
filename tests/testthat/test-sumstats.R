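test_that("canonical read/write round trip is lossless and sorted", {
  ss <- toy_sumstats()
  expect_equal(ss$pos, c(100, 200, 300, 200, 500))  # sorted by (chrom, pos)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, path)
  back <- suppressMessages(read_sumstats(path))
  expect_equal(as.data.frame(back), as.data.frame(ss))
})

test_that("COJO .ma dialect parses equivalently to the canonical header", {
  ss <- toy_sumstats()
  path <- withr::local_tempfile(fileext = ".ma")
  ma <- data.frame(SNP = variant_ids(ss), A1 = ss$a1, A2 = ss$a2,
                   freq = ss$freq, b = ss$beta, se = ss$se, p = ss$pval,
                   N = ss$n)
  utils::write.table(ma, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- suppressMessages(read_sumstats(path, dialect = "cojo"))
  expect_equal(back$beta, ss$beta)
  expect_equal(back$freq, ss$freq)
  expect_equal(variant_ids(back), variant_ids(ss))
})

test_that("invariant-violating rows are rejected, missing columns fatal", {
  df <- as.data.frame(toy_sumstats())
  df$se[2] <- 0
  expect_warning(ss <- sumstats(df), "invariant")
  expect_equal(nrow(ss), 4)

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("CHR\tPOS\tA1\tA2\tFREQ\tBETA", "1\t1\tA\tG\t0.2\t0.1"), path)
  expect_error(read_sumstats(path), "required column")

  # non-numeric field rejected row-wise with the file line reported
  df2 <- as.data.frame(toy_sumstats())
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(toy_sumstats(), p2)
  lines <- readLines(p2)
  lines[3] <- sub("^([^\t]*\t[^\t]*\t[^\t]*\t[^\t]*\t)[^\t]*", "\\1oops", lines[3])
  writeLines(lines, p2)
  expect_warning(back <- suppressMessages(read_sumstats(p2)), "non-numeric")
  expect_equal(nrow(back), nrow(df2) - 1)
})

test_that("allele harmonization polarizes, drops ambiguous, and is idempotent", {
  a <- sumstats(data.frame(
    chrom = "1", pos = c(100, 200, 300, 400),
    a1 = c("A", "C", "A", "C"), a2 = c("G", "T", "T", "A"),
    freq = c(0.3, 0.2, 0.45, 0.25), beta = c(0.1, -0.2, 0.3, 0.15),
    se = 0.05, pval = 0.01, n = 1000))
  b_df <- as.data.frame(a)
  # swap alleles at pos 200: harmonization must flip beta and freq
  b_df$a1[2] <- "T"; b_df$a2[2] <- "C"
  b_df$beta[2] <- -b_df$beta[2]; b_df$freq[2] <- 1 - b_df$freq[2]
  # pos 400: unmatched allele pair
  b_df$a1[4] <- "C"; b_df$a2[4] <- "G"
  b <- sumstats(b_df, trait = "b")

  expect_warning(h <- suppressMessages(harmonize_alleles(a, b)), "unmatched")
  # pos 300 is A/T with MAF 0.45 > 0.4: strand-ambiguous, dropped
  expect_equal(h$a$pos, c(100, 200))
  expect_equal(h$b$beta, a$beta[1:2])   # flipped back to a's orientation
  expect_equal(h$b$freq, a$freq[1:2])
  expect_equal(h$b$a1, h$a$a1)

  # idempotence: harmonizing the harmonized pair changes nothing
  h2 <- harmonize_alleles(h$a, h$b)
  expect_equal(as.data.frame(h2$b), as.data.frame(h$b))

  # identical orientation: betas unchanged
  hh <- harmonize_alleles(a, a)
  expect_equal(hh$b$beta, hh$a$beta)

  expect_error(harmonize_alleles(a, sumstats(data.frame(
    chrom = "9", pos = 1, a1 = "A", a2 = "G", freq = 0.5, beta = 0, se = 1,
    pval = 1, n = 10))), "no shared variants")
})

test_that("exact HWE test agrees with a direct enumeration oracle", {
  # oracle: enumerate heterozygote counts, conditional multinomial probs
  oracle <- function(naa, nab, nbb) {
    n <- naa + nab + nbb
    na <- 2 * naa + nab
    hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
    probs <- vapply(hets, function(h) {
      n11 <- (na - h) / 2
      n22 <- n - n11 - h
      exp(lfactorial(n) - lfactorial(n11) - lfactorial(h) - lfactorial(n22) +
            h * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
            lfactorial(2 * n))
    }, numeric(1))
    sum(probs[probs <= probs[match(nab, hets)] + 1e-14])
  }
  cases <- list(c(20, 10, 5), c(50, 20, 30), c(5, 40, 5), c(88, 10, 2))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 oracle(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  }
  # equilibrium counts: p should be large
  expect_gt(hwe_exact_test(2500, 5000, 2500), 0.5)
})

test_that("QC excludes one variant per violated rule with exact accounting", {
  n_panel <- 400
  mk_hwp <- function(f) stats::rbinom(n_panel, 2, f)
  set.seed(42)
  dos <- cbind(mk_hwp(0.3), mk_hwp(0.25), mk_hwp(0.4),
               rep(1, n_panel),          # all heterozygous: extreme HWE violation
               mk_hwp(0.35), mk_hwp(0.2))
  vars <- data.frame(chrom = "1", pos = (1:6) * 1000, a1 = "A", a2 = "G")
  panel <- genotype_panel(dos, vars)
  ss <- sumstats(data.frame(
    chrom = "1", pos = (1:6) * 1000, a1 = "A", a2 = "G",
    freq = c(0.005, 0.25, 0.4, 0.5, 0.35, 0.2),   # variant 1 fails MAF
    beta = 0.01, se = 0.02, pval = 0.5, n = 1000,
    info = c(1, 0.5, 1, 1, 1, 0.95),               # variant 2 fails info
    miss = c(0, 0, 0.2, 0.01, 0.05, 0)))           # variant 3 fails missingness
  out <- qc_filter(ss, panel)
  expect_equal(unname(attr(out, "exclusions")), c(1, 1, 1, 1))
  expect_equal(nrow(out), 2)
  expect_equal(sum(attr(out, "exclusions")) + nrow(out), nrow(ss))

  # all-clean table passes unchanged
  clean <- ss[5:6, , drop = FALSE]
  out2 <- qc_filter(sumstats(as.data.frame(clean)), panel)
  expect_equal(nrow(out2), 2)
  expect_equal(sum(attr(out2, "exclusions")), 0)

  # panel drawn in Hardy-Weinberg proportions: no HWE exclusions at 1e-10
  set.seed(7)
  dos_hwp <- sapply(runif(40, 0.1, 0.5), mk_hwp)
  panel_hwp <- genotype_panel(dos_hwp, data.frame(chrom = "1",
                                                  pos = (1:40) * 100,
                                                  a1 = "A", a2 = "G"))
  ss_hwp <- sumstats(data.frame(chrom = "1", pos = (1:40) * 100, a1 = "A",
                                a2 = "G", freq = colMeans(dos_hwp) / 2,
                                beta = 0, se = 0.02, pval = 0.5, n = 400),
                     validate = FALSE)
  out3 <- suppressMessages(qc_filter(ss_hwp, panel_hwp))
  expect_equal(unname(attr(out3, "exclusions")["hwe"]), 0L)

  expect_error(qc_filter(sumstats(as.data.frame(ss)[1, , drop = FALSE],
                                  validate = FALSE)),
               "all variants removed")
})
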