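# Small programmatic fixtures shared across tests.

toy_sumstats <- function() {
  sumstats(data.frame(
    chrom = c("2", "1", "1", "2", "1"),
    pos = c(500, 100, 300, 200, 200),
    a1 = c("A", "C", "G", "T", "A"),
    a2 = c("G", "T", "A", "C", "G"),
    freq = c(0.10, 0.25, 0.40, 0.33, 0.45),
    beta = c(0.05, -0.02, 0.10, 0.00, -0.07),
    se = c(0.01, 0.02, 0.03, 0.015, 0.02),
    pval = c(1e-6, 0.32, 8e-4, 0.99, 4e-4),
    n = 1000, stringsAsFactors = FALSE))
}

# sumstats with exact Var(beta) = sigma0^2 / (2 n f (1-f)); recovers sigma0
sigma_construction <- function(sigma0 = 1, m = 60, n = 20000) {
  f <- seq(0.05, 0.45, length.out = m)
  se <- sigma0 / sqrt(2 * n * f * (1 - f))
  sumstats(data.frame(chrom = "1", pos = seq_len(m) * 1000, a1 = "A",
                      a2 = "G", freq = f, beta = 0.01, se = se, pval = 0.5,
                      n = n, stringsAsFactors = FALSE), validate = FALSE)
}

# independent-instrument table with exact linear relation beta_out = c + t*bx
exact_instruments <- function(k = 5, intercept = 0, slope = 0.3) {
  bx <- seq(0.1, 0.5, length.out = k)
  data.frame(id = paste0("v", seq_len(k)), beta_exp = bx, se_exp = 0.01,
             beta_out = intercept + slope * bx, se_out = 0.02,
             stringsAsFactors = FALSE)
}
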