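#' Summary-statistics tables
#'
#' A `sumstats` object is a validated, position-sorted data frame of
#' per-variant GWAS summary statistics with one row per variant and the
#' columns:
#'
#' * `chrom` — chromosome label (character),
#' * `pos` — 1-based position (GRCh37 convention throughout),
#' * `a1`, `a2` — effect and other allele (uppercase nucleotides),
#' * `freq` — effect-allele frequency, in (0, 1),
#' * `beta` — per-allele additive effect on the phenotype,
#' * `se` — standard error of `beta` (so the effect variance is `se^2`),
#' * `pval` — association p-value, in (0, 1],
#' * `n` — sample size,
#' * `info` — imputation quality in \[0, 1\] (optional, may be `NA`),
#' * `miss` — genotype missingness fraction (optional, may be `NA`).
#'
#' The trait label and genome build are carried as attributes.
#'
#' @param df data frame holding the columns above (`info`/`miss` optional).
#' @param trait trait label.
#' @param build genome build tag; coordinates are 1-based inclusive.
#' @param validate set `FALSE` to skip row validation (internal use when
#'   rows are known valid).
#' @return a `sumstats` object.
#' @export
sumstats <- function(df, trait = "trait", build = "GRCh37", validate = TRUE) {
  required <- c("chrom", "pos", "a1", "a2", "freq", "beta", "se", "pval", "n")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$info)) df$info <- NA_real_
  if (is.null(df$miss)) df$miss <- NA_real_
  df <- df[c(required, "info", "miss")]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$a1 <- toupper(as.character(df$a1))
  df$a2 <- toupper(as.character(df$a2))
  for (col in c("freq", "beta", "se", "pval", "n", "info", "miss")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (validate) {
    bad <- !is.finite(df$beta) | !is.finite(df$se) | df$se <= 0 |
      !is.finite(df$freq) | df$freq <= 0 | df$freq >= 1 |
      !is.finite(df$pval) | df$pval <= 0 | df$pval > 1 |
      !is.finite(df$n) | df$n <= 0 | df$a1 == df$a2
    if (any(bad)) {
      warning(sum(bad), " row(s) violate summary-statistic invariants; dropped ",
              "(rows: ", paste(utils::head(which(bad), 10L), collapse = ", "),
              if (sum(bad) > 10L) ", ..." else "", ")")
      df <- df[!bad, , drop = FALSE]
    }
  }
  key <- paste(df$chrom, df$pos, df$a1, df$a2)
  if (anyDuplicated(key)) {
    warning("duplicate (chrom, pos, allele pair) rows dropped")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, trait = trait, build = build,
            class = c("sumstats", "data.frame"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat("GWAS summary statistics: trait '", attr(x, "trait"), "', build ",
      attr(x, "build"), ", ", nrow(x), " variants\n", sep = "")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Variant identifiers
#'
#' `chrom:pos` identifiers used to index LD matrices and genotype panels.
#'
#' @param x a `sumstats` object or a data frame with `chrom` and `pos`.
#' @return character vector of identifiers.
#' @export
variant_ids <- function(x) paste(x$chrom, x$pos, sep = ":")

# Column dialects: map from canonical column name to the header name used in
# the file.  The COJO .ma dialect carries coordinates inside the SNP id.
.dialects <- list(
  canonical = c(chrom = "CHR", pos = "POS", a1 = "A1", a2 = "A2",
                freq = "FREQ", beta = "BETA", se = "SE", pval = "P",
                n = "N", info = "INFO", miss = "MISS"),
  cojo = c(snp = "SNP", a1 = "A1", a2 = "A2", freq = "freq",
           beta = "b", se = "se", pval = "p", n = "N")
)

#' Read GWAS summary statistics
#'
#' Reads a delimited text table of per-variant summary statistics.  The
#' canonical dialect is tab-separated with header
#' `CHR POS A1 A2 FREQ BETA SE P N [INFO] [MISS]`; the `"cojo"` dialect
#' accepts GCTA-COJO `.ma` headers (`SNP A1 A2 freq b se p N`) with
#' coordinates parsed from `chrom:pos` SNP identifiers.  A custom dialect is
#' a named character vector mapping canonical names (`chrom`, `pos`, `a1`,
#' `a2`, `freq`, `beta`, `se`, `pval`, `n`, optionally `info`, `miss`, or
#' `snp` in place of `chrom`/`pos`) to the file's column names.
#'
#' Rows with non-numeric or invariant-violating values are rejected with a
#' warning naming the offending line numbers; a missing required column is
#' fatal.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect `"canonical"`, `"cojo"`, or a named character map.
#' @param trait,build passed to [sumstats()].
#' @param sep field separator (default: any whitespace).
#' @return a `sumstats` object.
#' @export
read_sumstats <- function(path, dialect = "canonical", trait = "trait",
                          build = "GRCh37", sep = "") {
  if (is.character(dialect) && length(dialect) == 1L && is.null(names(dialect))) {
    dialect <- .dialects[[match.arg(dialect, names(.dialects))]]
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  absent <- setdiff(unname(dialect), names(raw))
  optional <- unname(dialect[names(dialect) %in% c("info", "miss")])
  fatal <- setdiff(absent, optional)
  if (length(fatal) > 0L) {
    stop("required column(s) not found in ", path, ": ",
         paste(fatal, collapse = ", "))
  }
  present <- dialect[dialect %in% names(raw)]
  df <- stats::setNames(raw[unname(present)], names(present))
  if (is.null(df$chrom) && !is.null(df$snp)) {
    parts <- strsplit(df$snp, ":", fixed = TRUE)
    ok <- lengths(parts) >= 2L
    if (!all(ok)) stop("SNP identifiers must be 'chrom:pos' to recover coordinates")
    df$chrom <- vapply(parts, `[[`, "", 1L)
    df$pos <- vapply(parts, `[[`, "", 2L)
  }
  df$snp <- NULL
  num_cols <- intersect(c("pos", "freq", "beta", "se", "pval", "n", "info", "miss"),
                        names(df))
  suppressWarnings(num <- lapply(df[num_cols], as.numeric))
  # a row is rejected when a REQUIRED numeric field fails to parse;
  # optional columns (info, miss) silently coerce unparseable entries to NA
  required_num <- setdiff(num_cols, c("info", "miss"))
  bad_line <- Reduce(`|`, lapply(num[required_num], is.na))
  df[num_cols] <- num
  if (any(bad_line)) {
    warning(sum(bad_line), " row(s) with non-numeric fields rejected (file lines: ",
            paste(utils::head(which(bad_line) + 1L, 10L), collapse = ", "), ")")
    df <- df[!bad_line, , drop = FALSE]
  }
  message("read_sumstats: ", nrow(df), " candidate row(s) from ", basename(path))
  sumstats(df, trait = trait, build = build)
}

#' Write GWAS summary statistics
#'
#' Writes the canonical tab-separated format
#' (`CHR POS A1 A2 FREQ BETA SE P N INFO MISS`); the read/write round trip
#' is lossless.
#'
#' @param x a `sumstats` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  out <- as.data.frame(x)
  names(out) <- .dialects$canonical[names(out)]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize allele polarization between two summary-statistics tables
#'
#' Pairs two tables on shared `(chrom, pos)` keys and polarizes the second
#' table's effects to the first table's effect allele: where the second
#' table's alleles are swapped relative to the first, its `beta` sign is
#' flipped and its frequency replaced by `1 - freq`.  Strand-ambiguous
#' (A/T, C/G) variants whose minor-allele frequency exceeds
#' `ambiguous_maf` are dropped, as the strand cannot be resolved from
#' frequency; variants whose allele pairs cannot be matched are dropped
#' with a warning.  The operation is idempotent.
#'
#' @param a,b `sumstats` objects on the same genome build.
#' @param ambiguous_maf drop palindromic variants with
#'   `min(freq, 1 - freq) > ambiguous_maf` (default 0.4).
#' @return list with components `a` and `b`: row-aligned `sumstats` on the
#'   shared, harmonized variants.
#' @export
harmonize_alleles <- function(a, b, ambiguous_maf = 0.4) {
  if (!identical(attr(a, "build"), attr(b, "build"))) {
    stop("tables are on different genome builds: ",
         attr(a, "build"), " vs ", attr(b, "build"))
  }
  ia <- variant_ids(a)
  ib <- variant_ids(b)
  shared <- intersect(ia, ib)
  if (length(shared) == 0L) stop("no shared variants between the two tables")
  a2 <- as.data.frame(a)[match(shared, ia), , drop = FALSE]
  b2 <- as.data.frame(b)[match(shared, ib), , drop = FALSE]

  same <- a2$a1 == b2$a1 & a2$a2 == b2$a2
  swapped <- a2$a1 == b2$a2 & a2$a2 == b2$a1
  mismatch <- !(same | swapped)
  if (any(mismatch)) {
    warning(sum(mismatch), " shared position(s) with unmatched allele pairs dropped")
  }
  b2$beta[swapped] <- -b2$beta[swapped]
  b2$freq[swapped] <- 1 - b2$freq[swapped]
  tmp <- b2$a1[swapped]
  b2$a1[swapped] <- b2$a2[swapped]
  b2$a2[swapped] <- tmp

  ambiguous <- .is_palindromic(a2$a1, a2$a2) &
    pmin(a2$freq, 1 - a2$freq) > ambiguous_maf
  if (any(ambiguous)) {
    message("harmonize_alleles: ", sum(ambiguous),
            " strand-ambiguous variant(s) with MAF > ", ambiguous_maf, " dropped")
  }
  keep <- !mismatch & !ambiguous
  if (!any(keep)) stop("no harmonizable shared variants remain")
  list(
    a = sumstats(a2[keep, , drop = FALSE], trait = attr(a, "trait"),
                 build = attr(a, "build"), validate = FALSE),
    b = sumstats(b2[keep, , drop = FALSE], trait = attr(b, "trait"),
                 build = attr(b, "build"), validate = FALSE)
  )
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on biallelic genotype counts, summing the
#' probabilities of all heterozygote configurations no more probable than
#' the observed one, conditional on the allele counts.
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom-ref, het, hom-alt).
#' @return exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  rare <- min(n_a, n_b)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log-probability of each possible heterozygote count given allele counts
  logp <- lgamma(n + 1) - lgamma((n_a - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((n_b - hets) / 2 + 1) + hets * log(2) +
    lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_ab, hets)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Variant quality control
#'
#' Removes variants failing any of the quality-control rules used for the
#' association analysis: minor allele frequency below `maf_min`, imputation
#' quality below `info_min`, genotype missingness above `miss_max`, or
#' exact Hardy-Weinberg p-value below `hwe_p_min`.  The Hardy-Weinberg test
#' requires hard genotype counts and is computed from `panel` (dosages
#' rounded to genotypes); without a panel, or for variants absent from it,
#' the rule is skipped.  Filters on `info`/`miss` are skipped (with a
#' notice) when the column is entirely missing.
#'
#' @param x a `sumstats` object.
#' @param panel optional [genotype_panel()] supplying genotypes for the
#'   Hardy-Weinberg exact test.
#' @param maf_min,info_min,miss_max,hwe_p_min rule thresholds.
#' @return the filtered `sumstats`, with an `exclusions` attribute giving
#'   per-rule exclusion counts; a variant failing several rules is counted
#'   once, under the first rule it fails (order: maf, info, miss, hwe), so
#'   that the counts plus the survivors sum to the input size.
#' @export
qc_filter <- function(x, panel = NULL, maf_min = 0.01, info_min = 0.9,
                      miss_max = 0.10, hwe_p_min = 1e-10) {
  df <- as.data.frame(x)
  fail_maf <- pmin(df$freq, 1 - df$freq) < maf_min
  if (all(is.na(df$info))) {
    message("qc_filter: no imputation-quality column; info rule skipped")
    fail_info <- rep(FALSE, nrow(df))
  } else {
    fail_info <- !is.na(df$info) & df$info < info_min
  }
  if (all(is.na(df$miss))) {
    message("qc_filter: no missingness column; missingness rule skipped")
    fail_miss <- rep(FALSE, nrow(df))
  } else {
    fail_miss <- !is.na(df$miss) & df$miss > miss_max
  }
  fail_hwe <- rep(FALSE, nrow(df))
  if (!is.null(panel)) {
    idx <- match(variant_ids(df), variant_ids(panel$variants))
    for (i in which(!is.na(idx))) {
      g <- round(panel$dosage[, idx[i]])
      p <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
      fail_hwe[i] <- p < hwe_p_min
    }
  }
  exclusions <- c(maf = sum(fail_maf),
                  info = sum(fail_info & !fail_maf),
                  miss = sum(fail_miss & !fail_maf & !fail_info),
                  hwe = sum(fail_hwe & !fail_maf & !fail_info & !fail_miss))
  keep <- !(fail_maf | fail_info | fail_miss | fail_hwe)
  if (!any(keep)) {
    stop("all variants removed by QC (maf: ", exclusions["maf"],
         ", info: ", exclusions["info"], ", miss: ", exclusions["miss"],
         ", hwe: ", exclusions["hwe"], ")")
  }
  out <- sumstats(df[keep, , drop = FALSE], trait = attr(x, "trait"),
                  build = attr(x, "build"), validate = FALSE)
  attr(out, "exclusions") <- exclusions
  out
}
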