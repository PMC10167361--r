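#' Genotype panel
#'
#' A reference panel of additive genotype dosages used for LD calculation,
#' conditional analysis and Hardy-Weinberg testing: a samples-by-variants
#' matrix with entries in \[0, 2\] plus a variant annotation table whose
#' coordinates match the summary-statistics convention.
#'
#' @param dosage numeric matrix, samples in rows, variants in columns,
#'   entries in \[0, 2\].
#' @param variants data frame with columns `chrom`, `pos`, `a1`, `a2`
#'   (one row per dosage column, in column order).
#' @return a `genotype_panel` object (list with `dosage` and `variants`).
#' @export
genotype_panel <- function(dosage, variants) {
  dosage <- as.matrix(dosage)
  if (ncol(dosage) != nrow(variants)) {
    stop("dosage has ", ncol(dosage), " columns but ", nrow(variants),
         " variant annotations")
  }
  if (any(dosage < 0 | dosage > 2)) stop("dosages must lie in [0, 2]")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  colnames(dosage) <- paste(variants$chrom, variants$pos, sep = ":")
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel:", nrow(x$dosage), "samples x",
      ncol(x$dosage), "variants\n")
  invisible(x)
}

#' Write / read a genotype panel
#'
#' Plain-text representation: a tab-separated dosage matrix (samples x
#' variants, with a variant-id header) and a side-by-side variant
#' annotation table at `<path>.variants`.
#'
#' @param panel a [genotype_panel()].
#' @param path base path for the two files.
#' @return `path` (write) or a `genotype_panel` (read).
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel$dosage, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(panel$variants, paste0(path, ".variants"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  dosage <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                        check.names = FALSE))
  variants <- utils::read.table(paste0(path, ".variants"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  genotype_panel(dosage, variants)
}

#' LD matrix of allelic correlations
#'
#' Computes the pairwise Pearson correlation of dosages for a set of panel
#' variants.  The result is symmetric with a unit diagonal and carries the
#' variant identifiers as dimnames.
#'
#' @param panel a [genotype_panel()].
#' @param variants optional character vector of `chrom:pos` identifiers (or
#'   integer column indices) selecting variants; default: all.
#' @return an `ld_matrix`: correlation matrix with variant-id dimnames.
#' @export
compute_ld <- function(panel, variants = NULL) {
  g <- panel$dosage
  if (!is.null(variants)) {
    if (is.character(variants)) {
      idx <- match(variants, colnames(g))
      if (anyNA(idx)) {
        stop("variant(s) not in panel: ",
             paste(variants[is.na(idx)], collapse = ", "))
      }
    } else {
      idx <- variants
    }
    g <- g[, idx, drop = FALSE]
  }
  if (nrow(g) < 2L) stop("LD computation needs at least 2 samples")
  sds <- apply(g, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant dosage column(s): ",
         paste(colnames(g)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(g)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  class(r) <- c("ld_matrix", "matrix")
  r
}

#' @rdname compute_ld
#' @param x an `ld_matrix`.
#' @param path file path; whitespace-delimited square matrix with a
#'   variant-id header line.
#' @export
write_ld <- function(x, path) {
  utils::write.table(unclass(x), path, sep = " ", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname compute_ld
#' @export
read_ld <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, check.names = FALSE))
  rownames(m) <- colnames(m)
  class(m) <- c("ld_matrix", "matrix")
  m
}

# GRCh37 MHC interval excluded from locus definition (complex LD).
.MHC <- list(chrom = "6", start = 28477797L, end = 33448354L)

.in_mhc <- function(chrom, pos) {
  chrom == .MHC$chrom & pos >= .MHC$start & pos <= .MHC$end
}

#' Define association loci from genome-wide summary statistics
#'
#' Greedy locus definition: repeatedly take the smallest-p remaining
#' variant with `pval < p_threshold` as a locus index; the locus spans the
#' index position plus/minus `window`; all significant variants inside the
#' window are absorbed into the locus; repeat until no significant variant
#' remains.  An index falling inside the GRCh37 MHC interval
#' (6:28,477,797-33,448,354) is skipped and never forms a locus.
#'
#' @param x a QC'd `sumstats` object.
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param window half-width of the locus around the index variant, in bp
#'   (default 500 kb).
#' @param exclude_mhc drop indices inside the MHC interval (default TRUE).
#' @return data frame with one row per locus: `chrom`, `start`, `end`
#'   (1-based inclusive), `index_id`, `index_pos`, `index_pval`,
#'   `n_significant`, and a list column `members` of member variant ids
#'   (significant variants absorbed by the locus).  Empty (zero-row) when
#'   nothing is significant.
#' @export
define_loci <- function(x, p_threshold = 5e-8, window = 5e5,
                        exclude_mhc = TRUE) {
  df <- as.data.frame(x)
  df$id <- variant_ids(df)
  sig <- df[df$pval < p_threshold, , drop = FALSE]
  if (exclude_mhc) {
    mhc <- .in_mhc(sig$chrom, sig$pos)
    sig <- sig[!mhc, , drop = FALSE]
  }
  loci <- list()
  while (nrow(sig) > 0L) {
    i <- which.min(sig$pval)
    idx <- sig[i, ]
    inside <- sig$chrom == idx$chrom & abs(sig$pos - idx$pos) <= window
    members <- sig$id[inside]
    loci[[length(loci) + 1L]] <- data.frame(
      chrom = idx$chrom,
      start = max(1L, as.integer(idx$pos - window)),
      end = as.integer(idx$pos + window),
      index_id = idx$id,
      index_pos = idx$pos,
      index_pval = idx$pval,
      n_significant = length(members),
      stringsAsFactors = FALSE
    )
    loci[[length(loci)]]$members <- I(list(members))
    sig <- sig[!inside, , drop = FALSE]
  }
  if (length(loci) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), index_id = character(),
                      index_pos = integer(), index_pval = numeric(),
                      n_significant = integer(),
                      members = I(list()), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  out
}

#' Variants of a summary-statistics table inside a locus window
#'
#' @param x a `sumstats` object.
#' @param locus one row of the [define_loci()] result.
#' @return the `sumstats` subset falling in `[start, end]` on the locus
#'   chromosome.
#' @export
locus_variants <- function(x, locus) {
  keep <- x$chrom == locus$chrom & x$pos >= locus$start & x$pos <= locus$end
  sumstats(as.data.frame(x)[keep, , drop = FALSE], trait = attr(x, "trait"),
           build = attr(x, "build"), validate = FALSE)
}
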