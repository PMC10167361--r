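#' Default pipeline configuration
#'
#' Flat per-stage configuration embedding the analysis defaults — the
#' genome-wide locus threshold 5e-8, the locus-wide joint threshold 1e-6,
#' 500 kb locus windows, instrument pruning at r^2 < 0.01 within 250 kb,
#' gamma = 0.05 and prior scale 0.15 for fine-mapping, credible mass 0.99,
#' colocalization priors 1e-4/1e-4/1e-5, and the gene-screen FDR cutoff
#' 0.1 — so a bare configuration runs the full chain with the intended
#' settings.  Any subset of keys may be overridden via a YAML file or a
#' nested list.
#'
#' @param seed master seed propagated (via [substream_seed()]) to every
#'   stochastic stage.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    simulate = list(n_samples = 2000, block_sizes = c(120, 120), rho = 0.9,
                    maf_range = c(0.05, 0.5), h2 = 0.1,
                    causal_per_block = 1L),
    qc = list(maf_min = 0.01, info_min = 0.9, miss_max = 0.10,
              hwe_p_min = 1e-10),
    loci = list(p_threshold = 5e-8, window = 5e5),
    signals = list(p_joint = 1e-6, max_r2 = 0.9, ridge = 1e-8),
    finemap = list(omega_scale = 0.15, gamma = 0.05, credible_mass = 0.99,
                   pip_threshold = 0.01),
    coloc = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, window = 5e5,
                 shared = TRUE),
    mr = list(n_instruments = 10, theta = 0.2, pleiotropy = "none",
              p_threshold = 5e-8, r2_threshold = 0.01, window = 2.5e5,
              fdr = 0.1, n_boot = 200),
    prevalence = list(n_cohort = 1500, bin_width = 4, n_boot = 100,
                      population_sizes = c(F = 273000, M = 230000))
  )
}

# recursively overlay user values onto defaults
.merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]])) {
      .merge_config(base[[k]], user[[k]])
    } else {
      user[[k]]
    }
  }
  base
}

#' Validate a pipeline configuration
#'
#' Checks the schema before any stage runs: unknown stages, gamma/credible
#' mass/prior bounds, positive sizes and thresholds.
#'
#' @param cfg nested configuration list.
#' @return the validated configuration, invisibly; errors on violation.
#' @export
validate_config <- function(cfg) {
  known <- names(default_config())
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  }
  finemap_config(cfg$finemap$omega_scale, cfg$finemap$gamma,
                 cfg$finemap$credible_mass)
  coloc_config(cfg$coloc$p1, cfg$coloc$p2, cfg$coloc$p12, cfg$coloc$window)
  stopifnot(cfg$simulate$n_samples >= 100,
            cfg$loci$p_threshold > 0, cfg$loci$p_threshold < 1,
            cfg$signals$p_joint > 0, cfg$signals$p_joint < 1,
            cfg$mr$fdr > 0, cfg$mr$fdr < 1,
            cfg$prevalence$bin_width >= 1)
  invisible(cfg)
}

#' Load a pipeline configuration
#'
#' @param path YAML file with any subset of the [default_config()] keys,
#'   or `NULL` for the defaults.
#' @param seed optional seed override.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL, seed = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- .merge_config(cfg, user)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  validate_config(cfg)
  cfg
}

.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) if (is.list(df[[col]])) {
    df[[col]] <- vapply(df[[col]], paste, "", collapse = ",")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the end-to-end demonstration pipeline
#'
#' Executes the full chain on a simulated multi-locus genome: simulate
#' (panel, phenotype, marginal scan) → variant QC → locus definition →
#' stepwise conditional signals per locus → per-signal fine-mapping →
#' colocalization of a simulated trait pair → gene-screen two-sample MR →
#' spine-score prevalence projection.  Each stage writes its outputs
#' before the next runs; a failure stops the run naming the stage.  All
#' randomness derives from the configured seed, so a re-run with the same
#' configuration reproduces byte-identical stage outputs; the run manifest
#' (`manifest.json`) records the configuration, seeds, parameter values
#' and output-file digests.
#'
#' @param config a configuration list (see [default_config()]), a YAML
#'   file path, or `NULL` for the defaults.
#' @param out_dir output directory (created if absent).
#' @param seed optional master-seed override.
#' @return invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("dishmap_run_"),
                         seed = NULL) {
  cfg <- if (is.character(config)) {
    load_config(config, seed)
  } else if (is.null(config)) {
    load_config(NULL, seed)
  } else {
    if (!is.null(seed)) config$seed <- as.integer(seed)
    validate_config(.merge_config(default_config(), config))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- simulate ---------------------------------------------------------
  sim <- stage("simulate", {
    s <- cfg$simulate
    nb <- length(s$block_sizes)
    causal <- integer()
    offs <- cumsum(c(0L, utils::head(s$block_sizes, -1L)))
    for (b in seq_len(nb)) {
      causal <- c(causal, offs[b] + s$block_sizes[b] %/% 2L)
    }
    betas <- rep(0.25, length(causal))
    scfg <- sim_config(s$n_samples, s$block_sizes, s$rho, s$maf_range,
                       causal_index = causal, causal_betas = betas,
                       h2 = s$h2, seed = substream_seed(cfg$seed, 101L))
    simulate_gwas(scfg)
  })
  outputs <- c(outputs, write_sumstats(sim$sumstats,
                                       file.path(out_dir, "sumstats.tsv")))

  # --- qc ---------------------------------------------------------------
  ss <- stage("qc", suppressMessages(
    qc_filter(sim$sumstats, sim$panel, cfg$qc$maf_min, cfg$qc$info_min,
              cfg$qc$miss_max, cfg$qc$hwe_p_min)))
  qc_report <- data.frame(rule = names(attr(ss, "exclusions")),
                          excluded = as.integer(attr(ss, "exclusions")),
                          survivors = nrow(ss))
  outputs <- c(outputs, .write_tsv(qc_report, file.path(out_dir, "qc_report.tsv")))
  message("qc: ", nrow(sim$sumstats), " -> ", nrow(ss), " variants")

  # --- loci -------------------------------------------------------------
  loci <- stage("loci", define_loci(ss, cfg$loci$p_threshold, cfg$loci$window))
  outputs <- c(outputs, .write_tsv(loci, file.path(out_dir, "loci.tsv")))
  message("loci: ", nrow(loci), " locus/loci defined")

  # --- signals + finemap ------------------------------------------------
  sigma <- estimate_sigma(ss)
  fcfg <- finemap_config(cfg$finemap$omega_scale, cfg$finemap$gamma,
                         cfg$finemap$credible_mass)
  signals_rows <- list()
  finemap_rows <- list()
  stage("signals/finemap", {
    for (i in seq_len(nrow(loci))) {
      locus <- loci[i, ]
      lss <- locus_variants(ss, locus)
      ld <- compute_ld(sim$panel, variant_ids(lss))
      vx <- apply(sim$panel$dosage[, variant_ids(lss), drop = FALSE], 2,
                  stats::var)
      sigs <- stepwise_selection(locus, ss, ld, sigma2 = sigma^2,
                                 var_x = vx, ridge = cfg$signals$ridge,
                                 max_r2 = cfg$signals$max_r2,
                                 p_joint = cfg$signals$p_joint)
      sigs$locus <- locus$index_id
      signals_rows[[i]] <- sigs
      for (j in seq_len(nrow(sigs))) {
        fm <- finemap_signal(lss, ld, conditioning = sigs$conditioned_on[[j]],
                             cfg = fcfg, sigma = sigma, var_x = vx,
                             pip_threshold = cfg$finemap$pip_threshold)
        for (mode in c("marginal", "conditional")) {
          tab <- fm[[mode]]$table
          tab$mode <- mode
          tab$signal <- sigs$id[j]
          tab$locus <- locus$index_id
          finemap_rows[[length(finemap_rows) + 1L]] <- tab
        }
      }
    }
  })
  signals <- if (length(signals_rows)) do.call(rbind, signals_rows) else
    data.frame()
  finemap_tab <- if (length(finemap_rows)) do.call(rbind, finemap_rows) else
    data.frame()
  outputs <- c(outputs, .write_tsv(signals, file.path(out_dir, "signals.tsv")),
               .write_tsv(finemap_tab, file.path(out_dir, "finemap.tsv")))
  message("signals: ", nrow(signals), " conditionally independent signal(s)")

  # --- coloc ------------------------------------------------------------
  coloc_res <- stage("coloc", {
    pair <- simulate_trait_pair(
      sim_config(cfg$simulate$n_samples, cfg$simulate$block_sizes[1],
                 cfg$simulate$rho, cfg$simulate$maf_range,
                 h2 = cfg$simulate$h2),
      shared = isTRUE(cfg$coloc$shared), beta = 0.25,
      seed = substream_seed(cfg$seed, 102L))
    h <- harmonize_alleles(pair$t1, pair$t2)
    coloc_abf(h$a, h$b, coloc_config(cfg$coloc$p1, cfg$coloc$p2,
                                     cfg$coloc$p12, cfg$coloc$window))
  })
  coloc_row <- data.frame(t(coloc_res$pp),
                          classification = coloc_res$classification,
                          direction = coloc_res$direction,
                          top_variant = coloc_res$top_shared,
                          n_variants = coloc_res$n_variants)
  outputs <- c(outputs, .write_tsv(coloc_row, file.path(out_dir, "coloc.tsv")))

  # --- mr ---------------------------------------------------------------
  mr_tab <- stage("mr", {
    genes <- paste0("gene", 1:3)
    exposures <- list()
    lds <- list()
    outcome <- NULL
    for (gi in seq_along(genes)) {
      sc <- simulate_mr_scenario(mr_config(
        n_instruments = cfg$mr$n_instruments, theta = cfg$mr$theta,
        pleiotropy = cfg$mr$pleiotropy,
        seed = substream_seed(cfg$seed, 110L + gi)))
      exposures[[genes[gi]]] <- sc$exposure
      lds[[genes[gi]]] <- sc$ld
      outcome <- sc$outcome  # shared-outcome convention per scenario draw
    }
    mr_pipeline(exposures, outcome, lds, fdr = cfg$mr$fdr,
                p_threshold = cfg$mr$p_threshold,
                r2_threshold = cfg$mr$r2_threshold, window = cfg$mr$window,
                n_boot = cfg$mr$n_boot,
                seed = substream_seed(cfg$seed, 103L))
  })
  outputs <- c(outputs, .write_tsv(mr_tab, file.path(out_dir, "mr.tsv")))

  # --- prevalence -------------------------------------------------------
  prev <- stage("prevalence", {
    sp <- simulate_spine_cohort(cfg$prevalence$n_cohort,
                                seed = substream_seed(cfg$seed, 104L))
    curve <- fit_diagnosis_curve(sp$labels$score, sp$labels$dish)
    estimate_prevalence(sp$cohort$score, sp$cohort$sex, curve,
                        cfg$prevalence$population_sizes,
                        bin_width = cfg$prevalence$bin_width,
                        labels = data.frame(score = sp$labels$score,
                                            label = sp$labels$dish),
                        n_boot = cfg$prevalence$n_boot,
                        seed = substream_seed(cfg$seed, 105L))
  })
  outputs <- c(outputs, .write_tsv(prev, file.path(out_dir, "prevalence.tsv")))

  # --- manifest ---------------------------------------------------------
  manifest <- list(
    tool = "dishmap",
    version = as.character(utils::packageVersion("dishmap")),
    seed = cfg$seed,
    config = cfg,
    parameters = list(gamma = cfg$finemap$gamma,
                      omega_scale = cfg$finemap$omega_scale,
                      sigma_estimate = sigma,
                      credible_mass = cfg$finemap$credible_mass,
                      coloc_priors = c(cfg$coloc$p1, cfg$coloc$p2,
                                       cfg$coloc$p12),
                      mr_fdr = cfg$mr$fdr),
    outputs = as.list(tools::md5sum(outputs)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(config = cfg, sumstats = ss, loci = loci, signals = signals,
                 finemap = finemap_tab, coloc = coloc_res, mr = mr_tab,
                 prevalence = prev, manifest = manifest, out_dir = out_dir))
}
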