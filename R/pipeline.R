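# End-to-end pipeline driver: synthesize or load spectra, preprocess, PCA
# screening, deconvolution of selected samples, class totals, pairwise
# comparisons.

#' Default pipeline configuration
#'
#' @param seed integer seed for all randomness.
#' @return nested list understood by [run_pipeline]; override fields as
#'   needed.
#' @export
pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    input_dir = NULL,             # directory of <sample>_<portion>.csv; NULL = synthesize
    synth = list(n_portions = 10L, portion_scale_sd = 0.05,
                 noise_sd = NULL, param_jitter = 0.05, center_jitter = 0.5,
                 baseline_coeffs = c(0.02, 2e-4), effects = NULL),
    preprocess = list(sg_window = 25L, sg_order = 2L, als_lambda = 1e6,
                      als_p = 0.001, als_threshold = 0.01,
                      als_max_iter = 50L, band = c(1185, 1330)),
    pca = list(scale_unit = TRUE, n_pcs = 2L),
    selection = c("FYHHH", "FOCHH", "FOCMC", "FOMLG"),
    fit = list(center_box = 2, fwhm_box = c(7, 19)),
    compare = list(alpha = 0.05, measures = c("area", "relative_pct"),
                   var_equal = FALSE),
    out_dir = NULL
  )
}

.load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  base <- pipeline_config()
  merge_lists <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_lists(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  cfg <- merge_lists(base, as.list(config))
  if (is.null(cfg$seed)) stop("config must carry a seed")
  cfg
}

.config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' Run the two-stage Amide III analysis pipeline
#'
#' Executes the full chain: obtain spectra (synthesize a cohort, or load
#' `<sample>_<portion>.csv` files from `config$input_dir`), preprocess
#' every portion (Savitzky--Golay, ALS baseline, band crop), run the PCA
#' screening with factor description and level distances, deconvolve the
#' per-portion spectra of the selected samples, aggregate
#' secondary-structure class totals, and compare all selected sample pairs.
#'
#' @param config a config list (see [pipeline_config]) or the path of a
#'   YAML/JSON file with the same structure.
#' @param quiet suppress progress messages.
#' @return list of class `amide3_pipeline`: `seed`, `config`,
#'   `config_hash`, `factors`, `pca`, `association`, `distances`,
#'   `deconvolution` (per selected sample: list of per-portion
#'   `amide3_fit`s), `tables` (Table-3-style parameter summary),
#'   `class_totals`, `comparisons`.  If `config$out_dir` is set, CSV
#'   exports are written there.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  cfg <- .load_config(config)
  say <- function(...) if (!quiet) message("[amide3] ", sprintf(...))
  t0 <- Sys.time()

  # --- stage 0: spectra ---------------------------------------------------
  if (!is.null(cfg$input_dir)) {
    files <- list.files(cfg$input_dir, pattern = "\\.csv$", full.names = TRUE)
    if (!length(files)) stop("no CSV spectra in ", cfg$input_dir)
    say("loading %d spectra from %s", length(files), cfg$input_dir)
    spectra <- lapply(files, read_spectrum)
    factors <- NULL
  } else {
    roster <- cohort_roster()
    say("synthesizing cohort: %d participants x %d portions",
        nrow(roster), cfg$synth$n_portions)
    coh <- generate_cohort(roster,
                           n_portions = cfg$synth$n_portions,
                           param_jitter = cfg$synth$param_jitter,
                           center_jitter = cfg$synth$center_jitter,
                           effects = cfg$synth$effects,
                           seed = cfg$seed,
                           baseline_coeffs = cfg$synth$baseline_coeffs,
                           portion_scale_sd = cfg$synth$portion_scale_sd,
                           noise_sd = cfg$synth$noise_sd)
    spectra <- coh$spectra
    factors <- coh$factors
  }

  # --- stage 1: preprocessing ---------------------------------------------
  pp <- cfg$preprocess
  say("preprocessing %d spectra", length(spectra))
  corrected <- lapply(spectra, function(s)
    preprocess_spectrum(s, sg_window = pp$sg_window, sg_order = pp$sg_order,
                        als_lambda = pp$als_lambda, als_p = pp$als_p,
                        als_threshold = pp$als_threshold,
                        als_max_iter = pp$als_max_iter, band = pp$band))

  # --- stage 2: PCA screening ----------------------------------------------
  say("PCA screening")
  mat <- build_matrix(corrected, band = pp$band, average_portions = TRUE,
                      factors = factors)
  pca <- run_pca(mat, scale_unit = cfg$pca$scale_unit)
  association <- if (!is.null(mat$factors))
    describe_dimension(pca, mat$factors, n_pcs = cfg$pca$n_pcs) else NULL
  distances <- if (!is.null(mat$factors))
    level_distances(pca, mat$factors, n_pcs = cfg$pca$n_pcs) else NULL

  # --- stage 3: deconvolution of selected samples ---------------------------
  selection <- cfg$selection
  ids <- vapply(corrected, function(s) s$sample_id, character(1))
  # synthetic subjects carry make.unique suffixes; match on the code prefix
  base_id <- sub("_[0-9]+$", "", ids)
  constraints <- fit_constraints(center_box = cfg$fit$center_box,
                                 fwhm_box = cfg$fit$fwhm_box)
  deconvolution <- list()
  for (sel in selection) {
    hit <- which(base_id == sel)
    if (!length(hit)) {
      warning("selected sample not present: ", sel)
      next
    }
    # when several subjects share the code, take the first
    first_subject <- ids[hit][1]
    hit <- hit[ids[hit] == first_subject]
    say("deconvolving %s (%d portions)", sel, length(hit))
    deconvolution[[sel]] <- deconvolve_portions(corrected[hit],
                                                constraints = constraints)
  }

  tables <- do.call(rbind, lapply(names(deconvolution), function(sel)
    cbind(sample_id = sel, deconvolution[[sel]]$mean)))

  totals <- do.call(rbind, lapply(names(deconvolution), function(sel)
    cbind(sample_id = sel, class_totals(deconvolution[[sel]]$mean))))

  # --- stage 4: pairwise comparisons ----------------------------------------
  comparisons <- NULL
  if (length(deconvolution) >= 2L) {
    say("pairwise comparisons (%d samples)", length(deconvolution))
    comparisons <- compare_pairs(deconvolution,
                                 alpha = cfg$compare$alpha,
                                 measures = cfg$compare$measures,
                                 var_equal = cfg$compare$var_equal)
  }

  out <- structure(list(seed = cfg$seed, config = cfg,
                        config_hash = .config_hash(cfg),
                        factors = factors, pca = pca,
                        association = association, distances = distances,
                        deconvolution = deconvolution, tables = tables,
                        class_totals = totals, comparisons = comparisons),
                   class = "amide3_pipeline")
  if (!is.null(cfg$out_dir)) .export_pipeline(out, cfg$out_dir)
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out
}

.export_pipeline <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(obj, name)
    utils::write.csv(obj, file.path(out_dir, name), row.names = FALSE)
  wr(summary(x$pca), "pca_eigenvalues.csv")
  wr(data.frame(sample_id = rownames(x$pca$scores),
                round(x$pca$scores[, seq_len(min(5, ncol(x$pca$scores))),
                                   drop = FALSE], 6)),
     "pca_scores.csv")
  if (!is.null(x$association)) {
    wr(x$association$anova, "association_anova.csv")
    wr(x$association$levels, "association_levels.csv")
  }
  if (!is.null(x$distances)) {
    dd <- do.call(rbind, lapply(names(x$distances), function(fn)
      data.frame(factor = fn,
                 level = names(x$distances[[fn]]$center_distance),
                 distance = as.numeric(x$distances[[fn]]$center_distance))))
    wr(dd, "level_distances.csv")
  }
  if (!is.null(x$tables)) wr(x$tables, "deconvolution_parameters.csv")
  if (!is.null(x$class_totals)) wr(x$class_totals, "class_totals.csv")
  if (!is.null(x$comparisons)) {
    long <- do.call(rbind, lapply(names(x$comparisons), function(nm)
      cbind(pair = nm, as.data.frame(x$comparisons[[nm]]))))
    wr(long, "pairwise_comparisons.csv")
    wr(long[long$significant, , drop = FALSE], "significant_differences.csv")
  }
  meta <- data.frame(key = c("seed", "config_hash"),
                     value = c(x$seed, x$config_hash))
  wr(meta, "run_metadata.csv")
  invisible(out_dir)
}

#' @export
print.amide3_pipeline <- function(x, ...) {
  cat("Amide III two-stage pipeline run\n")
  cat(sprintf("  seed %d, config %s\n", x$seed, x$config_hash))
  cat(sprintf("  PCA: first 2 PCs explain %.1f%%\n", x$pca$cumulative_pct[2]))
  cat(sprintf("  deconvolved samples: %s\n",
              paste(names(x$deconvolution), collapse = ", ")))
  if (!is.null(x$comparisons)) {
    nsig <- sum(vapply(x$comparisons, function(cc) sum(cc$significant),
                       numeric(1)))
    cat(sprintf("  significant pairwise differences: %d\n", nsig))
  }
  invisible(x)
}
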