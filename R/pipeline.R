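#' Write a synthetic study to disk
#'
#' Materializes a [simulate_study()] draw as TSV feature tables (one per
#' metabolomics block, plus SCFA and taxa tables), a ground-truth JSON
#' sidecar, and an echo of the generating configuration — a deterministic
#' function of the seed.
#'
#' @param out_dir output directory, created if needed.
#' @param config a [sim_config()].
#' @param seed overrides `config$seed`.
#' @return invisibly, the named character vector of files written.
#' @export
pipeline_simulate <- function(out_dir, config = sim_config(), seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_study(config, seed = seed)
  files <- character(0)
  for (bn in names(sim$blocks)) {
    f <- file.path(out_dir, paste0(bn, ".tsv"))
    write_feature_table(sim$blocks[[bn]], f)
    files[bn] <- f
  }
  scfa_df <- cbind(sim$scfa$sample_meta,
                   as.data.frame(sim$scfa$concentrations))
  f <- file.path(out_dir, "scfa.tsv")
  utils::write.table(scfa_df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  files["scfa"] <- f
  f <- file.path(out_dir, "taxa.tsv")
  write_feature_table(sim$taxa, f)
  files["taxa"] <- f

  truth <- sim$truth
  f <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(
    blocks = lapply(truth$blocks, function(b) list(
      diet_markers = b$diet_markers, time_markers = b$time_markers,
      blank_features = b$blank_features)),
    scfa_diet_mult = as.list(truth$scfa_diet_mult),
    taxa_markers = truth$taxa_markers,
    diets = truth$diets), f, auto_unbox = TRUE, digits = NA)
  files["truth"] <- f

  f <- file.path(out_dir, "config.yaml")
  cfg <- rapply(unclass(sim$config), unclass, how = "replace")
  yaml::write_yaml(cfg, f)
  files["config"] <- f
  invisible(files)
}

## shared preprocessing for file-based runs
.load_and_preprocess <- function(paths, blank_threshold = 1, mz_max = NULL,
                                 rt_window = NULL, qc_normalize = TRUE) {
  tables <- list()
  for (bn in names(paths)) {
    t <- read_feature_table(paths[[bn]])
    if (qc_normalize && sum(t$sample_meta$role == "QC") >= 2L)
      t <- suppressWarnings(qc_drift_normalize(t))
    if (!is.null(blank_threshold) && any(t$sample_meta$role == "blank"))
      t <- blank_filter(t, blank_threshold)
    if (!is.null(mz_max) || !is.null(rt_window))
      t <- mz_rt_filter(t, mz_max %||% Inf, rt_window %||% c(-Inf, Inf))
    tables[[bn]] <- t
  }
  tables
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit and cross-validate a multi-block classification model from files
#'
#' End-to-end run: read the block tables, apply QC drift correction and the
#' blank/mass filters, align the blocks to their common samples, optimize the
#' degree-of-sparsity path and number of latent variables under
#' leave-one-subject-out CV, refit the final model on all samples, and write
#' a model archive, a JSON report (SR_CV or RMSE, A_opt, g path, confusion
#' matrix, scores, super weights) and score-plot figures.
#'
#' @param config run configuration: a YAML file path or a list with fields
#'   `blocks` (named list of table paths), `target` (sample-metadata column,
#'   e.g. `class_label` for diet or `time_point`), `out_dir`, and optionally
#'   `grid`, `ncomp_max`, `blank_threshold`, `mz_max`, `rt_window`,
#'   `qc_normalize`, `seed`.
#' @return invisibly, the report list.
#' @export
pipeline_fit_cv <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  needed <- c("blocks", "target", "out_dir")
  miss <- setdiff(needed, names(config))
  if (length(miss))
    .stopf("run config lacks field(s): %s", paste(miss, collapse = ", "))
  unknown <- setdiff(names(config),
                     c(needed, "grid", "ncomp_max", "blank_threshold",
                       "mz_max", "rt_window", "qc_normalize", "seed"))
  if (length(unknown))
    .stopf("unknown run config field(s): %s", paste(unknown, collapse = ", "))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))

  tables <- .load_and_preprocess(config$blocks,
                                 blank_threshold = config$blank_threshold %||% 1,
                                 mz_max = config$mz_max,
                                 rt_window = config$rt_window,
                                 qc_normalize = config$qc_normalize %||% TRUE)
  mb <- align_blocks(tables)
  si <- sample_info(mb)
  if (!config$target %in% names(si))
    .stopf("target column '%s' not present in sample metadata", config$target)
  y <- si[[config$target]]
  grid <- config$grid %||% c(0, 0.5, 0.8, 0.9, 0.95, 0.99)
  ncomp_max <- config$ncomp_max %||% 2L

  cv <- cross_validate(mb, y, grid = grid, ncomp_max = ncomp_max)
  model <- smbplsr(mb, y, ncomp = cv$ncomp_opt,
                   sparsity = cv$g_path[seq_len(cv$ncomp_opt)])

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_smbplsr(model, file.path(config$out_dir, "model.rds"))
  report <- list(
    package_version = as.character(utils::packageVersion("smbplsr")),
    seed = config$seed,
    target = config$target,
    n_samples = nrow(si),
    blocks = lapply(mb$blocks, function(b) ncol(b$intensities)),
    ncomp_opt = cv$ncomp_opt,
    g_path = cv$g_path[seq_len(cv$ncomp_opt)],
    explained_variance = model$explained_variance,
    super_weights = as.data.frame(model$super_weights),
    scores = as.data.frame(cbind(sample_id = si$sample_id,
                                 as.data.frame(model$scores))))
  if (cv$mode == "classification") {
    report$sr_cv <- cv$success_rate
    report$mcr <- cv$mcr
    report$confusion <- as.data.frame.matrix(cv$confusion)
    report$sensitivity <- as.list(cv$sensitivity)
  } else {
    report$rmse_cv <- cv$rmse
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  grDevices::pdf(file.path(config$out_dir, "figures.pdf"), width = 7, height = 6)
  on.exit(grDevices::dev.off(), add = TRUE)
  try({
    if (model$ncomp >= 2L) plot(model, "scores", labels = y, main = "Global scores")
    plot(model, "super_weights", main = "Super weights")
  }, silent = TRUE)
  invisible(report)
}

#' Biomarker report for a fitted model, written to disk
#'
#' @param model_path path to a model archive written by [write_smbplsr()].
#' @param block_paths named list of block table paths (the raw data the model
#'   was fitted on, for the univariate ANOVA confirmation).
#' @param out_dir output directory.
#' @param alpha significance level.
#' @return invisibly, the biomarker report data.frame.
#' @export
pipeline_biomarkers <- function(model_path, block_paths, out_dir, alpha = 0.05) {
  model <- read_smbplsr(model_path)
  tables <- .load_and_preprocess(block_paths)
  mb <- align_blocks(tables)
  rep <- biomarker_report(model, mb, alpha = alpha)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(rep, file.path(out_dir, "biomarkers.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!nrow(rep)) warning("empty biomarker set", call. = FALSE)
  invisible(rep)
}

#' Correlation-loading coordinates and rank-2 heat-map matrices, to disk
#'
#' @param model_path path to a model archive.
#' @param block_paths named list of block table paths.
#' @param out_dir output directory.
#' @return invisibly, a list with the correlation loadings and the rank-2
#'   correlation object.
#' @export
pipeline_corrloadings <- function(model_path, block_paths, out_dir) {
  model <- read_smbplsr(model_path)
  if (model$ncomp < 2L) stop(">= 2 components required")
  tables <- .load_and_preprocess(block_paths)
  mb <- align_blocks(tables)
  vars <- do.call(cbind, lapply(mb$blocks, function(b) b$intensities))
  cl <- correlation_loadings(model, vars)
  sel <- suppressWarnings(select_biomarkers(model))
  sel_ids <- intersect(sel$feature_id, colnames(vars))
  hm <- NULL
  if (length(sel_ids) >= 2L)
    hm <- rank2_correlation_heatmap(vars[, sel_ids, drop = FALSE], model$scores)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cl, file.path(out_dir, "correlation_loadings.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(hm)) {
    utils::write.table(hm$r, file.path(out_dir, "rank2_correlation.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(hm$p, file.path(out_dir, "rank2_pvalues.tsv"),
                       sep = "\t", quote = FALSE)
  }
  invisible(list(loadings = cl, heatmap = hm))
}

#' Diet energy and fiber arithmetic from a composition file
#'
#' @param spec_path YAML or JSON file whose fields match [diet_spec()]
#'   arguments (g/kg DM).
#' @param out_path optional JSON output path.
#' @return list with `energy_pct` and `total_dietary_fiber`.
#' @export
pipeline_dietcalc <- function(spec_path, out_path = NULL) {
  vals <- if (grepl("\\.ya?ml$", spec_path)) yaml::read_yaml(spec_path)
          else jsonlite::read_json(spec_path, simplifyVector = TRUE)
  spec <- do.call(diet_spec, vals)
  out <- list(energy_pct = as.list(diet_energy_contribution(spec)))
  tdf <- try(total_dietary_fiber(spec), silent = TRUE)
  if (!inherits(tdf, "try-error")) out$total_dietary_fiber <- tdf
  if (!is.null(out_path))
    jsonlite::write_json(out, out_path, auto_unbox = TRUE, digits = NA)
  out
}
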