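#' Configuration for a synthetic multi-block feeding study
#'
#' Describes the study design the generator emulates: two diet groups of
#' `n_subjects_per_diet` animals sampled at three time points, three
#' untargeted LC-MS metabolomics blocks with log-normal intensities and
#' cluster-correlated features, planted diet and time markers, QC injections
#' with multiplicative linear signal drift, blank-only features, per-block
#' missing samples, a fecal SCFA panel with diet/time multipliers, and a
#' compositional taxa block.
#'
#' @param n_subjects_per_diet animals per diet group (default 15).
#' @param diets two diet labels.
#' @param time_points sampling occasions.
#' @param blocks named list of metabolomics block configurations, see
#'   [sim_block_config()].
#' @param scfa list: `baseline` (named per-acid means, mmol/kg),
#'   `diet_mult` (named multipliers applied in the second diet),
#'   `time_mult` (named per-week-step multipliers), `noise_sdlog`,
#'   `missing_rate`.
#' @param taxa list: `n_taxa`, `n_diet_taxa` (taxa shifted between diets),
#'   `effect` (log-scale composition shift), `sigma` (logistic-normal spread),
#'   `missing_rate`.
#' @param seed integer seed making the whole study reproducible.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects_per_diet = 15L,
                       diets = c("HR", "LR"),
                       time_points = c("week4", "week12", "week20"),
                       blocks = list(plasma = sim_block_config(mode = "ESI+"),
                                     urine = sim_block_config(mode = "ESI+"),
                                     feces = sim_block_config(mode = "ESI-")),
                       scfa = list(
                         baseline = c(formic = 5, acetic = 60, propionic = 25,
                                      isobutyric = 2, n_butyric = 15,
                                      isovaleric = 3, n_valeric = 4,
                                      isocaproic = 0.3, n_caproic = 1,
                                      heptanoic = 0.2, sorbic = 0.1,
                                      benzoic = 0.2, dl_lactic = 2,
                                      succinic = 1.5, hippuric = 0.5),
                         diet_mult = c(acetic = 1.3, propionic = 1.4,
                                       n_butyric = 1.5, isobutyric = 0.7,
                                       isovaleric = 0.7),
                         time_mult = c(acetic = 1.05, n_butyric = 1.05),
                         noise_sdlog = 0.25, missing_rate = 0.05),
                       taxa = list(n_taxa = 50L, n_diet_taxa = 5L,
                                   effect = 1, sigma = 1,
                                   missing_rate = 0.05),
                       seed = 42L) {
  stopifnot(n_subjects_per_diet >= 1L, length(diets) == 2L,
            length(time_points) >= 2L)
  if (any(vapply(blocks, function(b)
    b$n_diet_markers + b$n_time_markers + b$n_blank_features > b$n_features,
    logical(1))))
    stop("marker and blank feature counts exceed n_features")
  structure(list(n_subjects_per_diet = as.integer(n_subjects_per_diet),
                 diets = diets, time_points = time_points, blocks = blocks,
                 scfa = scfa, taxa = taxa, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @param n_features features per block (blank-only features included).
#' @param n_diet_markers,n_time_markers planted discriminative features.
#' @param effect_size diet/time shift in units of the log-intensity SD.
#' @param baseline_logmean,baseline_logsd log-intensity location and spread.
#' @param cluster_size,rho feature-cluster size and within-cluster correlation
#'   (untargeted LC-MS features from adducts/isotopes of one compound are
#'   strongly correlated; this emulates that).
#' @param missing_rate probability a study sample is absent from this block.
#' @param n_qc number of QC injections.
#' @param n_blank_features features present only in blank injections.
#' @param drift_slope multiplicative intensity drift across the run
#'   (1 = doubling from first to last injection).
#' @param mode ionization-mode tag for the feature metadata.
#' @export
sim_block_config <- function(n_features = 200L, n_diet_markers = 20L,
                             n_time_markers = 10L, effect_size = 1.5,
                             baseline_logmean = 10, baseline_logsd = 0.6,
                             cluster_size = 10L, rho = 0.5,
                             missing_rate = 0.05, n_qc = 8L,
                             n_blank_features = 10L, drift_slope = 0.3,
                             mode = "ESI+") {
  stopifnot(n_features >= 1L, effect_size >= 0, rho >= 0, rho < 1,
            missing_rate >= 0, missing_rate <= 1)
  list(n_features = as.integer(n_features),
       n_diet_markers = as.integer(n_diet_markers),
       n_time_markers = as.integer(n_time_markers),
       effect_size = effect_size, baseline_logmean = baseline_logmean,
       baseline_logsd = baseline_logsd, cluster_size = as.integer(cluster_size),
       rho = rho, missing_rate = missing_rate, n_qc = as.integer(n_qc),
       n_blank_features = as.integer(n_blank_features),
       drift_slope = drift_slope, mode = mode)
}

## design data.frame: one row per subject x time point
.sim_design <- function(config) {
  n <- config$n_subjects_per_diet
  subjects <- sprintf("S%02d", seq_len(2L * n))
  diet_of <- rep(config$diets, each = n)
  design <- expand.grid(time_point = config$time_points, subject_id = subjects,
                        stringsAsFactors = FALSE)[, c(2, 1)]
  design$class_label <- diet_of[match(design$subject_id, subjects)]
  design$sample_id <- paste(design$subject_id, design$time_point, sep = "_")
  design$week_index <- match(design$time_point, config$time_points)
  design
}

.sim_met_block <- function(bc, design, block_name) {
  n <- nrow(design)
  p <- bc$n_features
  n_blank_feat <- bc$n_blank_features
  p_use <- p - n_blank_feat
  fid <- sprintf("%s_F%04d", block_name, seq_len(p))
  is_blank_feat <- seq_len(p) > p_use

  mu <- stats::rnorm(p, bc$baseline_logmean, 1)
  # cluster-correlated noise for the measured (non-blank) features
  n_inj_extra <- bc$n_qc + 2L
  n_rows <- n + n_inj_extra
  ncl <- ceiling(p_use / bc$cluster_size)
  cl <- rep(seq_len(ncl), each = bc$cluster_size)[seq_len(p_use)]
  Fm <- matrix(stats::rnorm(n_rows * ncl), n_rows, ncl)
  E <- matrix(stats::rnorm(n_rows * p_use), n_rows, p_use)
  Z <- sqrt(bc$rho) * Fm[, cl, drop = FALSE] + sqrt(1 - bc$rho) * E

  logx <- matrix(0, n_rows, p)
  logx[, seq_len(p_use)] <- sweep(bc$baseline_logsd * Z, 2L,
                                  mu[seq_len(p_use)], "+")
  # QC injections sit at the pooled profile with small analytical noise
  qc_rows <- n + seq_len(bc$n_qc)
  logx[qc_rows, seq_len(p_use)] <-
    matrix(mu[seq_len(p_use)], bc$n_qc, p_use, byrow = TRUE) +
    0.1 * bc$baseline_logsd * matrix(stats::rnorm(bc$n_qc * p_use), bc$n_qc)
  blank_rows <- n + bc$n_qc + 1:2

  # planted effects
  diet_ids <- time_ids <- character(0)
  diet_sign <- time_sign <- integer(0)
  if (bc$n_diet_markers > 0L) {
    jd <- seq_len(bc$n_diet_markers)
    diet_sign <- rep_len(c(1L, -1L), bc$n_diet_markers)
    diet_ids <- fid[jd]
    in_diet2 <- design$class_label == unique(design$class_label)[2]
    shift <- outer(as.numeric(in_diet2),
                   diet_sign * bc$effect_size * bc$baseline_logsd)
    logx[seq_len(n), jd] <- logx[seq_len(n), jd] + shift
  }
  if (bc$n_time_markers > 0L) {
    jt <- bc$n_diet_markers + seq_len(bc$n_time_markers)
    time_sign <- rep_len(c(1L, -1L), bc$n_time_markers)
    time_ids <- fid[jt]
    k <- max(design$week_index)
    tfrac <- (design$week_index - 1) / (k - 1)
    shift <- outer(tfrac, time_sign * bc$effect_size * bc$baseline_logsd)
    logx[seq_len(n), jt] <- logx[seq_len(n), jt] + shift
  }

  intens <- exp(logx)
  # blank-only features: zero everywhere except the blank injections
  if (n_blank_feat > 0L) {
    intens[, is_blank_feat] <- 0
    intens[blank_rows, is_blank_feat] <-
      exp(mu[is_blank_feat] + 0.1 * stats::rnorm(2 * n_blank_feat))
  }
  # measured features are essentially absent from blanks
  intens[blank_rows, seq_len(p_use)] <-
    exp(mu[seq_len(p_use)] - 8 + 0.1 * stats::rnorm(2 * p_use))

  # injection sequence: blanks first/last, QCs evenly spaced, samples randomized
  io <- integer(n_rows)
  io[blank_rows] <- c(1L, n_rows)
  inner <- 2:(n_rows - 1L)
  qc_pos <- unique(inner[round(seq(1, length(inner), length.out = bc$n_qc))])
  if (length(qc_pos) < bc$n_qc)
    stop("run too short to place ", bc$n_qc, " QC injections")
  io[qc_rows] <- qc_pos
  io[seq_len(n)] <- sample(setdiff(inner, qc_pos))
  drift <- 1 + bc$drift_slope * (io - 1) / (n_rows - 1)
  intens <- intens * drift

  # per-block sample missingness
  keep_sample <- stats::runif(n) >= bc$missing_rate
  keep <- c(which(keep_sample), qc_rows, blank_rows)

  sm <- data.frame(
    sample_id = c(design$sample_id, sprintf("QC%02d", seq_len(bc$n_qc)),
                  c("BLANK01", "BLANK02")),
    subject_id = c(design$subject_id, rep("", bc$n_qc + 2L)),
    class_label = c(design$class_label, rep("", bc$n_qc + 2L)),
    time_point = c(design$time_point, rep("", bc$n_qc + 2L)),
    injection_order = io,
    role = c(rep("sample", n), rep("QC", bc$n_qc), rep("blank", 2L)),
    stringsAsFactors = FALSE)
  vm <- data.frame(feature_id = fid,
                   mz = round(stats::runif(p, 100, 700), 4),
                   rt = round(stats::runif(p, 0.5, 15), 3),
                   mode = bc$mode, stringsAsFactors = FALSE)
  colnames(intens) <- fid
  ft <- feature_table(intens[keep, , drop = FALSE],
                      sm[keep, , drop = FALSE], vm)
  list(table = ft,
       truth = list(diet_markers = data.frame(feature_id = diet_ids,
                                              sign = diet_sign,
                                              stringsAsFactors = FALSE),
                    time_markers = data.frame(feature_id = time_ids,
                                              sign = time_sign,
                                              stringsAsFactors = FALSE),
                    blank_features = fid[is_blank_feat]))
}

.sim_scfa <- function(sc, design) {
  n <- nrow(design)
  acids <- names(sc$baseline)
  conc <- matrix(sc$baseline, n, length(acids), byrow = TRUE,
                 dimnames = list(design$sample_id, acids))
  diet2 <- design$class_label == unique(design$class_label)[2]
  for (a in names(sc$diet_mult))
    conc[diet2, a] <- conc[diet2, a] * sc$diet_mult[[a]]
  for (a in names(sc$time_mult))
    conc[, a] <- conc[, a] * sc$time_mult[[a]]^(design$week_index - 1)
  conc <- conc * exp(matrix(stats::rnorm(n * length(acids), 0, sc$noise_sdlog),
                            n))
  keep <- stats::runif(n) >= sc$missing_rate
  scfa_panel(conc[keep, , drop = FALSE], "fecal",
             design[keep, c("sample_id", "subject_id", "class_label",
                            "time_point")])
}

.sim_taxa <- function(tc, design, diets) {
  n <- nrow(design)
  p <- tc$n_taxa
  alpha <- stats::rnorm(p, 0, 1.5)
  shift_sign <- rep_len(c(1L, -1L), tc$n_diet_taxa)
  fid <- sprintf("taxa_T%03d", seq_len(p))
  diet2 <- design$class_label == diets[2]
  eta <- matrix(alpha, n, p, byrow = TRUE) +
    matrix(stats::rnorm(n * p, 0, tc$sigma), n)
  if (tc$n_diet_taxa > 0L)
    eta[diet2, seq_len(tc$n_diet_taxa)] <-
      eta[diet2, seq_len(tc$n_diet_taxa)] +
      matrix(shift_sign * tc$effect, sum(diet2), tc$n_diet_taxa, byrow = TRUE)
  rel <- exp(eta)
  rel <- rel / rowSums(rel)
  keep <- which(stats::runif(n) >= tc$missing_rate)
  sm <- data.frame(sample_id = design$sample_id,
                   subject_id = design$subject_id,
                   class_label = design$class_label,
                   time_point = design$time_point,
                   injection_order = seq_len(n),
                   role = "sample", stringsAsFactors = FALSE)
  vm <- data.frame(feature_id = fid, mode = "taxa", stringsAsFactors = FALSE)
  colnames(rel) <- fid
  list(table = feature_table(rel[keep, , drop = FALSE],
                             sm[keep, , drop = FALSE], vm),
       truth = data.frame(feature_id = fid[seq_len(tc$n_diet_taxa)],
                          sign = shift_sign, stringsAsFactors = FALSE))
}

#' Simulate a complete synthetic multi-block study
#'
#' Draws a full study under a [sim_config()]: three metabolomics feature
#' tables (with QC and blank injections, drift, planted markers and per-block
#' missing samples), a fecal SCFA panel, a compositional taxa table, and the
#' ground truth of every planted effect for recovery testing. The same seed
#' always yields the bit-identical study.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed` when given.
#' @return list of class `sim_study` with elements `blocks` (named list of
#'   metabolomics [feature_table()]s), `scfa` ([scfa_panel()]), `taxa`
#'   (relative-abundance `feature_table`), `truth` (per-block planted diet and
#'   time markers, blank features, SCFA multipliers, taxa markers, the full
#'   design) and `config`.
#' @export
simulate_study <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)
  design <- .sim_design(config)

  blocks <- list(); truth_blocks <- list()
  for (bn in names(config$blocks)) {
    sim <- .sim_met_block(config$blocks[[bn]], design, bn)
    blocks[[bn]] <- sim$table
    truth_blocks[[bn]] <- sim$truth
  }
  scfa <- .sim_scfa(config$scfa, design)
  taxa <- .sim_taxa(config$taxa, design, config$diets)

  structure(list(blocks = blocks, scfa = scfa, taxa = taxa$table,
                 truth = structure(list(blocks = truth_blocks,
                                        scfa_diet_mult = config$scfa$diet_mult,
                                        taxa_markers = taxa$truth,
                                        design = design,
                                        diets = config$diets),
                                   class = "ground_truth"),
                 config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("sim_study: %d diet groups x %d subjects x %d time points (seed %d)\n",
              2L, x$config$n_subjects_per_diet, length(x$config$time_points),
              x$config$seed))
  for (bn in names(x$blocks))
    cat(sprintf("  %s: %s\n", bn,
                paste(dim(x$blocks[[bn]]), collapse = " x ")))
  cat(sprintf("  scfa: %d samples; taxa: %d samples x %d taxa\n",
              nrow(x$scfa$concentrations), nrow(x$taxa$intensities),
              ncol(x$taxa$intensities)))
  invisible(x)
}

#' Recovery of planted markers by a biomarker selection
#'
#' @param selected a `biomarker_report` (or character vector of feature ids).
#' @param truth the `ground_truth` of the generating [simulate_study()] call.
#' @param blocks which blocks' planted diet markers form the target set
#'   (default: all metabolomics blocks).
#' @return list with `recall` (planted markers recovered / planted),
#'   `precision` (recovered / selected; `NA` and flagged when nothing was
#'   selected), `fdp` (1 - precision), `n_selected`, `n_planted`.
#' @export
recovery_metrics <- function(selected, truth, blocks = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (inherits(selected, "data.frame")) selected <- selected$feature_id
  selected <- unique(as.character(selected))
  if (is.null(blocks)) blocks <- names(truth$blocks)
  planted <- unlist(lapply(truth$blocks[blocks],
                           function(b) b$diet_markers$feature_id),
                    use.names = FALSE)
  hit <- length(intersect(selected, planted))
  precision <- if (length(selected)) hit / length(selected) else NA_real_
  if (!length(selected))
    .msgf("recovery_metrics: empty selection; precision undefined")
  list(recall = if (length(planted)) hit / length(planted) else NA_real_,
       precision = precision,
       fdp = if (is.na(precision)) NA_real_ else 1 - precision,
       n_selected = length(selected), n_planted = length(planted))
}
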