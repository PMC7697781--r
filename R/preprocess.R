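#' Remove features dominated by procedural blanks
#'
#' Untargeted LC-MS tables carry features that originate from solvents,
#' eluents or carry-over rather than from the samples. A feature is discarded
#' when its mean intensity in blank injections reaches `ratio_threshold` times
#' its mean intensity in study samples (missing cells count as zero in both
#' means).
#'
#' @param table a [feature_table()] containing at least one `role = "blank"` row.
#' @param ratio_threshold positive multiplier; the default 1 removes features
#'   at least as intense in blanks as in samples.
#' @return the filtered `feature_table`.
#' @export
blank_filter <- function(table, ratio_threshold = 1) {
  stopifnot(inherits(table, "feature_table"), ratio_threshold > 0)
  role <- table$sample_meta$role
  if (!any(role == "blank"))
    stop("no blank injections in table; skip the blank filter explicitly instead")
  x <- table$intensities
  x[is.na(x)] <- 0
  blank_mean <- colMeans(x[role == "blank", , drop = FALSE])
  sample_mean <- colMeans(x[role == "sample", , drop = FALSE])
  if (is.infinite(ratio_threshold)) {
    drop <- rep(FALSE, ncol(x))          # vacuous filter
  } else {
    drop <- blank_mean > 0 &
      (sample_mean == 0 | blank_mean >= ratio_threshold * sample_mean)
  }
  .msgf("blank_filter: removed %d of %d features", sum(drop), length(drop))
  table[, !drop]
}

#' Restrict features by mass and retention time
#'
#' Drops features whose m/z exceeds `mz_max` or whose retention time falls
#' outside `rt_window`. Features lacking the relevant metadata pass unchanged;
#' the boundary values themselves are kept (a feature at exactly `mz_max`
#' survives — only strictly higher masses are discarded).
#'
#' @param table a [feature_table()].
#' @param mz_max maximum mass-to-charge ratio (Da), e.g. 700 for a QTOF run.
#' @param rt_window length-2 numeric, retention-time window in minutes.
#' @return the filtered `feature_table`.
#' @export
mz_rt_filter <- function(table, mz_max = Inf, rt_window = c(-Inf, Inf)) {
  stopifnot(inherits(table, "feature_table"))
  if (rt_window[1] > rt_window[2]) stop("rt_window minimum exceeds maximum")
  vm <- table$variable_meta
  mz <- if ("mz" %in% names(vm)) vm$mz else rep(NA_real_, nrow(vm))
  rt <- if ("rt" %in% names(vm)) vm$rt else rep(NA_real_, nrow(vm))
  drop_mz <- !is.na(mz) & mz > mz_max
  drop_rt <- !is.na(rt) & (rt < rt_window[1] | rt > rt_window[2])
  drop <- drop_mz | drop_rt
  .msgf("mz_rt_filter: removed %d of %d features", sum(drop), length(drop))
  table[, !drop]
}

#' Correct within-run signal drift using QC injections
#'
#' Pooled quality-control samples injected throughout a run trace the
#' instrument's intensity drift. Per feature, a trend is fitted to the QC
#' intensities against injection order (linear least squares or loess), every
#' injection's intensity is divided by the fitted trend at its own injection
#' order, and the feature is rescaled so that the median of its drift-corrected
#' QC intensities equals the median of the raw QC intensities — units and the
#' per-feature QC median are preserved exactly. Features with fewer than two
#' usable QC values, or whose fitted trend is non-positive anywhere it is
#' needed, pass through unchanged with a warning.
#'
#' @param table a [feature_table()] with at least two `role = "QC"` rows.
#' @param smoother `"linear"` (default) or `"loess"`.
#' @param span loess span, used only for `smoother = "loess"`.
#' @return the drift-corrected `feature_table`.
#' @export
qc_drift_normalize <- function(table, smoother = c("linear", "loess"),
                               span = 0.75) {
  smoother <- match.arg(smoother)
  stopifnot(inherits(table, "feature_table"))
  role <- table$sample_meta$role
  io <- table$sample_meta$injection_order
  qc_idx <- which(role == "QC")
  if (length(unique(io[qc_idx])) < 2L)
    stop("need at least two QC injections with distinct injection_order")

  x <- table$intensities
  skipped <- 0L
  for (j in seq_len(ncol(x))) {
    qc_io <- io[qc_idx]
    qc_y <- x[qc_idx, j]
    usable <- !is.na(qc_y)
    if (sum(usable) < 2L) { skipped <- skipped + 1L; next }
    qc_io <- qc_io[usable]; qc_y <- qc_y[usable]
    trend_at <- switch(smoother,
      linear = {
        fit <- stats::lm.fit(cbind(1, qc_io), qc_y)
        function(t) fit$coefficients[1] + fit$coefficients[2] * t
      },
      loess = {
        fit <- try(stats::loess(qc_y ~ qc_io, span = span, degree = 1,
                                control = stats::loess.control(surface = "direct")),
                   silent = TRUE)
        if (inherits(fit, "try-error")) NULL else function(t) stats::predict(fit, data.frame(qc_io = t))
      })
    if (is.null(trend_at)) { skipped <- skipped + 1L; next }
    trend <- trend_at(io)
    if (any(!is.finite(trend) | trend <= 0)) { skipped <- skipped + 1L; next }
    corrected <- x[, j] / trend
    med_raw <- stats::median(qc_y)
    med_corr <- stats::median(corrected[qc_idx], na.rm = TRUE)
    if (!is.finite(med_corr) || med_corr == 0) { skipped <- skipped + 1L; next }
    x[, j] <- corrected * med_raw / med_corr
  }
  if (skipped > 0L)
    .warnf("qc_drift_normalize: %d feature(s) passed through unchanged (insufficient or non-positive QC trend)", skipped)
  table$intensities <- x
  table
}

## ---------------------------------------------------------------------------
## Scaling chain

#' Pareto scaling with a reusable state
#'
#' Centers each column by its mean and divides it by the square root of its
#' sample standard deviation, damping the dominance of high-intensity features
#' while retaining partial heteroscedasticity (scaled variance equals the
#' original standard deviation). Zero-variance columns are centered only.
#' When a `state` is supplied (e.g. transforming a held-out fold), its stored
#' means and standard deviations are used instead of recomputing them — the
#' transform is a deterministic function of `(input, state)`.
#'
#' @param x numeric matrix, samples x features.
#' @param state optional state returned by an earlier call.
#' @return list with elements `x` (scaled matrix) and `state`
#'   (`list(center, sd)`).
#' @export
pareto_scale <- function(x, state = NULL) {
  x <- as.matrix(x)
  if (is.null(state)) {
    state <- list(center = colMeans(x), sd = .col_sds(x))
  } else {
    if (length(state$center) != ncol(x))
      stop("scaling state does not match the number of features")
  }
  denom <- sqrt(state$sd)
  denom[denom == 0] <- 1
  xs <- sweep(sweep(x, 2L, state$center, "-"), 2L, denom, "/")
  list(x = xs, state = state)
}

#' Frobenius normalization of a set of blocks
#'
#' Divides each (already centered/scaled) block by its Frobenius norm — the
#' square root of the sum of its squared entries — so that blocks with very
#' different sizes and measurement units enter a multi-block model on the same
#' footing. With a `state`, the stored norms are reused.
#'
#' @param blocks a `multiblock`, or a named list of numeric matrices.
#' @param state optional numeric vector of norms from a previous call.
#' @return list with elements `blocks` (same shape as the input, normalized)
#'   and `state` (named numeric vector of the norms applied).
#' @export
frobenius_normalize <- function(blocks, state = NULL) {
  is_mb <- inherits(blocks, "multiblock")
  mats <- if (is_mb) lapply(blocks$blocks, function(b) b$intensities) else blocks
  nms <- if (is_mb) blocks$block_names else names(mats)
  if (is.null(state)) {
    state <- vapply(mats, .frobenius, numeric(1))
    names(state) <- nms
  }
  zero <- which(state == 0)
  if (length(zero))
    .stopf("zero Frobenius norm in block '%s'", nms[zero[1]])
  mats <- Map(function(m, s) m / s, mats, as.list(state))
  if (is_mb) {
    for (b in seq_along(mats)) blocks$blocks[[b]]$intensities <- mats[[b]]
    blocks$block_norms <- unname(state)
    list(blocks = blocks, state = state)
  } else {
    list(blocks = mats, state = state)
  }
}

#' Natural-log transform with an explicit zero policy
#'
#' @param values non-negative numeric vector or matrix (columns transformed
#'   independently).
#' @param offset_policy `"half-min"` replaces zeros by half the smallest
#'   positive value of the column before taking logs; `"error"` refuses zeros.
#' @return the log-transformed values.
#' @export
log_transform <- function(values, offset_policy = c("half-min", "error")) {
  offset_policy <- match.arg(offset_policy)
  one_col <- function(v) {
    if (any(v < 0, na.rm = TRUE)) stop("negative values cannot be log-transformed")
    z <- which(!is.na(v) & v == 0)
    if (length(z)) {
      if (offset_policy == "error") stop("zero values under offset_policy = 'error'")
      pos <- v[!is.na(v) & v > 0]
      if (!length(pos)) stop("all values are zero; cannot derive a half-min offset")
      v[z] <- min(pos) / 2
    }
    log(v)
  }
  if (is.matrix(values)) apply(values, 2L, one_col) else one_col(values)
}

## Full preprocessing used by the model: Pareto (or plain centering) per
## block, then Frobenius normalization, all frozen in one state for reuse on
## new samples.
.preprocess_blocks <- function(mats, state = NULL, scale = "pareto",
                               frobenius = TRUE) {
  if (is.null(state)) {
    st <- list(scale = scale, frobenius_applied = frobenius,
               pareto = vector("list", length(mats)), frobenius = NULL)
    names(st$pareto) <- names(mats)
    if (scale %in% c("pareto", "center")) {
      for (b in seq_along(mats)) {
        ps <- pareto_scale(mats[[b]])
        if (scale == "center") {
          ps$state$sd <- rep(1, length(ps$state$sd))
          ps <- pareto_scale(mats[[b]], ps$state)
        }
        mats[[b]] <- ps$x
        st$pareto[[b]] <- ps$state
      }
    }
    if (frobenius) {
      fn <- frobenius_normalize(mats)
      mats <- fn$blocks
      st$frobenius <- fn$state
    }
    list(blocks = mats, state = st)
  } else {
    if (state$scale %in% c("pareto", "center")) {
      for (b in seq_along(mats))
        mats[[b]] <- pareto_scale(mats[[b]], state$pareto[[b]])$x
    }
    if (isTRUE(state$frobenius_applied))
      mats <- frobenius_normalize(mats, state$frobenius)$blocks
    list(blocks = mats, state = state)
  }
}
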