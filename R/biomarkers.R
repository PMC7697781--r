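#' Biomarker selection from sparse regression coefficients
#'
#' In a sparse model a feature participates only if it carries nonzero weight
#' on some component; exactly those features have a nonzero row in the
#' regression coefficient matrix B. The report lists them per block, ordered
#' by the largest absolute coefficient, with the per-class coefficient
#' direction (which class the feature points towards).
#'
#' @param model a fitted [smbplsr()] model.
#' @return data.frame of class `biomarker_report`: `feature_id`, `block`,
#'   `coef_max_abs`, one `coef_<class>` column per response column.
#' @export
select_biomarkers <- function(model) {
  stopifnot(inherits(model, "smbplsr"))
  if (all(model$sparsity == 0))
    warning("selection not sparse; all features returned", call. = FALSE)
  B <- model$coefficients
  nz <- rowSums(B != 0) > 0
  out <- data.frame(feature_id = model$feature_ids[nz],
                    block = model$block_names[model$block_index[nz]],
                    coef_max_abs = apply(abs(B[nz, , drop = FALSE]), 1L, max),
                    stringsAsFactors = FALSE)
  for (cl in colnames(B)) out[[paste0("coef_", cl)]] <- B[nz, cl]
  out <- out[order(-out$coef_max_abs), ]
  rownames(out) <- NULL
  class(out) <- c("biomarker_report", "data.frame")
  out
}

#' One-way ANOVA on log-transformed intensities
#'
#' Univariate confirmation of a candidate biomarker: the intensities are
#' natural-log transformed (zeros replaced by half the smallest positive
#' value, see [log_transform()]) and compared across groups by classical
#' one-way ANOVA, returning the F statistic and the p-value from the F
#' distribution. When there is no variance anywhere and the group means are
#' equal, the groups are indistinguishable and `F = 0`, `p = 1` is returned.
#'
#' @param values non-negative numeric vector of raw intensities.
#' @param groups group labels, at least two groups with two observations each.
#' @param log log-transform before testing (default `TRUE`; set `FALSE` if
#'   `values` are already on the log scale).
#' @return named numeric vector `c(F, p)`.
#' @export
anova_log <- function(values, groups, log = TRUE) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("each group needs at least two observations")
  v <- if (log) log_transform(values) else values
  if (max(v) - min(v) < .Machine$double.eps * 100 * max(1, abs(max(v))))
    return(c(F = 0, p = 1))   # all observations equal: groups indistinguishable
  fit <- stats::anova(stats::lm(v ~ groups))
  Fv <- fit$`F value`[1L]
  pv <- fit$`Pr(>F)`[1L]
  if (!is.finite(Fv)) {
    # no residual variance: identical groups mean F is 0/0
    gm <- tapply(v, groups, mean)
    if (max(gm) - min(gm) < .Machine$double.eps * 100) {
      Fv <- 0; pv <- 1
    } else {
      Fv <- Inf; pv <- 0
    }
  }
  c(F = unname(Fv), p = unname(pv))
}

#' Full biomarker report with univariate confirmation
#'
#' Combines [select_biomarkers()] with per-feature [anova_log()] against a
#' grouping factor, flagging significance at `alpha`.
#'
#' @param model a fitted [smbplsr()] model.
#' @param x the raw (pre-scaling) `multiblock` or named list of matrices the
#'   model was fitted on.
#' @param groups grouping labels per sample (defaults to the model's training
#'   class labels).
#' @param alpha significance level for the flag (default 0.05).
#' @return the `biomarker_report` data.frame with `anova_F`, `anova_p` and
#'   `significant` columns appended.
#' @export
biomarker_report <- function(model, x, groups = NULL, alpha = 0.05) {
  rep0 <- suppressWarnings(select_biomarkers(model))
  if (is.null(groups)) groups <- model$y_labels
  if (is.null(groups)) stop("groups are required for a regression model")
  mats <- .as_block_matrices(x)
  names(mats) <- model$block_names
  Fv <- pv <- rep(NA_real_, nrow(rep0))
  for (i in seq_len(nrow(rep0))) {
    m <- mats[[rep0$block[i]]]
    j <- match(rep0$feature_id[i], colnames(m))
    if (is.na(j)) {
      # concatenated ids may be block-prefixed
      j <- match(sub(paste0("^", rep0$block[i], "\\."), "", rep0$feature_id[i]),
                 colnames(m))
    }
    if (is.na(j)) next
    ap <- anova_log(m[, j], groups)
    Fv[i] <- ap["F"]; pv[i] <- ap["p"]
  }
  rep0$anova_F <- Fv
  rep0$anova_p <- pv
  rep0$significant <- !is.na(pv) & pv <= alpha
  rep0
}

#' Correlation loadings of variables on the first two latent variables
#'
#' For every variable, its Pearson correlations with the first two global
#' score vectors `(r1, r2)` locate it in the correlation loading plot: points
#' on the outer unit circle are fully explained by the two latent variables,
#' points on the inner circle of radius sqrt(0.5) are 50% explained.
#' Additional design variables (class dummies, time) can be appended to be
#' plotted alongside the omics variables.
#'
#' @param model a fitted [smbplsr()] (or [cpca()]) model with >= 2 components.
#' @param variables numeric matrix, samples x variables, aligned to the model
#'   samples (e.g. the concatenated raw blocks and/or design variables).
#' @return data.frame of class `correlation_loadings` with `variable`, `r1`,
#'   `r2` and `missing` (constant variables, flagged); attributes
#'   `inner_radius` (sqrt(0.5)) and `outer_radius` (1).
#' @export
correlation_loadings <- function(model, variables) {
  scores <- model$scores
  if (ncol(scores) < 2L) stop(">= 2 components required for correlation loadings")
  variables <- as.matrix(variables)
  if (nrow(variables) != nrow(scores))
    stop("variables must be aligned to the model samples")
  sds <- .col_sds(variables)
  r1 <- r2 <- rep(NA_real_, ncol(variables))
  ok <- sds > 0
  if (any(ok)) {
    r1[ok] <- stats::cor(variables[, ok, drop = FALSE], scores[, 1L])
    r2[ok] <- stats::cor(variables[, ok, drop = FALSE], scores[, 2L])
  }
  if (any(!ok))
    .msgf("correlation_loadings: %d constant variable(s) flagged missing", sum(!ok))
  nm <- colnames(variables)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(variables)))
  out <- data.frame(variable = nm, r1 = r1, r2 = r2, missing = !ok,
                    stringsAsFactors = FALSE)
  attr(out, "inner_radius") <- sqrt(0.5)
  attr(out, "outer_radius") <- 1
  class(out) <- c("correlation_loadings", "data.frame")
  out
}

#' @export
plot.correlation_loadings <- function(x, ...) {
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::plot(cos(th), sin(th), type = "l", asp = 1,
                 xlab = "correlation with LV1", ylab = "correlation with LV2", ...)
  graphics::lines(sqrt(0.5) * cos(th), sqrt(0.5) * sin(th), lty = 2)
  graphics::abline(h = 0, v = 0, lty = 3)
  graphics::points(x$r1, x$r2, pch = 19, cex = 0.6)
  invisible(x)
}

#' Rank-2 correlation heat-map matrix with significance
#'
#' Represents each variable by its orthogonal projection onto the plane
#' spanned by the first two latent-variable score vectors — the same
#' two-dimensional summary shown in a score or correlation loading plot — and
#' computes all pairwise Pearson correlations between the projections,
#' with two-sided p-values from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom (`n - 3`, one fewer for the rank-2 restriction,
#' behind `conservative_df = TRUE`). Pairs involving a variable whose
#' projection has (near-)zero norm are flagged missing.
#'
#' @param variables numeric matrix, samples x selected variables.
#' @param scores score matrix with >= 2 columns (first two used).
#' @param conservative_df use `n - 3` degrees of freedom instead of `n - 2`.
#' @return list of class `rank2_cor`: symmetric correlation matrix `r` with
#'   unit diagonal, p-value matrix `p` (zero diagonal), `df`, and logical
#'   `missing` vector.
#' @export
rank2_correlation_heatmap <- function(variables, scores,
                                      conservative_df = FALSE) {
  variables <- as.matrix(variables)
  if (ncol(variables) < 2L) stop("need at least two variables")
  n <- nrow(variables)
  if (n <= 3L) stop("need more than three samples")
  if (ncol(scores) < 2L) stop(">= 2 score columns required")
  T2 <- scores[, 1:2, drop = FALSE]
  T2 <- sweep(T2, 2L, colMeans(T2), "-")
  Vc <- sweep(variables, 2L, colMeans(variables), "-")
  proj <- T2 %*% solve(crossprod(T2), crossprod(T2, Vc))

  norms <- sqrt(colSums(proj^2))
  ok <- norms > max(norms) * 1e-10
  if (any(!ok))
    .msgf("rank2_correlation_heatmap: %d variable(s) with ~zero projection flagged missing",
          sum(!ok))
  m <- ncol(variables)
  r <- matrix(NA_real_, m, m)
  if (any(ok)) r[ok, ok] <- stats::cor(proj[, ok, drop = FALSE])
  diag(r) <- 1
  r[which(r > 1)] <- 1; r[which(r < -1)] <- -1

  df <- if (conservative_df) n - 3L else n - 2L
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[which(abs(r) >= 1)] <- 0
  diag(p) <- 0
  nm <- colnames(variables)
  if (is.null(nm)) nm <- paste0("V", seq_len(m))
  dimnames(r) <- dimnames(p) <- list(nm, nm)
  structure(list(r = r, p = p, df = df, missing = !ok), class = "rank2_cor")
}

#' @export
print.rank2_cor <- function(x, ...) {
  cat(sprintf("rank-2 correlation matrix: %d variables, df = %d\n",
              ncol(x$r), x$df))
  invisible(x)
}

#' @export
plot.rank2_cor <- function(x, ...) {
  m <- ncol(x$r)
  graphics::image(seq_len(m), seq_len(m), t(x$r[m:1, , drop = FALSE]),
                  zlim = c(-1, 1), xlab = "", ylab = "", axes = FALSE,
                  col = grDevices::hcl.colors(64, "Blue-Red 2"), ...)
  graphics::axis(1, at = seq_len(m), labels = colnames(x$r), las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(m), labels = rev(colnames(x$r)), las = 2, cex.axis = 0.6)
  invisible(x)
}
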