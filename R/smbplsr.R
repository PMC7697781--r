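#' One-hot indicator matrix for class labels
#'
#' Builds the 0/1 response matrix used by PLS discriminant models: one column
#' per class in sorted label order, each row summing to one.
#'
#' @param labels character or factor vector of class memberships.
#' @return integer matrix, samples x classes, with class names as columns.
#' @export
encode_classes <- function(labels) {
  labels <- as.character(labels)
  if (anyNA(labels) || any(labels == ""))
    stop("empty or missing class label")
  lev <- sort(unique(labels))
  if (length(lev) < 2L) stop("need at least two distinct classes")
  y <- matrix(0L, nrow = length(labels), ncol = length(lev),
              dimnames = list(NULL, lev))
  y[cbind(seq_along(labels), match(labels, lev))] <- 1L
  y
}

#' Soft-threshold a loading weight vector to a given degree of sparsity
#'
#' Retains the `k = max(1, round((1 - g) * p))` largest entries in absolute
#' value, shrinks every entry towards zero by the (k+1)-th largest magnitude
#' (soft thresholding), and renormalizes to unit length. Entries tied exactly
#' at the threshold shrink to zero, so fewer than `k` entries may survive;
#' if the tie wipes out every entry, the first index among the largest
#' magnitudes is retained and the event is logged.
#'
#' @param w numeric weight vector, not all zero.
#' @param g degree of sparsity in `[0, 1)`: the fraction of entries forced to
#'   zero (`g = 0` leaves the vector dense).
#' @return the sparse unit-norm weight vector.
#' @export
soft_threshold <- function(w, g) {
  if (g < 0 || g >= 1) stop("degree of sparsity must lie in [0, 1)")
  if (all(w == 0)) stop("cannot threshold a zero weight vector")
  p <- length(w)
  if (g == 0) return(.unitize(w))
  k <- max(1L, round((1 - g) * p))
  aw <- abs(w)
  lambda <- if (k >= p) 0 else sort(aw, decreasing = TRUE)[k + 1L]
  out <- sign(w) * pmax(aw - lambda, 0)
  if (all(out == 0)) {
    keep <- which(aw == max(aw))[1L]
    out[keep] <- w[keep]
    .msgf("soft_threshold: ties at the threshold removed all entries; retaining index %d", keep)
  }
  .unitize(out)
}

## ---------------------------------------------------------------------------
## NIPALS engine on preprocessed matrices.
##
## X: concatenated superblock (centered/scaled, blocks Frobenius-normalized),
## Yc: centered response, block_index: integer vector mapping X columns to
## blocks. Sparsity applied to the concatenated super-weight vector, one
## degree per component; deflation of X and Y by the super score (standard
## PLS2 deflation).
.smbplsr_core <- function(X, Yc, ncomp, sparsity, block_index,
                          tol = 1e-10, max_iter = 500L) {
  n <- nrow(X); p <- ncol(X); G <- ncol(Yc)
  nblocks <- max(block_index)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, G, ncomp); Tm <- matrix(0, n, ncomp)
  block_scores <- array(0, dim = c(n, ncomp, nblocks))
  super_weights <- matrix(0, nblocks, ncomp)
  ssx0 <- sum(X^2); ssy0 <- sum(Yc^2)
  r2x <- numeric(ncomp); r2y <- numeric(ncomp)
  iters <- integer(ncomp); converged <- logical(ncomp)

  Xd <- X; Yd <- Yc
  for (a in seq_len(ncomp)) {
    vars <- .col_sds(Yd)^2
    if (all(vars < .Machine$double.eps))
      stop("degenerate response: Y has no variance left at component ", a)
    u <- Yd[, which.max(vars)]
    t_old <- rep(0, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xd, u))
      nw <- sqrt(sum(w^2))
      if (nw == 0) stop("degenerate component ", a, ": X'u vanished")
      w <- soft_threshold(w / nw, sparsity[a])
      tt <- drop(Xd %*% w)
      stt <- sum(tt^2)
      if (stt == 0) stop("degenerate component ", a, ": zero score vector")
      q <- drop(crossprod(Yd, tt)) / stt
      u <- drop(Yd %*% q) / sum(q^2)
      delta <- sqrt(sum((tt - t_old)^2)) / sqrt(stt)
      t_old <- tt
      if (delta < tol) { converged[a] <- TRUE; break }
    }
    iters[a] <- it
    if (!converged[a])
      .warnf("NIPALS did not converge for component %d after %d iterations; using last iterate", a, max_iter)
    stt <- sum(tt^2)
    pp <- drop(crossprod(Xd, tt)) / stt
    W[, a] <- w; P[, a] <- pp; Q[, a] <- q; Tm[, a] <- tt
    for (b in seq_len(nblocks)) {
      cols <- block_index == b
      block_scores[, a, b] <- drop(Xd[, cols, drop = FALSE] %*% w[cols])
      super_weights[b, a] <- sum(w[cols]^2)
    }
    r2x[a] <- stt * sum(pp^2) / ssx0
    r2y[a] <- stt * sum(q^2) / ssy0
    Xd <- Xd - tcrossprod(tt, pp)
    Yd <- Yd - tcrossprod(tt, q)
  }
  PW <- crossprod(P, W)
  B <- tryCatch(W %*% solve(PW, t(Q)),
                error = function(e) stop("degenerate components: P'W is singular",
                                         call. = FALSE))
  list(W = W, P = P, Q = Q, scores = Tm, B = B,
       block_scores = block_scores, super_weights = super_weights,
       r2x = r2x, r2y = r2y, iterations = iters, converged = converged)
}

#' Fit a sparse multi-block partial least squares regression model
#'
#' Fits PLS2 by NIPALS on the column-wise concatenation of several omics
#' blocks, with soft-thresholded (sparse) loading weights for variable
#' selection. Each block is Pareto-scaled and then divided by its Frobenius
#' norm so blocks of different size and unit enter on the same footing; the
#' response is an indicator matrix of class memberships (classification) or a
#' centered numeric matrix (regression). Sparsity is imposed on the
#' concatenated super-weight vector with one degree of sparsity per component;
#' both X and Y are deflated by the super score. Block scores
#' (`X_b w_b`, which sum to the super score exactly) and super weights (the
#' squared weight mass per block, summing to one per component) record each
#' block's contribution.
#'
#' @param x a `multiblock`, a named list of numeric matrices, or a single
#'   matrix (rows = samples).
#' @param y class labels (character/factor, for classification) or a numeric
#'   vector/matrix (regression). For a `multiblock`, a character scalar names
#'   a sample-metadata column to use.
#' @param ncomp number of latent variables A.
#' @param sparsity degree(s) of sparsity in `[0, 1)`, recycled to length
#'   `ncomp`: the fraction of super-weight entries forced to zero per
#'   component.
#' @param scale per-block scaling before modelling: `"pareto"` (default),
#'   `"center"` (mean-centering only) or `"none"` (input used as-is; the
#'   caller is then responsible for centering).
#' @param frobenius divide each block by its Frobenius norm (default `TRUE`).
#' @param tol,max_iter NIPALS convergence tolerance on the relative change of
#'   the score vector, and iteration cap.
#' @return an object of class `smbplsr` with components `weights` (sparse
#'   super weights, features x A, unit columns), `x_loadings`, `y_loadings`,
#'   `scores`, `block_scores`, `super_weights` (blocks x A),
#'   `coefficients` (on the preprocessed scale), `scaling_state`,
#'   `explained_variance`, `sparsity`, `mode`, `class_labels`.
#' @seealso [predict.smbplsr()], [cross_validate()], [select_biomarkers()],
#'   [cpca()]
#' @export
smbplsr <- function(x, y, ncomp = 2L, sparsity = 0,
                    scale = c("pareto", "center", "none"), frobenius = TRUE,
                    tol = 1e-10, max_iter = 500L) {
  scale <- match.arg(scale)
  if (ncomp < 1L) stop("ncomp must be at least 1")
  if (inherits(x, "multiblock") && is.character(y) && length(y) == 1L)
    y <- sample_info(x)[[y]]
  mats <- .as_block_matrices(x)
  sparsity <- rep_len(sparsity, ncomp)
  if (any(sparsity < 0 | sparsity >= 1))
    stop("sparsity degrees must lie in [0, 1)")

  mode <- if (is.numeric(y)) "regression" else "classification"
  if (mode == "classification") {
    labels <- as.character(y)
    Y <- encode_classes(labels)
    class_labels <- colnames(Y)
  } else {
    Y <- as.matrix(y)
    if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
    class_labels <- NULL
  }
  if (nrow(Y) != nrow(mats[[1L]]))
    stop("response length does not match the number of samples")

  prep <- .preprocess_blocks(mats, scale = scale, frobenius = frobenius)
  Xb <- prep$blocks
  block_index <- rep(seq_along(Xb), vapply(Xb, ncol, integer(1)))
  X <- do.call(cbind, Xb)
  feature_ids <- unlist(lapply(Xb, function(m) {
    if (is.null(colnames(m))) rep(NA_character_, ncol(m)) else colnames(m)
  }), use.names = FALSE)
  if (anyNA(feature_ids))
    feature_ids <- paste0("V", seq_len(ncol(X)))
  if (anyDuplicated(feature_ids))
    feature_ids <- paste(names(Xb)[block_index], feature_ids, sep = ".")
  colnames(X) <- feature_ids

  y_center <- colMeans(Y)
  Yc <- sweep(Y, 2L, y_center, "-")
  fit <- .smbplsr_core(X, Yc, ncomp, sparsity, block_index,
                       tol = tol, max_iter = max_iter)

  dimnames(fit$W) <- dimnames(fit$P) <-
    list(feature_ids, paste0("LV", seq_len(ncomp)))
  dimnames(fit$B) <- list(feature_ids, colnames(Y))
  dimnames(fit$Q) <- list(colnames(Y), paste0("LV", seq_len(ncomp)))
  colnames(fit$scores) <- paste0("LV", seq_len(ncomp))
  dimnames(fit$super_weights) <- list(names(Xb), paste0("LV", seq_len(ncomp)))
  bs <- lapply(seq_along(Xb), function(b) {
    m <- fit$block_scores[, , b, drop = FALSE]; dim(m) <- dim(m)[1:2]
    colnames(m) <- paste0("LV", seq_len(ncomp)); m
  })
  names(bs) <- names(Xb)

  structure(list(
    ncomp = ncomp, sparsity = sparsity, mode = mode,
    class_labels = class_labels,
    y_labels = if (mode == "classification") labels else NULL,
    weights = fit$W, x_loadings = fit$P, y_loadings = fit$Q,
    scores = fit$scores, block_scores = bs, super_weights = fit$super_weights,
    coefficients = fit$B, y_center = y_center,
    block_names = names(Xb), block_index = block_index,
    feature_ids = feature_ids,
    scaling_state = prep$state,
    explained_variance = data.frame(component = seq_len(ncomp),
                                    R2X = fit$r2x, R2Y = fit$r2y,
                                    cumR2X = cumsum(fit$r2x),
                                    cumR2Y = cumsum(fit$r2y)),
    iterations = fit$iterations, converged = fit$converged,
    call = match.call()), class = "smbplsr")
}

#' @export
print.smbplsr <- function(x, ...) {
  cat(sprintf("Sparse multi-block PLS regression (%s)\n", x$mode))
  cat(sprintf("  %d block(s): %s\n", length(x$block_names),
              paste(x$block_names, collapse = ", ")))
  cat(sprintf("  %d samples, %d features, %d latent variable(s)\n",
              nrow(x$scores), length(x$feature_ids), x$ncomp))
  cat("  degree of sparsity:", paste(format(x$sparsity), collapse = ", "), "\n")
  nz <- sum(rowSums(x$weights != 0) > 0)
  cat(sprintf("  features with nonzero weight: %d\n", nz))
  ev <- x$explained_variance
  cat(sprintf("  cumulative explained variance: X %.1f%%, Y %.1f%%\n",
              100 * ev$cumR2X[x$ncomp], 100 * ev$cumR2Y[x$ncomp]))
  invisible(x)
}

#' @export
summary.smbplsr <- function(object, ...) {
  out <- list(model = object,
              explained_variance = object$explained_variance,
              super_weights = object$super_weights,
              n_selected = sum(rowSums(object$weights != 0) > 0))
  class(out) <- "summary.smbplsr"
  out
}

#' @export
print.summary.smbplsr <- function(x, ...) {
  print(x$model)
  cat("\nExplained variance per latent variable:\n")
  print(format(x$explained_variance, digits = 3), row.names = FALSE)
  cat("\nSuper weights (block share of squared weight mass):\n")
  print(round(x$super_weights, 3))
  invisible(x)
}

#' @export
coef.smbplsr <- function(object, ...) object$coefficients

#' Predict responses or class labels from a fitted sMBPLSR model
#'
#' New blocks are transformed with the model's frozen scaling state (training
#' Pareto means/SDs and Frobenius norms — nothing is re-estimated from the new
#' data), multiplied by the regression coefficients and shifted by the stored
#' response centering. In classification mode the hard label is the argmax
#' over class columns; exact ties go to the first class in column order and
#' are logged.
#'
#' @param object a fitted [smbplsr()] model.
#' @param newdata a `multiblock`, named list of matrices, or matrix with the
#'   same features (per block) as the training data.
#' @param type `"response"` for the continuous indicator/response predictions,
#'   `"class"` for hard labels (classification models only).
#' @param ... ignored.
#' @return a matrix of continuous predictions, or a character vector of class
#'   labels.
#' @export
predict.smbplsr <- function(object, newdata,
                            type = c("response", "class"), ...) {
  type <- match.arg(type)
  mats <- .as_block_matrices(newdata)
  if (length(mats) != length(object$block_names))
    stop("newdata must contain the same blocks as the training data")
  pc <- vapply(mats, ncol, integer(1))
  tc <- tabulate(object$block_index, nbins = length(object$block_names))
  if (!all(pc == tc))
    .stopf("feature mismatch: newdata has %s features per block, model expects %s",
           paste(pc, collapse = "/"), paste(tc, collapse = "/"))
  Xn <- do.call(cbind, .preprocess_blocks(mats, state = object$scaling_state)$blocks)
  yhat <- Xn %*% object$coefficients
  yhat <- sweep(yhat, 2L, object$y_center, "+")
  if (type == "response") return(yhat)
  if (object$mode != "classification")
    stop("type = 'class' requires a classification model")
  .argmax_classes(yhat, object$class_labels)
}

## argmax with a deterministic, logged first-index tie rule
.argmax_classes <- function(yhat, class_labels) {
  idx <- integer(nrow(yhat))
  for (i in seq_len(nrow(yhat))) {
    r <- yhat[i, ]
    hit <- which(r == max(r))
    if (length(hit) > 1L)
      .msgf("predict: tie between classes %s at sample %d; first class retained",
            paste(class_labels[hit], collapse = "/"), i)
    idx[i] <- hit[1L]
  }
  class_labels[idx]
}

#' Score and correlation plots for sMBPLSR models
#'
#' @param x a fitted [smbplsr()] model.
#' @param type `"scores"` (global score plot), `"block_scores"` or
#'   `"super_weights"`.
#' @param comps length-2 integer, which latent variables to plot.
#' @param labels optional point labels (defaults to class labels).
#' @param ... passed to the underlying plotting functions.
#' @export
plot.smbplsr <- function(x, type = c("scores", "block_scores", "super_weights"),
                         comps = c(1L, 2L), labels = NULL, ...) {
  type <- match.arg(type)
  ev <- x$explained_variance
  lab_axis <- function(a) sprintf("LV%d (X %.1f%%, Y %.1f%%)", a,
                                  100 * ev$R2X[a], 100 * ev$R2Y[a])
  if (type == "super_weights") {
    graphics::barplot(x$super_weights, beside = TRUE,
                      legend.text = rownames(x$super_weights),
                      ylab = "super weight", ...)
    return(invisible(x))
  }
  if (x$ncomp < 2L) stop("score plots need at least two latent variables")
  if (is.null(labels)) labels <- x$y_labels
  if (type == "scores") {
    grp <- labels
    col <- if (!is.null(grp)) as.integer(factor(grp)) else 1L
    graphics::plot(x$scores[, comps[1]], x$scores[, comps[2]],
                   xlab = lab_axis(comps[1]), ylab = lab_axis(comps[2]),
                   col = col, pch = 19, ...)
    graphics::abline(h = 0, v = 0, lty = 3)
  } else {
    old <- graphics::par(mfrow = c(1, length(x$block_scores)))
    on.exit(graphics::par(old))
    for (b in seq_along(x$block_scores)) {
      bs <- x$block_scores[[b]]
      graphics::plot(bs[, comps[1]], bs[, comps[2]],
                     main = x$block_names[b],
                     xlab = paste0("LV", comps[1]), ylab = paste0("LV", comps[2]),
                     pch = 19, ...)
      graphics::abline(h = 0, v = 0, lty = 3)
    }
  }
  invisible(x)
}

#' Serialize a fitted model to a single archive
#'
#' `write_smbplsr()` stores the complete fitted object (arrays plus metadata,
#' including the frozen scaling state) in one file; `read_smbplsr()` restores
#' it. The round trip is exact.
#'
#' @param model a fitted [smbplsr()] model.
#' @param path file path for the archive.
#' @export
write_smbplsr <- function(model, path) {
  stopifnot(inherits(model, "smbplsr"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_smbplsr
#' @export
read_smbplsr <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "smbplsr")) stop("archive does not contain an smbplsr model")
  model
}
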