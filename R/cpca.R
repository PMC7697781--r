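#' Consensus principal component analysis of multiple blocks
#'
#' Unsupervised multi-block overview: principal components of the column-wise
#' concatenation of the centered (optionally Pareto-scaled),
#' Frobenius-normalized blocks, with the same block bookkeeping as the
#' supervised model — block scores `X_b p_b` that sum to the global score, and
#' super weights equal to each block's squared loading mass (summing to one
#' per component).
#'
#' @param x a `multiblock`, named list of matrices, or single matrix.
#' @param ncomp number of components; truncated with a warning when it exceeds
#'   the rank of the concatenated superblock.
#' @param scale per-block scaling, as in [smbplsr()] (default Pareto).
#' @param frobenius divide each block by its Frobenius norm (default `TRUE`).
#' @return an object of class `cpca`: `scores` (n x A), `loadings`
#'   (features x A, unit columns), `block_scores`, `super_weights`
#'   (blocks x A), `explained_variance` (per-component share of total
#'   variance), `scaling_state`.
#' @export
cpca <- function(x, ncomp = 2L, scale = c("pareto", "center", "none"),
                 frobenius = TRUE) {
  scale <- match.arg(scale)
  mats <- .as_block_matrices(x)
  if (scale == "none") {
    # still center: PCA of an uncentered matrix is not a variance decomposition
    mats <- lapply(mats, function(m) sweep(m, 2L, colMeans(m), "-"))
  }
  prep <- .preprocess_blocks(mats, scale = if (scale == "none") "none" else scale,
                             frobenius = frobenius)
  Xb <- prep$blocks
  block_index <- rep(seq_along(Xb), vapply(Xb, ncol, integer(1)))
  X <- do.call(cbind, Xb)

  sv <- svd(X)
  rank <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1])
  if (ncomp > rank) {
    .warnf("cpca: requested %d components but rank is %d; truncating", ncomp, rank)
    ncomp <- rank
  }
  scores <- sv$u[, seq_len(ncomp), drop = FALSE] %*%
    diag(sv$d[seq_len(ncomp)], ncomp)
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(ncomp))
  rownames(loadings) <- colnames(X)

  nblocks <- length(Xb)
  block_scores <- lapply(seq_len(nblocks), function(b) {
    cols <- block_index == b
    bs <- Xb[[b]] %*% loadings[cols, , drop = FALSE]
    colnames(bs) <- paste0("PC", seq_len(ncomp)); bs
  })
  names(block_scores) <- names(Xb)
  super_weights <- vapply(seq_len(nblocks), function(b)
    colSums(loadings[block_index == b, , drop = FALSE]^2), numeric(ncomp))
  super_weights <- t(matrix(super_weights, ncol = nblocks))
  dimnames(super_weights) <- list(names(Xb), paste0("PC", seq_len(ncomp)))

  structure(list(ncomp = ncomp, scores = scores, loadings = loadings,
                 block_scores = block_scores, super_weights = super_weights,
                 explained_variance = sv$d[seq_len(ncomp)]^2 / sum(sv$d^2),
                 singular_values = sv$d,
                 block_names = names(Xb), block_index = block_index,
                 scaling_state = prep$state, call = match.call()),
            class = "cpca")
}

#' @export
print.cpca <- function(x, ...) {
  cat(sprintf("Consensus PCA: %d block(s), %d samples, %d component(s)\n",
              length(x$block_names), nrow(x$scores), x$ncomp))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.cpca <- function(x, comps = c(1L, 2L), labels = NULL, ...) {
  if (x$ncomp < 2L) stop("need at least two components to plot")
  col <- if (!is.null(labels)) as.integer(factor(labels)) else 1L
  graphics::plot(x$scores[, comps[1]], x$scores[, comps[2]],
                 xlab = sprintf("PC%d (%.1f%%)", comps[1],
                                100 * x$explained_variance[comps[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", comps[2],
                                100 * x$explained_variance[comps[2]]),
                 col = col, pch = 19, ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}
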