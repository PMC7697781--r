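#' @keywords internal
"_PACKAGE"

## Column standard deviations without an extra dependency.
.col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(0, ncol(x)))
  ctr <- colMeans(x)
  sqrt(colSums(sweep(x, 2L, ctr, "-")^2) / (n - 1L))
}

.frobenius <- function(x) sqrt(sum(x^2))

#' Unit-norm a vector, erroring on the zero vector
#' @noRd
.unitize <- function(w, what = "weight vector") {
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("cannot normalize a zero ", what, call. = FALSE)
  w / nw
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
.msgf  <- function(fmt, ...) message(sprintf(fmt, ...))

## Coerce model inputs to a named list of numeric matrices.
.as_block_matrices <- function(x) {
  if (inherits(x, "multiblock")) {
    out <- lapply(x$blocks, function(b) b$intensities)
    names(out) <- x$block_names
  } else if (is.matrix(x)) {
    out <- list(X = x)
  } else if (is.list(x)) {
    if (!all(vapply(x, is.matrix, logical(1))))
      stop("blocks must be matrices, a multiblock, or a list of matrices")
    out <- x
    if (is.null(names(out))) names(out) <- paste0("block", seq_along(out))
  } else stop("unsupported block input of class ", paste(class(x), collapse = "/"))
  for (b in names(out)) {
    if (anyNA(out[[b]]))
      .stopf("block '%s' contains missing values; impute or drop them before modelling", b)
    storage.mode(out[[b]]) <- "double"
  }
  ns <- vapply(out, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all blocks must have the same number of rows (samples)")
  out
}
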