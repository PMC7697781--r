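#' Establish sample-to-sample correspondence across omics blocks
#'
#' Multi-block modelling requires every block to describe the same samples in
#' the same order. `align_blocks()` drops QC and blank injections, intersects
#' the remaining `sample_id` sets, removes any sample missing from one block
#' from all other blocks, and orders the shared samples canonically
#' (lexicographically by `subject_id`, then `time_point`).
#'
#' @param tables list of two or more [feature_table()] objects.
#' @param block_names optional character names for the blocks; defaults to the
#'   list names or `block1`, `block2`, ...
#' @return an object of class `multiblock`: a list with elements `blocks`
#'   (the aligned feature tables), `block_names`, `block_norms` (filled by
#'   [frobenius_normalize()], `NA` until then) and `dropped` (per-block count
#'   of study samples removed to achieve correspondence).
#' @export
align_blocks <- function(tables, block_names = NULL) {
  if (!is.list(tables) || length(tables) < 2L)
    stop("need a list of at least two feature tables")
  stopifnot(all(vapply(tables, inherits, logical(1), "feature_table")))
  if (is.null(block_names)) block_names <- names(tables)
  if (is.null(block_names)) block_names <- paste0("block", seq_along(tables))

  keep <- lapply(tables, function(t) t[t$sample_meta$role == "sample", ])
  ids <- lapply(keep, function(t) t$sample_meta$sample_id)
  common <- Reduce(intersect, ids)
  if (!length(common)) stop("no common samples across blocks")

  dropped <- vapply(seq_along(keep), function(b) length(ids[[b]]) - length(common),
                    integer(1))
  names(dropped) <- block_names
  for (b in seq_along(keep)) {
    if (dropped[b] > 0L)
      .msgf("align_blocks: dropped %d sample(s) from block '%s'",
            dropped[b], block_names[b])
  }

  ref <- keep[[1L]]$sample_meta
  ref <- ref[match(common, ref$sample_id), ]
  ord <- order(as.character(ref$subject_id), as.character(ref$time_point))
  common <- common[ord]

  blocks <- lapply(keep, function(t) {
    t[match(common, t$sample_meta$sample_id), ]
  })
  names(blocks) <- block_names
  structure(list(blocks = blocks,
                 block_names = block_names,
                 block_norms = rep(NA_real_, length(blocks)),
                 dropped = dropped),
            class = "multiblock")
}

#' @export
print.multiblock <- function(x, ...) {
  cat(sprintf("multiblock: %d blocks over %d common samples\n",
              length(x$blocks), nrow(x$blocks[[1]]$intensities)))
  for (b in seq_along(x$blocks))
    cat(sprintf("  %s: %d features (dropped %d samples)\n", x$block_names[b],
                ncol(x$blocks[[b]]$intensities), x$dropped[b]))
  invisible(x)
}

#' Shared sample metadata of an aligned multiblock
#' @param x a `multiblock`.
#' @return the sample metadata data.frame of the common samples.
#' @export
sample_info <- function(x) {
  stopifnot(inherits(x, "multiblock"))
  x$blocks[[1L]]$sample_meta
}
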