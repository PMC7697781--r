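#' Feature tables: one omics block as samples x features
#'
#' A `feature_table` couples an intensity matrix (rows = injections, columns =
#' features) with per-sample metadata (subject, class label, time point,
#' injection order, role) and per-feature metadata (m/z, retention time,
#' ionization mode). It is the unit of currency for the preprocessing and
#' modelling functions: untargeted LC-MS blocks, targeted SCFA panels and taxa
#' relative-abundance tables all travel in this shape.
#'
#' @param intensities numeric matrix, samples x features, non-negative;
#'   missing measurements are `NA`, never zero-imputed here.
#' @param sample_meta data.frame with columns `sample_id`, `subject_id`,
#'   `class_label`, `time_point`, `injection_order`, `role`
#'   (one of `"sample"`, `"QC"`, `"blank"`), one row per intensity row.
#' @param variable_meta data.frame with columns `feature_id` and optionally
#'   `mz` (Da), `rt` (minutes), `mode` (`"ESI+"`, `"ESI-"`, `"targeted"`,
#'   `"taxa"`), one row per intensity column.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(intensities, sample_meta, variable_meta = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  if (is.null(variable_meta)) {
    ids <- colnames(intensities)
    if (is.null(ids)) ids <- sprintf("F%04d", seq_len(ncol(intensities)))
    variable_meta <- data.frame(feature_id = ids, stringsAsFactors = FALSE)
  }
  variable_meta <- as.data.frame(variable_meta, stringsAsFactors = FALSE)
  ft <- structure(list(intensities = intensities,
                       sample_meta = sample_meta,
                       variable_meta = variable_meta),
                  class = "feature_table")
  validate_feature_table(ft)
}

#' @rdname feature_table
#' @param x a putative `feature_table`.
#' @export
validate_feature_table <- function(x) {
  req <- c("sample_id", "subject_id", "class_label", "time_point",
           "injection_order", "role")
  missing_cols <- setdiff(req, names(x$sample_meta))
  if (length(missing_cols))
    .stopf("sample_meta lacks required column(s): %s",
           paste(missing_cols, collapse = ", "))
  if (!"feature_id" %in% names(x$variable_meta))
    stop("variable_meta lacks required column 'feature_id'")
  if (nrow(x$sample_meta) != nrow(x$intensities))
    stop("sample_meta rows do not match intensity rows")
  if (nrow(x$variable_meta) != ncol(x$intensities))
    stop("variable_meta rows do not match intensity columns")

  sid <- as.character(x$sample_meta$sample_id)
  dup <- unique(sid[duplicated(sid)])
  if (length(dup))
    .stopf("duplicate sample_id: %s", paste(dup, collapse = ", "))
  fid <- as.character(x$variable_meta$feature_id)
  dup <- unique(fid[duplicated(fid)])
  if (length(dup))
    .stopf("duplicate feature_id: %s", paste(dup, collapse = ", "))
  io <- x$sample_meta$injection_order
  if (anyNA(io) || any(io <= 0) || any(io != round(io)))
    stop("injection_order must be positive integers")
  if (anyDuplicated(io))
    stop("injection_order must be unique within a table")
  if (!all(x$sample_meta$role %in% c("sample", "QC", "blank")))
    stop("role must be one of sample/QC/blank")

  neg <- which(x$intensities < 0, arr.ind = TRUE)
  if (nrow(neg))
    .stopf("negative intensity at sample '%s', feature '%s' (value %g)",
           sid[neg[1, 1]], fid[neg[1, 2]], x$intensities[neg[1, , drop = FALSE]])

  rownames(x$intensities) <- sid
  colnames(x$intensities) <- fid
  x$sample_meta$sample_id <- sid
  x$variable_meta$feature_id <- fid
  x
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d injections x %d features\n",
              nrow(x$intensities), ncol(x$intensities)))
  tab <- table(x$sample_meta$role)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (anyNA(x$intensities))
    cat(sprintf("  missing cells: %d\n", sum(is.na(x$intensities))))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Subset a feature table by sample and/or feature index
#' @param x a `feature_table`.
#' @param i,j sample (row) and feature (column) indices.
#' @param ... ignored.
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensities))
  if (missing(j)) j <- seq_len(ncol(x$intensities))
  feature_table(x$intensities[i, j, drop = FALSE],
                x$sample_meta[i, , drop = FALSE],
                x$variable_meta[j, , drop = FALSE])
}

.meta_cols <- c("sample_id", "subject_id", "class_label", "time_point",
                "injection_order", "role")
.varmeta_rows <- c("mz", "rt", "mode")

#' Read and write feature tables as delimited text
#'
#' The on-disk layout is one header row of feature ids preceded by the six
#' reserved sample-metadata columns; optional feature metadata (`mz`, `rt`,
#' `mode`) is carried in up to three pseudo-rows whose `sample_id` is
#' `#mz` / `#rt` / `#mode`. Empty cells are missing values. Intensities are
#' written with 17 significant digits so a write/read round trip reproduces
#' them bit-exactly.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `read_feature_table` returns a validated [feature_table()];
#'   `write_feature_table` returns `path` invisibly.
#' @export
read_feature_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", na.strings = "",
                           comment.char = "", quote = "\"")
  if (!all(.meta_cols %in% names(raw)))
    .stopf("missing reserved metadata column(s): %s",
           paste(setdiff(.meta_cols, names(raw)), collapse = ", "))
  is_meta_row <- startsWith(raw$sample_id, "#")
  meta_rows <- raw[is_meta_row, , drop = FALSE]
  body <- raw[!is_meta_row, , drop = FALSE]
  feat_cols <- setdiff(names(raw), .meta_cols)
  if (!length(feat_cols)) stop("no feature columns found")

  intens <- vapply(body[feat_cols], as.numeric, numeric(nrow(body)))
  intens <- matrix(intens, nrow = nrow(body),
                   dimnames = list(NULL, feat_cols))
  sm <- body[.meta_cols]
  sm$injection_order <- as.integer(sm$injection_order)
  sm$class_label[is.na(sm$class_label)] <- ""
  vm <- data.frame(feature_id = feat_cols, stringsAsFactors = FALSE)
  for (field in .varmeta_rows) {
    row <- meta_rows[meta_rows$sample_id == paste0("#", field), feat_cols]
    if (nrow(row) == 1L) {
      vals <- unlist(row, use.names = FALSE)
      vm[[field]] <- if (field == "mode") as.character(vals) else as.numeric(vals)
    }
  }
  feature_table(intens, sm, vm)
}

#' @rdname read_feature_table
#' @param x a `feature_table`.
#' @export
write_feature_table <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "feature_table"))
  sep <- if (dialect == "tsv") "\t" else ","
  fid <- x$variable_meta$feature_id
  fmt_num <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  header <- paste(c(.meta_cols, fid), collapse = sep)
  lines <- header
  for (field in .varmeta_rows) {
    if (field %in% names(x$variable_meta)) {
      vals <- x$variable_meta[[field]]
      vals <- if (is.numeric(vals)) fmt_num(vals) else ifelse(is.na(vals), "", vals)
      meta <- c(paste0("#", field), rep("", length(.meta_cols) - 1L), vals)
      lines <- c(lines, paste(meta, collapse = sep))
    }
  }
  sm <- x$sample_meta
  for (i in seq_len(nrow(sm))) {
    cells <- c(as.character(sm$sample_id[i]), as.character(sm$subject_id[i]),
               as.character(sm$class_label[i]), as.character(sm$time_point[i]),
               as.character(sm$injection_order[i]), as.character(sm$role[i]),
               fmt_num(x$intensities[i, ]))
    lines <- c(lines, paste(cells, collapse = sep))
  }
  writeLines(lines, path)
  invisible(path)
}
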