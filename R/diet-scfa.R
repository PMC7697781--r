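#' Diet composition arithmetic
#'
#' `diet_spec()` records the proximate composition of an experimental diet in
#' g/kg dry matter. `total_dietary_fiber()` sums the five fiber fractions
#' (total non-starch polysaccharides, fructans, resistant starch, Klason
#' lignin, arabinoxylan-oligosaccharides). `diet_energy_contribution()`
#' converts the macronutrients to energy with the FAO conversion factors —
#' 17 kJ/g for available carbohydrate and protein, 37 kJ/g for fat, 8 kJ/g for
#' total dietary fiber — and reports each component's share of total energy as
#' a percentage rounded to one decimal.
#'
#' @param available_carbohydrates,protein,fat,total_dietary_fiber g/kg DM.
#' @param total_nsp,fructans,resistant_starch,klason_lignin,axos optional
#'   fiber fractions, g/kg DM.
#' @return `diet_spec()` an object of class `diet_spec`.
#' @export
diet_spec <- function(available_carbohydrates = NA_real_, protein = NA_real_,
                      fat = NA_real_, total_dietary_fiber = NA_real_,
                      total_nsp = NA_real_, fructans = NA_real_,
                      resistant_starch = NA_real_, klason_lignin = NA_real_,
                      axos = NA_real_) {
  x <- list(available_carbohydrates = available_carbohydrates,
            protein = protein, fat = fat,
            total_dietary_fiber = total_dietary_fiber,
            total_nsp = total_nsp, fructans = fructans,
            resistant_starch = resistant_starch,
            klason_lignin = klason_lignin, axos = axos)
  bad <- names(x)[vapply(x, function(v) !is.na(v) && v < 0, logical(1))]
  if (length(bad))
    .stopf("diet components must be non-negative: %s", paste(bad, collapse = ", "))
  structure(x, class = "diet_spec")
}

#' @rdname diet_spec
#' @param spec a `diet_spec`.
#' @return `total_dietary_fiber()` the fiber sum in g/kg DM.
#' @export
total_dietary_fiber <- function(spec) {
  stopifnot(inherits(spec, "diet_spec"))
  fr <- c("total_nsp", "fructans", "resistant_starch", "klason_lignin", "axos")
  vals <- unlist(spec[fr])
  if (anyNA(vals))
    .stopf("fiber fraction(s) absent: %s", paste(fr[is.na(vals)], collapse = ", "))
  sum(vals)
}

#' @rdname diet_spec
#' @return `diet_energy_contribution()` a named numeric vector of percentages
#'   (`carbohydrate`, `fat`, `protein`, `fiber`), one decimal, summing to
#'   approximately 100.
#' @export
diet_energy_contribution <- function(spec) {
  stopifnot(inherits(spec, "diet_spec"))
  comp <- c(carbohydrate = spec$available_carbohydrates, protein = spec$protein,
            fat = spec$fat, fiber = spec$total_dietary_fiber)
  if (anyNA(comp))
    .stopf("macro component(s) absent: %s",
           paste(names(comp)[is.na(comp)], collapse = ", "))
  kj_per_g <- c(carbohydrate = 17, protein = 17, fat = 37, fiber = 8)
  energy <- comp * kj_per_g
  if (sum(energy) == 0) stop("zero energy: all components are zero")
  pct <- round(100 * energy / sum(energy), 1)
  pct[c("carbohydrate", "fat", "protein", "fiber")]
}

## ---------------------------------------------------------------------------
## Short-chain fatty acid panels

#' Acid vocabularies for SCFA panels
#'
#' Canonical acid names accepted per compartment. Fecal panels are measured in
#' mmol/kg wet feces, plasma panels in umol/L.
#' @export
scfa_vocabulary <- function() {
  list(
    fecal = c("formic", "acetic", "propionic", "isobutyric", "n_butyric",
              "isovaleric", "n_valeric", "isocaproic", "n_caproic",
              "heptanoic", "sorbic", "benzoic", "dl_lactic", "succinic",
              "hippuric"),
    plasma = c("acetic", "propionic", "butyric", "valeric", "isobutyric",
               "isovaleric", "succinic"))
}

#' Short-chain fatty acid concentration panel
#'
#' @param concentrations numeric matrix, samples x acids, non-negative; column
#'   names must come from the compartment's vocabulary
#'   (see [scfa_vocabulary()]).
#' @param compartment `"fecal"` or `"plasma"`.
#' @param sample_meta optional per-sample metadata carried along (sample_id,
#'   subject_id, class_label, time_point).
#' @return an object of class `scfa_panel`.
#' @export
scfa_panel <- function(concentrations, compartment = c("fecal", "plasma"),
                       sample_meta = NULL) {
  compartment <- match.arg(compartment)
  concentrations <- as.matrix(concentrations)
  storage.mode(concentrations) <- "double"
  vocab <- scfa_vocabulary()[[compartment]]
  unknown <- setdiff(colnames(concentrations), vocab)
  if (length(unknown))
    .stopf("unknown acid name(s) for %s panel: %s", compartment,
           paste(unknown, collapse = ", "))
  if (any(concentrations < 0, na.rm = TRUE))
    stop("SCFA concentrations must be non-negative")
  structure(list(concentrations = concentrations, compartment = compartment,
                 sample_meta = sample_meta),
            class = "scfa_panel")
}

#' @export
print.scfa_panel <- function(x, ...) {
  cat(sprintf("scfa_panel (%s): %d samples x %d acids\n", x$compartment,
              nrow(x$concentrations), ncol(x$concentrations)))
  invisible(x)
}

.scfa_defs <- list(
  fecal = list(
    total_scfa = c("formic", "acetic", "propionic", "isobutyric", "n_butyric",
                   "isovaleric", "n_valeric"),
    extra_organic = c("isocaproic", "n_caproic", "heptanoic", "sorbic",
                      "benzoic", "dl_lactic", "succinic", "hippuric"),
    bcfa = c("isobutyric", "isovaleric", "isocaproic"),
    apb = c("acetic", "propionic", "n_butyric")),
  plasma = list(
    total_scfa = c("acetic", "propionic", "butyric", "valeric", "isobutyric",
                   "isovaleric"),
    extra_organic = "succinic",
    bcfa = c("isobutyric", "isovaleric"),
    apb = c("acetic", "propionic", "butyric")))

#' Derived SCFA sums and proportions
#'
#' Computes per-sample aggregate concentrations: total SCFA (fecal: formic +
#' acetic + propionic + isobutyric + n-butyric + isovaleric + n-valeric;
#' plasma: acetic + propionic + butyric + valeric + isobutyric + isovaleric),
#' total organic acids (total SCFA plus the longer/other organic acids;
#' plasma: plus succinic only), branched-chain fatty acids (fecal: isobutyric +
#' isovaleric + isocaproic; plasma: isobutyric + isovaleric), and the
#' acetic + propionic + (n-)butyric subtotal (APB). Each constituent acid's
#' percentage of total SCFA and of APB is appended; proportions are `NA` when
#' the corresponding total is zero.
#'
#' @param panel an [scfa_panel()].
#' @return data.frame with one row per sample: the four totals, then
#'   `pct_total_<acid>` and `pct_apb_<acid>` columns.
#' @export
scfa_totals <- function(panel) {
  stopifnot(inherits(panel, "scfa_panel"))
  defs <- .scfa_defs[[panel$compartment]]
  cm <- panel$concentrations
  need <- unique(unlist(defs))
  absent <- setdiff(need, colnames(cm))
  if (length(absent))
    .stopf("missing required acid column(s): %s", paste(absent, collapse = ", "))

  sum_of <- function(acids) rowSums(cm[, acids, drop = FALSE])
  total_scfa <- sum_of(defs$total_scfa)
  out <- data.frame(
    total_scfa = total_scfa,
    total_organic = total_scfa + sum_of(defs$extra_organic),
    bcfa = sum_of(defs$bcfa),
    apb = sum_of(defs$apb))
  rownames(out) <- rownames(cm)

  safe_pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  for (a in defs$total_scfa)
    out[[paste0("pct_total_", a)]] <- safe_pct(cm[, a], total_scfa)
  for (a in defs$apb)
    out[[paste0("pct_apb_", a)]] <- safe_pct(cm[, a], out$apb)
  if (any(total_scfa == 0))
    .msgf("scfa_totals: %d sample(s) with zero total SCFA; proportions set to NA",
          sum(total_scfa == 0))
  out
}
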