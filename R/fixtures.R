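#' Packaged calibration and validation fixtures
#'
#' Returns the four datasets shipped with the package, transcribed
#' cell-for-cell from the published compendium (Unicode minus signs as
#' ASCII, formulas as printed -- including three apparent typographical
#' errors flagged in `compounds$formula_note`):
#' \describe{
#'   \item{table1}{a [compound_set()]: 31 heterocycles with their
#'     literature pKa records (per-source values, with `"-"` and `"N/A"`
#'     sentinels kept distinct) and external-predictor values with
#'     printed uncertainties.}
#'   \item{table2}{a `thermo_table`: experimental and computed gas-phase
#'     deprotonation Gibbs energies (kJ/mol) for six compounds.}
#'   \item{table3}{the cation->neutral (pKa1) calibration table: compound,
#'     aqueous deprotonation energy `delta_e` (kJ/mol, printed as
#'     integers), consolidated experimental value, published calculated
#'     value (numeric, or the qualitative markers `"<0"` / `"<<0"` for
#'     estimates in the poorly-measured negative range) and residual.}
#'   \item{table4}{the analogous neutral->anion (pKa2) table.}
#' }
#' In `table3`/`table4` the published fit membership is exposed as
#' `in_fit`: rows carrying a numeric residual are the (n = 17 / n = 12)
#' calibration points.
#'
#' @return a named list with elements `table1`, `table2`, `table3`,
#'   `table4`.
#' @export
fixture_tables <- function() {
  ext <- function(f) system.file("extdata", f, package = "pkaqsar",
                                 mustWork = TRUE)
  list(table1 = load_dataset(ext("table1.csv")),
       table2 = load_dataset(ext("table2.csv")),
       table3 = .load_calibration_csv(ext("table3.csv"), "pKa1"),
       table4 = .load_calibration_csv(ext("table4.csv"), "pKa2"))
}

.load_calibration_csv <- function(path, step) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  expcol <- paste0("exp_", tolower(step))
  calcol <- paste0("calc_", tolower(step))
  calc_raw <- trimws(df[[calcol]])
  out <- data.frame(
    compound_id = df$compound_id,
    step = step,
    delta_e = .parse_numeric_column(df$delta_e, "delta_e", path,
                                    sentinels = character()),
    exp = .parse_numeric_column(df[[expcol]], expcol, path),
    calc = .parse_numeric_column(ifelse(calc_raw %in% c("<0", "<<0"),
                                        NA_character_, calc_raw),
                                 calcol, path),
    qualitative = ifelse(calc_raw %in% c("<0", "<<0"), calc_raw, "numeric"),
    residual = .parse_numeric_column(df$residual, "residual", path),
    stringsAsFactors = FALSE)
  out$in_fit <- !is.na(out$residual)
  class(out) <- c("pka_calibration_table", "data.frame")
  out
}

#' Calibration points of a fixture table
#'
#' Filters a calibration table to the complete (descriptor, experimental)
#' pairs used for fitting: rows with a numeric experimental value whose
#' published estimate is itself numeric (compounds whose estimates fall in
#' the qualitative negative range carry no residual and are excluded, per
#' the published convention).
#'
#' @param table a `table3`/`table4`-style data frame from
#'   [fixture_tables()].
#' @return the subset of rows entering the fit.
#' @export
calibration_points <- function(table) {
  stopifnot(all(c("delta_e", "exp") %in% names(table)))
  keep <- !is.na(table$delta_e) & !is.na(table$exp)
  if ("in_fit" %in% names(table)) keep <- keep & table$in_fit
  table[keep, , drop = FALSE]
}
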