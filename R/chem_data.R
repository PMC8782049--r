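#' Compound datasets: microstates, literature records, external predictions
#'
#' A `compound_set` bundles everything known about a collection of
#' compounds:
#' \describe{
#'   \item{compounds}{one row per compound: `compound_id` (a lowercase
#'     hyphenated slug), `name`, `formula`, `formula_note` (transcription
#'     flags for formulas stored as printed in the source compendium).}
#'   \item{microstates}{one row per (compound, charge, tautomer, phase)
#'     with its electronic `energy` in kJ/mol.  `charge` is -1, 0 or +1;
#'     `phase` is `"gas"` or `"aqueous"`.}
#'   \item{literature}{experimental pKa records: `compound_id`, `step`
#'     (`"pKa1"` cation->neutral, `"pKa2"` neutral->anion), `value`,
#'     `source`, and a `status` distinguishing a measured value from the
#'     two sentinels used in the compendium: `"not_reported"` (no
#'     measurement found; a prediction is still meaningful) and
#'     `"no_proton"` (the step does not exist for the compound).}
#'   \item{external}{predictions from an external empirical package:
#'     `compound_id`, `step`, `value`, `uncertainty`.}
#' }
#'
#' @param compounds,microstates,literature,external data frames as
#'   described above; missing components default to empty frames.
#' @return an object of class `compound_set`.
#' @seealso [load_dataset()], [fixture_tables()]
#' @export
compound_set <- function(compounds,
                         microstates = NULL,
                         literature = NULL,
                         external = NULL) {
  compounds <- .validate_compounds(compounds)
  microstates <- .validate_microstates(microstates %||% .empty_microstates())
  literature <- .validate_literature(literature %||% .empty_literature())
  external <- .validate_external(external %||% .empty_external())
  structure(list(compounds = compounds, microstates = microstates,
                 literature = literature, external = external),
            class = "compound_set")
}

#' @export
print.compound_set <- function(x, ...) {
  cat(sprintf("<compound_set> %d compounds, %d microstates, %d literature pKa records, %d external predictions\n",
              nrow(x$compounds), nrow(x$microstates),
              nrow(x$literature), nrow(x$external)))
  invisible(x)
}

#' @export
length.compound_set <- function(x) nrow(x$compounds)

.empty_microstates <- function() {
  data.frame(compound_id = character(), charge = integer(),
              tautomer_id = character(), phase = character(),
              energy = numeric(), stringsAsFactors = FALSE)
}
.empty_literature <- function() {
  data.frame(compound_id = character(), step = character(),
              value = numeric(), source = character(),
              status = character(), stringsAsFactors = FALSE)
}
.empty_external <- function() {
  data.frame(compound_id = character(), step = character(),
              value = numeric(), uncertainty = numeric(),
              stringsAsFactors = FALSE)
}

.validate_compounds <- function(df) {
  need <- c("compound_id", "name", "formula")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("compounds table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"formula_note" %in% names(df)) df$formula_note <- rep("", nrow(df))
  if (anyDuplicated(df$compound_id))
    stop("duplicate compound_id in compounds table: ",
         paste(unique(df$compound_id[duplicated(df$compound_id)]),
               collapse = ", "), call. = FALSE)
  df
}

.validate_microstates <- function(df) {
  need <- c("compound_id", "charge", "tautomer_id", "phase", "energy")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("microstates table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$charge <- as.integer(df$charge)
  if (nrow(df)) {
    if (!all(df$charge %in% c(-1L, 0L, 1L)))
      stop("microstate charge must be -1, 0 or +1", call. = FALSE)
    if (!all(df$phase %in% c("gas", "aqueous")))
      stop("microstate phase must be 'gas' or 'aqueous'", call. = FALSE)
    if (!all(is.finite(df$energy)))
      stop("microstate energies must be finite", call. = FALSE)
    key <- paste(df$compound_id, df$charge, df$tautomer_id, df$phase)
    if (anyDuplicated(key))
      stop("duplicate microstate key (compound_id, charge, tautomer_id, phase): ",
           key[duplicated(key)][1L], call. = FALSE)
  }
  df
}

.validate_literature <- function(df) {
  need <- c("compound_id", "step", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("literature table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"source" %in% names(df)) df$source <- rep("", nrow(df))
  if (!"status" %in% names(df))
    df$status <- ifelse(is.na(df$value), "not_reported", "measured")
  if (nrow(df)) {
    if (!all(df$step %in% c("pKa1", "pKa2")))
      stop("literature step must be 'pKa1' or 'pKa2'", call. = FALSE)
    if (!all(df$status %in% c("measured", "not_reported", "no_proton")))
      stop("literature status must be measured/not_reported/no_proton",
           call. = FALSE)
    if (any(df$status == "measured" & is.na(df$value)))
      stop("measured literature record lacks a value", call. = FALSE)
  }
  df
}

# Plausibility bound for experimental compendium records.  Applied when
# parsing the compendium format only: synthetic datasets may legitimately
# carry model-implied values outside the measurable window.
.check_pka_range <- function(df, file) {
  bad <- df$status == "measured" & (df$value < -10 | df$value > 25)
  if (any(bad))
    stop(sprintf("'%s': measured literature pKa outside the plausible range [-10, 25] for: %s",
                 file, paste(unique(df$compound_id[bad]), collapse = ", ")),
         call. = FALSE)
  invisible(df)
}

.validate_external <- function(df) {
  need <- c("compound_id", "step", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("external table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"uncertainty" %in% names(df)) df$uncertainty <- rep(NA_real_, nrow(df))
  if (nrow(df) && !all(df$step %in% c("pKa1", "pKa2")))
    stop("external step must be 'pKa1' or 'pKa2'", call. = FALSE)
  df
}

# ---------------------------------------------------------------------------
# parsing helpers

# Parse a character column to numeric, treating "", "-" and "N/A" as NA and
# failing loudly (with file, line and column) on anything else non-numeric.
# `line_offset` accounts for the header row so reported lines match the file.
.parse_numeric_column <- function(x, column, file, line_offset = 1L,
                                  sentinels = c("", "-", "N/A")) {
  x <- trimws(as.character(x))
  x[x %in% sentinels] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("parse error in '%s' at line %d, column '%s': cannot interpret %s as a number",
                 file, bad[1L] + line_offset, column, dQuote(x[bad[1L]])),
         call. = FALSE)
  }
  out
}

#' Read a microstate energy table
#'
#' Expects columns `compound_id, charge, tautomer_id, phase, energy` and an
#' optional `unit` column (`"kJ/mol"`, the internal unit, or `"hartree"`,
#' converted on load by 2625.5 kJ/mol per hartree).
#'
#' @param path path to a CSV file.
#' @return a validated microstates data frame with energies in kJ/mol.
#' @export
read_microstates <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!nrow(df)) return(.empty_microstates())
  df$charge <- as.integer(.parse_numeric_column(df$charge, "charge", path,
                                                sentinels = character()))
  df$energy <- .parse_numeric_column(df$energy, "energy", path,
                                     sentinels = character())
  if ("unit" %in% names(df)) {
    unit <- ifelse(trimws(df$unit) == "", "kJ/mol", trimws(df$unit))
    if (!all(unit %in% c("kJ/mol", "hartree")))
      stop(sprintf("parse error in '%s', column 'unit': units must be 'kJ/mol' or 'hartree'",
                   path), call. = FALSE)
    df$energy <- ifelse(unit == "hartree", df$energy * .HARTREE_KJMOL, df$energy)
    df$unit <- NULL
  }
  .validate_microstates(df)
}

#' Load a dataset from CSV or JSON
#'
#' Dispatches on the file's schema: a wide compound compendium (one row per
#' compound with semicolon-separated literature values) or a per-component
#' schema becomes a [compound_set()]; a gas-phase thermochemistry table
#' (columns `exp_drG`, `calc_drG`) becomes a `thermo_table` data frame.
#' A header-only file yields the corresponding empty object.
#'
#' @param path a CSV/JSON file, or a directory holding `compounds.csv`,
#'   `microstates.csv`, `pka.csv`, `external.csv`.
#' @param format `"csv"` or `"json"`; inferred from the file extension when
#'   omitted.
#' @return a `compound_set` or a `thermo_table` data frame.
#' @export
load_dataset <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "csv"
              else if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (format == "json") return(.load_json(path))
  if (dir.exists(path)) return(.load_csv_dir(path))
  header <- names(read.csv(path, nrows = 1, stringsAsFactors = FALSE,
                           check.names = FALSE))
  if (all(c("exp_drG", "calc_drG") %in% header)) {
    .load_thermo_csv(path)
  } else if ("pka1_values" %in% header || "pka2_values" %in% header) {
    .load_compendium_csv(path)
  } else if (all(c("charge", "tautomer_id") %in% header)) {
    ms <- read_microstates(path)
    ids <- unique(ms$compound_id)
    compound_set(data.frame(compound_id = ids, name = ids,
                            formula = "", stringsAsFactors = FALSE),
                 microstates = ms)
  } else {
    stop(sprintf("unrecognised CSV schema in '%s' (columns: %s)",
                 path, paste(header, collapse = ", ")), call. = FALSE)
  }
}

.load_thermo_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  out <- data.frame(compound_id = as.character(df$compound_id),
                    stringsAsFactors = FALSE)
  for (col in c("exp_drG", "calc_drG", "calc_dE")) {
    out[[col]] <- if (col %in% names(df))
      .parse_numeric_column(df[[col]], col, path, sentinels = character())
    else rep(NA_real_, nrow(df))
  }
  if (anyDuplicated(out$compound_id))
    stop("duplicate compound_id in thermochemistry table", call. = FALSE)
  class(out) <- c("thermo_table", "data.frame")
  out
}

# Wide one-row-per-compound compendium with cells holding either a sentinel
# ("-" no measurement, "N/A" no dissociable proton) or ";"-separated values.
.load_compendium_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!nrow(df)) return(compound_set(.validate_compounds(
    data.frame(compound_id = character(), name = character(),
               formula = character(), stringsAsFactors = FALSE))))
  compounds <- data.frame(compound_id = df$compound_id, name = df$name,
                          formula = df$formula,
                          formula_note = df$formula_note %||% "",
                          stringsAsFactors = FALSE)

  lit <- list(); ext <- list()
  for (i in seq_len(nrow(df))) {
    id <- df$compound_id[i]
    for (step in c("pKa1", "pKa2")) {
      vcol <- paste0(tolower(step), "_values")
      scol <- paste0(tolower(step), "_sources")
      cell <- trimws(df[[vcol]][i])
      if (cell %in% c("", "-")) {
        lit[[length(lit) + 1L]] <- data.frame(
          compound_id = id, step = step, value = NA_real_, source = "",
          status = "not_reported", stringsAsFactors = FALSE)
      } else if (cell == "N/A") {
        lit[[length(lit) + 1L]] <- data.frame(
          compound_id = id, step = step, value = NA_real_, source = "",
          status = "no_proton", stringsAsFactors = FALSE)
      } else {
        vals <- .parse_numeric_column(strsplit(cell, ";", fixed = TRUE)[[1L]],
                                      vcol, path, line_offset = i,
                                      sentinels = character())
        srcs <- strsplit(trimws(df[[scol]][i] %||% ""), ";", fixed = TRUE)[[1L]]
        length(srcs) <- length(vals)
        lit[[length(lit) + 1L]] <- data.frame(
          compound_id = id, step = step, value = vals,
          source = ifelse(is.na(srcs), "", srcs),
          status = "measured", stringsAsFactors = FALSE)
      }
      acol <- paste0("acd_", tolower(step))
      ucol <- paste0(acol, "_unc")
      aval <- .parse_numeric_column(df[[acol]][i], acol, path, line_offset = i)
      if (!is.na(aval)) {
        ext[[length(ext) + 1L]] <- data.frame(
          compound_id = id, step = step, value = aval,
          uncertainty = .parse_numeric_column(df[[ucol]][i], ucol, path,
                                              line_offset = i),
          stringsAsFactors = FALSE)
      }
    }
  }
  literature <- .check_pka_range(do.call(rbind, lit), path)
  compound_set(compounds, literature = literature,
               external = if (length(ext)) do.call(rbind, ext) else NULL)
}

.load_csv_dir <- function(path) {
  fp <- function(f) file.path(path, f)
  compounds <- if (file.exists(fp("compounds.csv")))
    read.csv(fp("compounds.csv"), stringsAsFactors = FALSE)
  else stop("directory dataset lacks compounds.csv: ", path, call. = FALSE)
  ms <- if (file.exists(fp("microstates.csv"))) read_microstates(fp("microstates.csv"))
  lit <- if (file.exists(fp("pka.csv"))) {
    df <- read.csv(fp("pka.csv"), stringsAsFactors = FALSE,
                   colClasses = "character")
    if (nrow(df)) df$value <- .parse_numeric_column(df$value, "value", fp("pka.csv"))
    df
  }
  ext <- if (file.exists(fp("external.csv"))) {
    df <- read.csv(fp("external.csv"), stringsAsFactors = FALSE,
                   colClasses = "character")
    if (nrow(df)) {
      df$value <- .parse_numeric_column(df$value, "value", fp("external.csv"))
      df$uncertainty <- .parse_numeric_column(df$uncertainty, "uncertainty",
                                              fp("external.csv"))
    }
    df
  }
  compound_set(compounds, microstates = ms, literature = lit, external = ext)
}

.load_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.null(obj$exp_drG) || identical(obj$type, "thermo_table")) {
    df <- as.data.frame(obj$records %||% obj, stringsAsFactors = FALSE)
    class(df) <- c("thermo_table", "data.frame")
    return(df)
  }
  as_df <- function(x, empty) {
    if (is.null(x) || (is.data.frame(x) && !nrow(x)) || !length(x)) empty
    else as.data.frame(x, stringsAsFactors = FALSE)
  }
  compound_set(as_df(obj$compounds,
                     data.frame(compound_id = character(), name = character(),
                                formula = character(), stringsAsFactors = FALSE)),
               microstates = as_df(obj$microstates, .empty_microstates()),
               literature = as_df(obj$literature, .empty_literature()),
               external = as_df(obj$external, .empty_external()))
}

#' Write a dataset to CSV or JSON
#'
#' CSV output for a `compound_set` is a directory of component files
#' (`compounds.csv`, `microstates.csv`, `pka.csv`, `external.csv`); JSON
#' output is a single file mirroring the same schema.  Floats are written
#' at full precision so that a write/read round trip is exact to well
#' below 1e-9.
#'
#' @param x a `compound_set` or `thermo_table`.
#' @param path output directory (CSV compound_set) or file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- if (inherits(x, "thermo_table"))
      list(type = "thermo_table", records = as.data.frame(x))
    else unclass(x)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    return(invisible(path))
  }
  if (inherits(x, "thermo_table")) {
    write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  stopifnot(inherits(x, "compound_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) {
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(v) {
      out <- formatC(v, digits = 17, format = "g")
      out[is.na(v)] <- ""
      out
    })
    write.csv(df, file.path(path, f), row.names = FALSE)
  }
  wr(x$compounds, "compounds.csv")
  wr(x$microstates, "microstates.csv")
  wr(x$literature, "pka.csv")
  wr(x$external, "external.csv")
  invisible(path)
}
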