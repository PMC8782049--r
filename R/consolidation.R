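#' Consolidate multi-source literature pKa values
#'
#' Collapses the literature reports for one compound and step into the
#' single experimental value used for calibration.  The default policy is
#' the arithmetic mean of the *distinct* reported values (the same number
#' cited by several sources counts once), rounded half-up to `digits`
#' decimals; `"median"` and `"first"` (first-cited value) are available as
#' alternatives.
#'
#' @param values numeric vector of reported pKa values (may be empty or
#'   all-NA, e.g. for sentinel rows).
#' @param policy `"mean"` (default), `"median"` or `"first"`.
#' @param digits decimals kept in the consolidated value (default 2, the
#'   precision of the source compendium); `NULL` keeps full precision.
#' @return the consolidated value, or `NA_real_` when no measured value
#'   is available.
#' @examples
#' consolidate_pka(c(4.32, 4.58, 4.6))     # 4.50
#' consolidate_pka(c(7.15, 6.99, 6.99))    # 7.07 (duplicate counted once)
#' @export
consolidate_pka <- function(values, policy = c("mean", "median", "first"),
                            digits = 2) {
  policy <- match.arg(policy)
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  out <- switch(policy,
                mean = mean(unique(values)),
                median = stats::median(unique(values)),
                first = values[1L])
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Consolidated experimental table for a dataset
#'
#' Applies [consolidate_pka()] per compound to the literature records of a
#' [compound_set()] for one dissociation step.  Sentinel rows are carried
#' through: `"not_reported"` compounds get `NA` (they may still receive
#' predictions), `"no_proton"` compounds are marked as having no such
#' dissociation.
#'
#' @param dataset a [compound_set()].
#' @param step `"pKa1"` or `"pKa2"`.
#' @inheritParams consolidate_pka
#' @return data frame: `compound_id`, `step`, `exp` (consolidated value or
#'   `NA`), `n_sources`, `status`.
#' @export
consolidate_dataset <- function(dataset, step,
                                policy = c("mean", "median", "first"),
                                digits = 2) {
  stopifnot(inherits(dataset, "compound_set"))
  step <- .assert_step(step)
  policy <- match.arg(policy)
  lit <- dataset$literature[dataset$literature$step == step, , drop = FALSE]
  ids <- dataset$compounds$compound_id
  rows <- lapply(ids, function(id) {
    sub <- lit[lit$compound_id == id, , drop = FALSE]
    measured <- sub[sub$status == "measured", , drop = FALSE]
    status <- if (nrow(measured)) "measured"
              else if (any(sub$status == "no_proton")) "no_proton"
              else "not_reported"
    data.frame(compound_id = id, step = step,
               exp = consolidate_pka(measured$value, policy, digits),
               n_sources = nrow(measured), status = status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
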