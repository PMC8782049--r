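#' Dissociation-energy descriptor for one compound and step
#'
#' Builds the regression descriptor deltaE = E(deprotonated species) -
#' E(parent species) for one dissociation step, with each charge state
#' resolved to a single energy by the active tautomer policy.  For the
#' cation->neutral step (`pKa1`) the parent is the +1 cation and the
#' product the neutral; for the neutral->anion step (`pKa2`) the parent
#' is the neutral and the product the -1 anion.  The neutral state is
#' resolved once, so the pKa1 product and the pKa2 parent are the same
#' microstate.
#'
#' @param x a [compound_set()] or a microstates data frame.
#' @param compound_id compound to build the descriptor for.
#' @param step `"pKa1"` or `"pKa2"`.
#' @param phase `"aqueous"` (default) or `"gas"`.
#' @param policy tautomer resolution policy: `"most_stable"` (default,
#'   the calibration convention) or `"boltzmann"` (ensemble effective
#'   energies; see [boltzmann_effective_energy()]).
#' @param temperature temperature in K for the Boltzmann policy.
#' @return one-row data frame: `compound_id`, `step`, `phase`, `delta_e`
#'   (kJ/mol), `parent_tautomer`, `product_tautomer`.
#' @export
compute_delta_e <- function(x, compound_id, step,
                            phase = c("aqueous", "gas"),
                            policy = c("most_stable", "boltzmann"),
                            temperature = .T_STANDARD) {
  step <- .assert_step(step)
  phase <- match.arg(phase)
  policy <- match.arg(policy)
  ms <- if (inherits(x, "compound_set")) x$microstates else x
  ms <- ms[ms$compound_id == compound_id & ms$phase == phase, , drop = FALSE]
  charges <- if (step == "pKa1") c(parent = 1L, product = 0L)
             else c(parent = 0L, product = -1L)
  resolve <- function(charge, role) {
    sub <- ms[ms$charge == charge, , drop = FALSE]
    if (!nrow(sub))
      stop(sprintf("missing-state error: compound '%s' has no %s microstate with charge %+d for %s",
                   compound_id, phase, charge, step), call. = FALSE)
    rep <- select_representative(sub)
    energy <- if (policy == "most_stable") rep$energy
              else boltzmann_effective_energy(sub, temperature)
    list(energy = energy, tautomer = rep$tautomer_id)
  }
  parent <- resolve(charges[["parent"]], "parent")
  product <- resolve(charges[["product"]], "product")
  data.frame(compound_id = compound_id, step = step, phase = phase,
             delta_e = product$energy - parent$energy,
             parent_tautomer = parent$tautomer,
             product_tautomer = product$tautomer,
             stringsAsFactors = FALSE)
}

#' Descriptors for every compound in a dataset
#'
#' @inheritParams compute_delta_e
#' @param compound_ids compounds to include (default: all in `x`).
#' @param on_missing `"error"` (default; a compound lacking a required
#'   charge state aborts the run -- no compound is silently dropped) or
#'   `"omit"` (skip such compounds with a warning naming them).
#' @return data frame with one row per computable compound, columns as in
#'   [compute_delta_e()].
#' @export
compute_descriptors <- function(x, step, phase = c("aqueous", "gas"),
                                policy = c("most_stable", "boltzmann"),
                                temperature = .T_STANDARD,
                                compound_ids = NULL,
                                on_missing = c("error", "omit")) {
  on_missing <- match.arg(on_missing)
  ms <- if (inherits(x, "compound_set")) x$microstates else x
  ids <- compound_ids %||% unique(ms$compound_id)
  rows <- list(); skipped <- character()
  for (id in ids) {
    d <- tryCatch(compute_delta_e(x, id, step, phase, policy, temperature),
                  error = function(e) e)
    if (inherits(d, "error")) {
      if (on_missing == "error") stop(d)
      skipped <- c(skipped, id)
    } else rows[[length(rows) + 1L]] <- d
  }
  if (length(skipped))
    warning("descriptor skipped for compound(s) lacking a charge state: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (!length(rows))
    return(data.frame(compound_id = character(), step = character(),
                      phase = character(), delta_e = numeric(),
                      parent_tautomer = character(),
                      product_tautomer = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write descriptors to CSV
#'
#' @param descriptors data frame from [compute_descriptors()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(descriptors, path) {
  write.csv(descriptors, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
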