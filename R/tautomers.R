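#' Select the representative tautomer of one charge state
#'
#' Implements the most-stable-tautomer rule: each (compound, charge,
#' phase) condition is represented by its minimum-energy microstate.
#' Exact energy ties are broken deterministically by the lexicographically
#' smallest `tautomer_id`, so the choice is invariant to input order.
#'
#' @param microstates data frame of microstates sharing one compound,
#'   charge and phase (columns as in [compound_set()]).
#' @return the selected one-row data frame.
#' @export
select_representative <- function(microstates) {
  .check_ensemble(microstates)
  ord <- order(microstates$energy, microstates$tautomer_id)
  microstates[ord[1L], , drop = FALSE]
}

#' Energy gap between the two most stable tautomers
#'
#' The gap (second-lowest minus lowest energy, kJ/mol) gauges how safe the
#' most-stable-tautomer approximation is: a large gap means the ensemble
#' is effectively a single species.  A single-tautomer ensemble has an
#' infinite gap.  A warning is raised when the gap does not exceed
#' `warn_below` (default 25 kJ/mol, the customary "substantial gap"
#' threshold).
#'
#' @inheritParams select_representative
#' @param warn_below warn when the gap is at or below this value (kJ/mol).
#' @return the gap in kJ/mol (`Inf` for a single tautomer).
#' @export
energy_gap <- function(microstates, warn_below = 25) {
  .check_ensemble(microstates)
  if (nrow(microstates) == 1L) return(Inf)
  e <- sort(microstates$energy)
  gap <- e[2L] - e[1L]
  if (gap <= warn_below) {
    warning(sprintf("small tautomer gap (%.3g kJ/mol <= %.3g) for compound '%s' (charge %+d): the most-stable-tautomer approximation may be inadequate",
                    gap, warn_below, microstates$compound_id[1L],
                    microstates$charge[1L]), call. = FALSE)
  }
  gap
}

#' Boltzmann-weighted effective energy of a tautomer ensemble
#'
#' The ensemble free energy -RT log(sum exp(-E_i/RT)), computed stably by
#' shifting by the minimum energy.  It is always at or below the minimum
#' energy and converges to it as the inter-tautomer gaps grow; with k
#' degenerate tautomers of energy E it equals E - RT log(k).  Offered as
#' an opt-in alternative to the most-stable rule for sensitivity
#' analysis.
#'
#' @inheritParams select_representative
#' @param temperature absolute temperature in K (default 298.15).
#' @return effective energy in kJ/mol.
#' @export
boltzmann_effective_energy <- function(microstates,
                                       temperature = .T_STANDARD) {
  .check_ensemble(microstates)
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop("temperature must be a single positive number (K)", call. = FALSE)
  rt <- .RGAS * temperature
  e <- microstates$energy
  emin <- min(e)
  emin - rt * log(sum(exp(-(e - emin) / rt)))
}

.check_ensemble <- function(microstates) {
  if (!is.data.frame(microstates) ||
      !all(c("compound_id", "charge", "tautomer_id", "phase", "energy")
           %in% names(microstates)))
    stop("expected a microstates data frame (compound_id, charge, tautomer_id, phase, energy)",
         call. = FALSE)
  if (!nrow(microstates))
    stop("missing-state error: empty tautomer ensemble (no microstates supplied)",
         call. = FALSE)
  for (col in c("compound_id", "charge", "phase")) {
    if (length(unique(microstates[[col]])) != 1L)
      stop(sprintf("tautomer ensemble mixes values of '%s'; supply microstates for a single compound, charge and phase",
                   col), call. = FALSE)
  }
  if (!all(is.finite(microstates$energy)))
    stop("microstate energies must be finite", call. = FALSE)
  invisible(microstates)
}
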