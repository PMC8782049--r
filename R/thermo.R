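#' Gas-phase deprotonation Gibbs energy
#'
#' The standard Gibbs energy magnitude of the gas-phase acid dissociation
#' AH -> A- + H+, computed from the free energies of the neutral and the
#' anion with the fixed proton free energy G(H+) = -26.3 kJ/mol at
#' 298.15 K:
#' `|G(A-) + G(H+) - G(AH)|`.
#' The magnitude convention matches the positive tabulated gas-phase
#' acidities (~1400-1600 kJ/mol); the reverse (association) reaction has
#' the same magnitude.  Translation-invariant: adding a constant to both
#' free energies leaves the result unchanged.
#'
#' @param g_neutral,g_anion gas-phase free energies of the neutral
#'   species and the anion (kJ/mol); vectorized.
#' @return gas-phase acidity magnitude(s) in kJ/mol.
#' @examples
#' reaction_drG(0, 1627.3)  # 1601.0
#' @export
reaction_drG <- function(g_neutral, g_anion) {
  stopifnot(is.numeric(g_neutral), is.numeric(g_anion),
            all(is.finite(g_neutral)), all(is.finite(g_anion)))
  abs(g_anion + .G_PROTON_GAS - g_neutral)
}

#' Squared correlation between experimental and calculated values
#'
#' The coefficient of determination used for method validation: the
#' squared Pearson correlation of the paired columns.  Invariant to a
#' positive linear rescaling or shift of either column.
#'
#' @param experimental,calculated paired numeric vectors, length >= 3.
#' @return R-squared in [0, 1].
#' @export
agreement_r2 <- function(experimental, calculated) {
  keep <- !is.na(experimental) & !is.na(calculated)
  experimental <- experimental[keep]; calculated <- calculated[keep]
  if (length(experimental) < 3L)
    stop("insufficient data: need at least 3 complete pairs", call. = FALSE)
  if (sd(experimental) == 0 || sd(calculated) == 0)
    stop("undefined statistic: a column has zero variance", call. = FALSE)
  cor(experimental, calculated)^2
}

#' Per-compound deviation report for gas-phase validation
#'
#' Signed differences (calculated - experimental) for a gas-phase
#' validation table, with the largest-magnitude deviator identified.
#'
#' @param records a `thermo_table` data frame (`compound_id`, `exp_drG`,
#'   `calc_drG`).
#' @return data frame `compound_id`, `exp_drG`, `calc_drG`, `diff`, with
#'   attributes `max_abs_compound` and `max_abs_diff` (both `NA` for an
#'   empty input).
#' @export
deviation_report <- function(records) {
  stopifnot(all(c("compound_id", "exp_drG", "calc_drG") %in% names(records)))
  out <- data.frame(compound_id = records$compound_id,
                    exp_drG = records$exp_drG,
                    calc_drG = records$calc_drG,
                    diff = records$calc_drG - records$exp_drG,
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    i <- which.max(abs(out$diff))
    attr(out, "max_abs_compound") <- out$compound_id[i]
    attr(out, "max_abs_diff") <- abs(out$diff[i])
  } else {
    attr(out, "max_abs_compound") <- NA_character_
    attr(out, "max_abs_diff") <- NA_real_
  }
  out
}
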