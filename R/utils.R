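#' Round half away from zero at a fixed number of decimals
#'
#' Decimal rounding as used for all printed pKa values in this package:
#' ties at the last retained digit round away from zero (so 7.625 -> 7.63
#' and -0.075 -> -0.08), unlike [base::round()]'s round-half-even.  A small
#' epsilon guards against binary floating-point representations that land
#' a hair below an exact decimal tie.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(7.625, 2)   # 7.63
#' round_half_up(-0.075, 2)  # -0.08
#' @export
round_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  out <- sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
  out[!is.finite(x)] <- x[!is.finite(x)]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# match.arg wrapper giving consistent error wording for enum-like fields
.match_enum <- function(value, choices, what) {
  if (length(value) != 1L || !value %in% choices) {
    stop(sprintf("%s must be one of: %s", what,
                 paste(choices, collapse = ", ")), call. = FALSE)
  }
  value
}

.assert_step <- function(step) .match_enum(step, c("pKa1", "pKa2"), "step")
.assert_phase <- function(phase) .match_enum(phase, c("gas", "aqueous"), "phase")
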