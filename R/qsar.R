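#' Fit a univariate pKa QSAR calibration
#'
#' Ordinary least squares for the linear free-energy relationship
#' `pKa = slope * deltaE + intercept`, computed in closed form together
#' with the full set of simple-regression diagnostics:
#' \itemize{
#'   \item coefficient standard errors with n - 2 degrees of freedom,
#'   \item `r_squared = 1 - SSE/SST`,
#'   \item residual standard error `s = sqrt(SSE/(n - 2))`,
#'   \item Fisher statistic `f_stat = (n - 2) * R2 / (1 - R2)` (the
#'     one-regressor ANOVA F with (1, n - 2) degrees of freedom).
#' }
#' The fitted line passes through the sample means by construction and
#' residuals sum to zero.
#'
#' @param formula a two-sided formula, response ~ descriptor (e.g.
#'   `pka ~ delta_e`).
#' @param data data frame holding the formula variables; rows with a
#'   missing response or descriptor are dropped.
#' @param step optional dissociation step label (`"pKa1"`/`"pKa2"`)
#'   carried into predictions and reports.
#' @param qualitative_cut boundary between the qualitative markers for
#'   negative estimates: values in [cut, 0) report `"<0"`, values below
#'   the cut `"<<0"` (default -7; see [classify_pka()]).
#' @return an object of class `pka_qsar` with components `coefficients`,
#'   `slope`, `intercept`, `slope_se`, `intercept_se`, `n`, `r_squared`,
#'   `s`, `f_stat`, `fitted.values`, `residuals`, `model`.
#' @seealso [published_model()] for the published calibration
#'   coefficients, [predict.pka_qsar()], [build_report()].
#' @examples
#' fit <- pka_qsar(exp ~ delta_e, calibration_points(fixture_tables()$table4),
#'                 step = "pKa2")
#' summary(fit)
#' @export
pka_qsar <- function(formula, data, step = NULL, qualitative_cut = -7) {
  if (!is.null(step)) step <- .assert_step(step)
  mf <- model.frame(formula, data, na.action = stats::na.omit)
  if (ncol(mf) != 2L)
    stop("formula must have exactly one response and one descriptor",
         call. = FALSE)
  y <- model.response(mf)
  x <- mf[[2L]]
  n <- length(x)
  if (n < 3L)
    stop(sprintf("insufficient data: %d complete point(s), need at least 3", n),
         call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0)
    stop("fit error: descriptor has zero variance", call. = FALSE)

  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- slope * x + intercept
  res <- y - fitted
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  s2 <- sse / (n - 2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_

  obj <- structure(list(
    coefficients = setNames(c(intercept, slope),
                            c("(Intercept)", names(mf)[2L])),
    slope = slope, intercept = intercept,
    slope_se = sqrt(s2 / sxx),
    intercept_se = sqrt(s2 * (1 / n + mean(x)^2 / sxx)),
    n = n, r_squared = r2, s = sqrt(s2),
    f_stat = if (!is.na(r2) && r2 < 1) (n - 2) * r2 / (1 - r2) else Inf,
    fitted.values = fitted, residuals = res,
    model = data.frame(x = x, y = y),
    xname = names(mf)[2L], yname = names(mf)[1L],
    step = step, qualitative_cut = qualitative_cut,
    source = "fitted", call = match.call()),
    class = "pka_qsar")
  obj
}

#' Calibration from explicit coefficients
#'
#' Wraps externally supplied slope/intercept pairs (for instance the
#' published calibration equations) in a `pka_qsar` object usable with
#' [predict.pka_qsar()] and [build_report()].  Diagnostics that require
#' the underlying data are `NA`.
#'
#' @param slope,intercept coefficients of `pKa = slope * deltaE +
#'   intercept` (slope in pKa per kJ/mol).
#' @inheritParams pka_qsar
#' @return a `pka_qsar` object.
#' @export
pka_calibration <- function(slope, intercept, step = NULL,
                            qualitative_cut = -7) {
  stopifnot(is.finite(slope), is.finite(intercept))
  if (!is.null(step)) step <- .assert_step(step)
  structure(list(
    coefficients = setNames(c(intercept, slope), c("(Intercept)", "delta_e")),
    slope = slope, intercept = intercept,
    slope_se = NA_real_, intercept_se = NA_real_,
    n = NA_integer_, r_squared = NA_real_, s = NA_real_, f_stat = NA_real_,
    fitted.values = NULL, residuals = NULL, model = NULL,
    xname = "delta_e", yname = "pka",
    step = step, qualitative_cut = qualitative_cut,
    source = "explicit", call = match.call()),
    class = "pka_qsar")
}

#' Published calibration equations
#'
#' The reported aqueous-phase calibrations for the two dissociation
#' steps: `pKa1 = -0.131 * deltaE - 151.54` (reported n = 17, R2 = 0.965,
#' s = 1.25) and `pKa2 = -0.141 * deltaE - 159.42` (reported n = 12,
#' R2 = 0.962, s = 0.612), with deltaE in kJ/mol.
#'
#' @param step `"pKa1"` or `"pKa2"`.
#' @return a `pka_qsar` object built by [pka_calibration()].
#' @export
published_model <- function(step) {
  step <- .assert_step(step)
  if (step == "pKa1") pka_calibration(-0.131, -151.54, "pKa1")
  else pka_calibration(-0.141, -159.42, "pKa2")
}

#' @export
coef.pka_qsar <- function(object, ...) object$coefficients

#' @export
residuals.pka_qsar <- function(object, ...) object$residuals

#' @export
fitted.pka_qsar <- function(object, ...) object$fitted.values

#' Predict pKa values from a calibration
#'
#' @param object a `pka_qsar` object.
#' @param newdata descriptor values: a numeric vector of deltaE (kJ/mol)
#'   or a data frame containing the descriptor column; omitted, the
#'   fitted values are returned.
#' @param ... unused.
#' @return unrounded predicted pKa values (see [pka_predict()] for the
#'   rounded/qualitative report form).
#' @export
predict.pka_qsar <- function(object, newdata, ...) {
  if (missing(newdata) || is.null(newdata)) {
    if (is.null(object$fitted.values))
      stop("this calibration has no training data; supply newdata",
           call. = FALSE)
    return(object$fitted.values)
  }
  x <- if (is.data.frame(newdata)) {
    if (!object$xname %in% names(newdata))
      stop(sprintf("newdata lacks descriptor column '%s'", object$xname),
           call. = FALSE)
    newdata[[object$xname]]
  } else as.numeric(newdata)
  object$slope * x + object$intercept
}

#' Qualitative classification of a pKa estimate
#'
#' Estimates in the experimentally ill-characterised negative range are
#' reported qualitatively rather than numerically: `"numeric"` for values
#' at or above 0, `"<0"` (modestly negative) for values in [cut, 0), and
#' `"<<0"` (significantly negative) below the cut.  The default cut of -7
#' separates all published qualitative cases.
#'
#' @param value numeric pKa estimate(s).
#' @param cut boundary between `"<0"` and `"<<0"` (default -7).
#' @return character vector in `{"numeric", "<0", "<<0"}`.
#' @export
classify_pka <- function(value, cut = -7) {
  ifelse(is.na(value), NA_character_,
         ifelse(value >= 0, "numeric", ifelse(value >= cut, "<0", "<<0")))
}

#' Rounded predictions with the qualitative convention
#'
#' @param object a `pka_qsar` object.
#' @param delta_e numeric descriptor values (kJ/mol).
#' @param compound_id optional compound labels.
#' @param digits decimals in the reported value (default 2).
#' @return data frame: `compound_id` (if given), `delta_e`, `pka`
#'   (predicted value rounded half-up), `qualitative`, `display` (the
#'   table cell: the rounded number, or `"<0"`/`"<<0"`).
#' @export
pka_predict <- function(object, delta_e, compound_id = NULL, digits = 2) {
  stopifnot(inherits(object, "pka_qsar"))
  raw <- predict(object, delta_e)
  qual <- classify_pka(raw, object$qualitative_cut)
  val <- round_half_up(raw, digits)
  out <- data.frame(delta_e = delta_e, pka = val, qualitative = qual,
                    display = ifelse(qual == "numeric",
                                     formatC(val, format = "f", digits = digits),
                                     qual),
                    stringsAsFactors = FALSE)
  if (!is.null(compound_id)) out <- cbind(compound_id = compound_id, out)
  out
}

#' Residual of a prediction
#'
#' `experimental - predicted`, rounded half-up to `digits` decimals.
#' A missing experimental value yields `NA` (absent), never zero.
#'
#' @param experimental,predicted numeric vectors.
#' @param digits decimals (default 2).
#' @return numeric vector of residuals.
#' @export
pka_residual <- function(experimental, predicted, digits = 2) {
  round_half_up(experimental - predicted, digits)
}

#' Agreement regression against an external predictor
#'
#' Regresses experimental pKa values on the predictions of an external
#' package using the same closed-form machinery as [pka_qsar()]
#' (`experimental = slope * external + intercept`).
#'
#' @param external,experimental paired numeric vectors; incomplete pairs
#'   are dropped.
#' @inheritParams pka_qsar
#' @return a `pka_qsar` object (descriptor = external prediction).
#' @export
external_agreement <- function(external, experimental, step = NULL) {
  pka_qsar(experimental ~ external,
           data.frame(external = external, experimental = experimental),
           step = step)
}

#' Result table for one dissociation step
#'
#' Mirrors the published per-step result tables: one row per compound
#' with the descriptor, the consolidated experimental value (or `NA`),
#' the calculated value under the calibration (numeric, or a qualitative
#' marker for negative-range estimates) and the residual (absent when
#' either side is non-numeric).
#'
#' @param data data frame with columns `compound_id`, `delta_e` and
#'   (optionally) `exp`.
#' @param model a `pka_qsar` calibration.
#' @param digits decimals for reported values (default 2).
#' @param flag_outliers if `TRUE`, adds a logical `outlier` column
#'   marking fitted-sample residuals whose externally studentized value
#'   exceeds 2.5 in magnitude (an alerting annotation only; no point is
#'   removed).
#' @return data frame: `compound_id`, `delta_e`, `exp`, `calc`,
#'   `qualitative`, `display`, `residual` (+ `outlier` when requested).
#' @export
build_report <- function(data, model, digits = 2, flag_outliers = FALSE) {
  stopifnot(inherits(model, "pka_qsar"))
  if (!nrow(data)) {
    out <- data.frame(compound_id = character(), delta_e = numeric(),
                      exp = numeric(), calc = numeric(),
                      qualitative = character(), display = character(),
                      residual = numeric(), stringsAsFactors = FALSE)
    if (flag_outliers) out$outlier <- logical()
    return(out)
  }
  exp <- if ("exp" %in% names(data)) data$exp else rep(NA_real_, nrow(data))
  pred <- pka_predict(model, data$delta_e, digits = digits)
  calc <- ifelse(pred$qualitative == "numeric", pred$pka, NA_real_)
  residual <- ifelse(is.na(exp) | is.na(calc), NA_real_,
                     pka_residual(exp, predict(model, data$delta_e), digits))
  out <- data.frame(compound_id = data$compound_id, delta_e = data$delta_e,
                    exp = exp, calc = calc, qualitative = pred$qualitative,
                    display = pred$display, residual = residual,
                    stringsAsFactors = FALSE)
  if (flag_outliers) out$outlier <- .studentized_flag(out, model)
  out
}

# Externally studentized residuals of the complete rows under `model`'s own
# fit geometry; used only to annotate reports.
.studentized_flag <- function(report, model, threshold = 2.5) {
  flag <- rep(NA, nrow(report))
  idx <- which(!is.na(report$exp) & !is.na(report$calc))
  if (length(idx) < 4L) return(flag)
  x <- report$delta_e[idx]
  y <- report$exp[idx]
  fit <- pka_qsar(y ~ x, data.frame(x = x, y = y))
  n <- fit$n
  h <- 1 / n + (x - mean(x))^2 / sum((x - mean(x))^2)
  r <- fit$residuals
  s2 <- sum(r^2) / (n - 2)
  # leave-one-out variance estimate
  s2i <- pmax((s2 * (n - 2) - r^2 / (1 - h)) / (n - 3), .Machine$double.eps)
  t <- r / sqrt(s2i * (1 - h))
  flag[idx] <- abs(t) > threshold
  flag
}

#' Leave-one-out cross-validation of a calibration
#'
#' Closed-form leave-one-out (PRESS) residuals `e_i / (1 - h_i)` for a
#' fitted calibration, offered as a quick predictive-quality check.
#'
#' @param object a fitted `pka_qsar` object.
#' @return list with `residuals` (LOO prediction errors), `press`
#'   (their sum of squares) and `rmse` (root mean square LOO error).
#' @export
loo_cv <- function(object) {
  stopifnot(inherits(object, "pka_qsar"))
  if (is.null(object$model))
    stop("leave-one-out requires a fitted calibration", call. = FALSE)
  x <- object$model$x
  h <- 1 / object$n + (x - mean(x))^2 / sum((x - mean(x))^2)
  loo <- object$residuals / (1 - h)
  list(residuals = loo, press = sum(loo^2), rmse = sqrt(mean(loo^2)))
}

#' @export
print.pka_qsar <- function(x, ...) {
  lbl <- x$step %||% "pKa"
  cat(sprintf("%s QSAR calibration (%s)\n", lbl,
              if (x$source == "fitted") "fitted" else "explicit coefficients"))
  cat(sprintf("  %s = %.4g * %s %+.4g\n", lbl, x$slope, x$xname, x$intercept))
  if (!is.na(x$n))
    cat(sprintf("  n = %d, R2 = %.3f, s = %.3f, F = %.1f\n",
                x$n, x$r_squared, x$s, x$f_stat))
  invisible(x)
}

#' @export
summary.pka_qsar <- function(object, ...) {
  structure(list(model = object), class = "summary.pka_qsar")
}

#' @export
print.summary.pka_qsar <- function(x, ...) {
  m <- x$model
  print(m)
  if (!is.na(m$n)) {
    tval <- m$slope / m$slope_se
    cat(sprintf("  slope     %10.5f  (SE %.5f)\n", m$slope, m$slope_se))
    cat(sprintf("  intercept %10.3f  (SE %.3f)\n", m$intercept, m$intercept_se))
    cat(sprintf("  slope t = %.2f on %d df (p = %.3g)\n",
                tval, m$n - 2L, 2 * pt(-abs(tval), m$n - 2L)))
  }
  invisible(x)
}

#' Confidence intervals for calibration coefficients
#'
#' @param object a fitted `pka_qsar` object.
#' @param parm coefficients to include (default: both).
#' @param level confidence level (default 0.95).
#' @param ... unused.
#' @return matrix of lower/upper bounds.
#' @export
confint.pka_qsar <- function(object, parm = NULL, level = 0.95, ...) {
  if (is.na(object$n))
    stop("confidence intervals require a fitted calibration", call. = FALSE)
  tq <- qt(1 - (1 - level) / 2, object$n - 2L)
  est <- c(object$intercept, object$slope)
  se <- c(object$intercept_se, object$slope_se)
  out <- cbind(est - tq * se, est + tq * se)
  dimnames(out) <- list(names(object$coefficients),
                        sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                   1 - (1 - level) / 2)))
  if (!is.null(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Calibration scatter plot
#'
#' @param x a fitted `pka_qsar` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pka_qsar <- function(x, ...) {
  if (is.null(x$model))
    stop("plotting requires a fitted calibration", call. = FALSE)
  lbl <- x$step %||% x$yname
  graphics::plot(x$model$x, x$model$y,
                 xlab = sprintf("%s (kJ/mol)", x$xname),
                 ylab = sprintf("experimental %s", lbl), ...)
  graphics::abline(a = x$intercept, b = x$slope)
  invisible(x)
}

#' Simulate responses from a fitted calibration
#'
#' Draws new response vectors at the calibration's own descriptor values,
#' adding Gaussian noise with the fitted residual standard error.
#'
#' @param object a fitted `pka_qsar` object.
#' @param nsim number of response vectors.
#' @param seed optional seed passed to [set.seed()].
#' @param ... unused.
#' @return data frame with `nsim` columns of simulated responses.
#' @export
simulate.pka_qsar <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$model))
    stop("simulation requires a fitted calibration", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  out <- as.data.frame(replicate(nsim, mu + rnorm(length(mu), 0, object$s)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Serialize a calibration to JSON
#'
#' Writes slope, intercept, diagnostics and the step label; readable back
#' with [read_model()].
#'
#' @param object a `pka_qsar` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(object, path) {
  stopifnot(inherits(object, "pka_qsar"))
  fields <- object[c("slope", "intercept", "slope_se", "intercept_se",
                     "n", "r_squared", "s", "f_stat", "step",
                     "qualitative_cut", "source")]
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @return for `read_model`, the reconstructed `pka_qsar` object (an
#'   explicit-coefficient calibration carrying the stored diagnostics).
#' @export
read_model <- function(path) {
  f <- jsonlite::fromJSON(path)
  obj <- pka_calibration(f$slope, f$intercept, f$step %||% NULL,
                         f$qualitative_cut %||% -7)
  for (nm in c("slope_se", "intercept_se", "n", "r_squared", "s", "f_stat"))
    obj[[nm]] <- f[[nm]] %||% NA_real_
  obj
}
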