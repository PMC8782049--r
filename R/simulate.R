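#' Simulate a synthetic compound dataset
#'
#' Generates a dataset with the statistical structure the calibration
#' pipeline assumes, so that every stage (tautomer resolution, descriptor
#' construction, consolidation, fitting) can be exercised end to end with
#' known truth:
#' \enumerate{
#'   \item each compound draws a true descriptor value deltaE uniformly
#'     in `de_range`;
#'   \item both charge states of the step get a tautomer ensemble whose
#'     representative (minimum-energy) states differ by exactly that
#'     deltaE -- extra tautomers sit above the representative by gaps
#'     drawn from an exponential law with mean `gap_scale`;
#'   \item absolute energy baselines are drawn uniformly in an arbitrary
#'     window, since only energy differences carry information (the
#'     pipeline is translation-invariant);
#'   \item the true pKa is `slope * deltaE + intercept`; one noisy
#'     "observed" value adds Gaussian observation noise (`noise_sd`), and
#'     1-3 literature replicates scatter around it with independent
#'     Gaussian noise (`replicate_sd`).
#' }
#' Defaults reproduce the published cation->neutral study conditions:
#' 17 compounds, slope -0.131 pKa/(kJ/mol), intercept -151.54, noise
#' 1.25 pKa units (the calibration's residual standard error), deltaE
#' spanning the calibrated range [-1254, -872] kJ/mol, gaps of mean
#' 25 kJ/mol, and replicate spread 0.05 pKa units (typical inter-source
#' disagreement in the compendium).
#'
#' @param n_compounds number of compounds (>= 3).
#' @param slope,intercept true linear relation between pKa and deltaE.
#' @param noise_sd SD of the per-compound observation noise (pKa units).
#' @param de_range length-2 numeric, range of true deltaE (kJ/mol).
#' @param n_tautomers length-2 integer, min/max ensemble size per charge
#'   state.
#' @param gap_scale mean of the exponential inter-tautomer gaps (kJ/mol).
#' @param replicate_sd SD of the literature replicate noise (pKa units).
#' @param step dissociation step the dataset represents.
#' @param seed integer seed; mandatory, every random draw flows from it.
#' @return a [compound_set()] with attributes `truth` (per-compound true
#'   deltaE and pKa), `gap_scale`, `step` and `params`.
#' @export
simulate_pka_dataset <- function(n_compounds = 17,
                                 slope = -0.131, intercept = -151.54,
                                 noise_sd = 1.25,
                                 de_range = c(-1254, -872),
                                 n_tautomers = c(1L, 4L),
                                 gap_scale = 25,
                                 replicate_sd = 0.05,
                                 step = c("pKa1", "pKa2"),
                                 seed) {
  step <- match.arg(step)
  if (missing(seed)) stop("seed is mandatory for simulate_pka_dataset()",
                          call. = FALSE)
  if (n_compounds < 3) stop("n_compounds must be at least 3", call. = FALSE)
  if (noise_sd < 0 || replicate_sd < 0)
    stop("noise_sd and replicate_sd must be non-negative", call. = FALSE)
  if (length(de_range) != 2L || !all(is.finite(de_range)) ||
      de_range[1L] >= de_range[2L])
    stop("de_range must be a finite (low, high) interval", call. = FALSE)
  if (gap_scale <= 0) stop("gap_scale must be positive", call. = FALSE)
  n_tautomers <- as.integer(n_tautomers)
  if (length(n_tautomers) != 2L || n_tautomers[1L] < 1L ||
      n_tautomers[1L] > n_tautomers[2L])
    stop("n_tautomers must be an increasing pair of counts >= 1", call. = FALSE)
  set.seed(as.integer(seed))

  ids <- sprintf("cmp%03d", seq_len(n_compounds))
  de <- runif(n_compounds, de_range[1L], de_range[2L])
  base <- runif(n_compounds, -6e5, -4e5)
  charges <- if (step == "pKa1") c(parent = 1L, product = 0L)
             else c(parent = 0L, product = -1L)

  one_state <- function(charge, rep_energy) {
    k <- sample(seq(n_tautomers[1L], n_tautomers[2L]), n_compounds,
                replace = TRUE)
    extra <- k - 1L
    rep_rows <- data.frame(compound_id = ids, charge = charge,
                           tautomer_id = "t01", phase = "aqueous",
                           energy = rep_energy, stringsAsFactors = FALSE)
    if (sum(extra) == 0L) return(rep_rows)
    idx <- rep.int(seq_len(n_compounds), extra)
    tnum <- sequence(extra) + 1L
    extra_rows <- data.frame(compound_id = ids[idx], charge = charge,
                             tautomer_id = sprintf("t%02d", tnum),
                             phase = "aqueous",
                             energy = rep_energy[idx] +
                               rexp(length(idx), rate = 1 / gap_scale),
                             stringsAsFactors = FALSE)
    rbind(rep_rows, extra_rows)
  }
  # deltaE = E(product representative) - E(parent representative), exactly
  ms <- rbind(one_state(charges[["parent"]], base),
              one_state(charges[["product"]], base + de))

  pka_true <- slope * de + intercept
  pka_obs <- pka_true + rnorm(n_compounds, 0, noise_sd)
  n_rep <- sample(1:3, n_compounds, replace = TRUE)
  lidx <- rep.int(seq_len(n_compounds), n_rep)
  lit <- data.frame(compound_id = ids[lidx], step = step,
                    value = pka_obs[lidx] +
                      rnorm(length(lidx), 0, replicate_sd),
                    source = paste0("sim", sequence(n_rep)),
                    status = "measured", stringsAsFactors = FALSE)

  ds <- compound_set(data.frame(compound_id = ids, name = ids,
                                formula = "synthetic",
                                stringsAsFactors = FALSE),
                     microstates = ms, literature = lit)
  attr(ds, "truth") <- data.frame(compound_id = ids, delta_e = de,
                                  pka_true = pka_true, pka_obs = pka_obs,
                                  stringsAsFactors = FALSE)
  attr(ds, "gap_scale") <- gap_scale
  attr(ds, "step") <- step
  attr(ds, "params") <- list(n_compounds = n_compounds, slope = slope,
                             intercept = intercept, noise_sd = noise_sd,
                             de_range = de_range, n_tautomers = n_tautomers,
                             gap_scale = gap_scale,
                             replicate_sd = replicate_sd, seed = seed)
  ds
}

#' Rescale the inter-tautomer gaps of a simulated dataset
#'
#' Multiplies every tautomer's offset above its state's minimum energy by
#' `new_gap_scale / gap_scale(dataset)`.  Representative-state energies
#' (and hence descriptors under the most-stable policy) are unchanged;
#' Boltzmann-policy descriptors shift by a bounded amount that vanishes
#' as the gaps grow.
#'
#' @param dataset a dataset from [simulate_pka_dataset()].
#' @param new_gap_scale new mean gap (kJ/mol, > 0); may be `Inf`.
#' @return the perturbed dataset (attributes updated).
#' @export
perturb_tautomer_gap <- function(dataset, new_gap_scale) {
  stopifnot(inherits(dataset, "compound_set"))
  old <- attr(dataset, "gap_scale")
  if (is.null(old))
    stop("dataset lacks a gap_scale attribute; only simulated datasets can be perturbed",
         call. = FALSE)
  if (!is.numeric(new_gap_scale) || length(new_gap_scale) != 1L ||
      is.na(new_gap_scale) || new_gap_scale <= 0)
    stop("new_gap_scale must be a single positive value", call. = FALSE)
  ms <- dataset$microstates
  grp <- paste(ms$compound_id, ms$charge, ms$phase)
  emin <- stats::ave(ms$energy, grp, FUN = min)
  offset <- ms$energy - emin
  scaled <- if (is.infinite(new_gap_scale))
    ifelse(offset > 0, Inf, 0) else offset * (new_gap_scale / old)
  # keep energies finite: an infinite gap removes the excited tautomers
  if (is.infinite(new_gap_scale)) {
    keep <- offset == 0
    dataset$microstates <- ms[keep, , drop = FALSE]
  } else {
    ms$energy <- emin + scaled
    dataset$microstates <- ms
  }
  attr(dataset, "gap_scale") <- new_gap_scale
  dataset
}

#' Fit the calibration pipeline to a dataset
#'
#' Convenience wrapper running consolidation, tautomer resolution,
#' descriptor construction and calibration on a [compound_set()] that
#' carries microstates and literature records (e.g. a simulated
#' dataset): the full pipeline in one call.
#'
#' @param dataset a [compound_set()].
#' @param step `"pKa1"` or `"pKa2"` (default: the dataset's own step
#'   attribute, if present).
#' @param policy tautomer policy, see [compute_delta_e()].
#' @param consolidate_policy see [consolidate_pka()].
#' @param digits decimals kept by consolidation; `NULL` (default) keeps
#'   full precision for fitting.
#' @return a fitted `pka_qsar` object.
#' @export
fit_dataset <- function(dataset, step = NULL,
                        policy = c("most_stable", "boltzmann"),
                        consolidate_policy = c("mean", "median", "first"),
                        digits = NULL) {
  stopifnot(inherits(dataset, "compound_set"))
  step <- step %||% attr(dataset, "step") %||% "pKa2"
  policy <- match.arg(policy)
  desc <- compute_descriptors(dataset, step, "aqueous", policy)
  cons <- consolidate_dataset(dataset, step, match.arg(consolidate_policy),
                              digits = digits)
  df <- merge(desc, cons[, c("compound_id", "exp")], by = "compound_id")
  pka_qsar(exp ~ delta_e, df, step = step)
}

#' Monte-Carlo parameter recovery study
#'
#' Repeatedly simulates datasets with [simulate_pka_dataset()] and refits
#' the pipeline, summarising how well the true slope is recovered: the
#' mean fitted slope with its Monte-Carlo standard error, and the
#' empirical coverage of the per-fit confidence interval for the slope.
#'
#' @param n_sims number of simulated datasets.
#' @param seed integer seed for the whole study.
#' @param level confidence level for the coverage check (default 0.95).
#' @param ... parameters forwarded to [simulate_pka_dataset()] (e.g.
#'   `n_compounds`, `slope`, `noise_sd`).
#' @return list: `slopes` (all fitted slopes), `mean_slope`, `mc_se`,
#'   `bias`, `coverage`, `s_values` (fitted residual standard errors),
#'   `true_slope`.
#' @export
parameter_recovery <- function(n_sims = 500, seed, level = 0.95, ...) {
  if (missing(seed)) stop("seed is mandatory for parameter_recovery()",
                          call. = FALSE)
  args <- list(...)
  true_slope <- args$slope %||% -0.131
  set.seed(as.integer(seed))
  sim_seeds <- sample.int(.Machine$integer.max, n_sims)
  slopes <- numeric(n_sims); svals <- numeric(n_sims)
  covered <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    ds <- do.call(simulate_pka_dataset, c(args, list(seed = sim_seeds[i])))
    fit <- fit_dataset(ds)
    slopes[i] <- fit$slope
    svals[i] <- fit$s
    ci <- confint(fit, level = level)[2L, ]
    covered[i] <- ci[1L] <= true_slope && true_slope <= ci[2L]
  }
  list(slopes = slopes, mean_slope = mean(slopes),
       mc_se = sd(slopes) / sqrt(n_sims),
       bias = mean(slopes) - true_slope,
       coverage = mean(covered), s_values = svals,
       true_slope = true_slope)
}
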