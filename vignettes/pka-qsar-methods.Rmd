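---
title: "Estimating heterocycle acidities from solution-phase deprotonation energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating heterocycle acidities from solution-phase deprotonation energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkaqsar)
```

## The model

Pyrimidines and related nitrogen heterocycles — the uracils, cytosines,
imidazoles, azines and their saturated cousins — change protonation state
within the physiological and preparative pH range, so their acid
dissociation constants decide which species dominates in solution. This
package implements a linear free-energy-relationship (QSAR) estimator for
those constants. Two dissociation steps are handled:

* **pKa1**, the cation-to-neutral step AH₂⁺ → AH + H⁺, and
* **pKa2**, the neutral-to-anion step AH → A⁻ + H⁺.

The single molecular descriptor is the electronic-energy difference in
aqueous solution between the dissociation product and its parent,

$$\Delta E_{\mathrm{H_2O}} = E_{\mathrm{H_2O}}(\text{deprotonated}) -
  E_{\mathrm{H_2O}}(\text{parent}),$$

with energies from continuum-solvation quantum-chemical calculations
(density-functional theory with an implicit aqueous solvent model, in the
original study). The model for each step is a straight line,

$$\mathrm{p}K_a = b \cdot \Delta E_{\mathrm{H_2O}} + a ,$$

fitted by ordinary least squares. Thermodynamics motivates the form: a
dissociation free-energy difference of $\Delta\Delta G$ shifts a pKa by
$\Delta\Delta G / (RT \ln 10)$, so if $\Delta E$ tracked free energy
perfectly the slope would be $-1/(RT\ln 10) \approx -0.175$ pKa per
kJ/mol at 298.15 K. Fitted slopes must be smaller in magnitude (solvation
and entropic contributions are only partially captured by the raw energy
difference); the package tests this bound on every calibration fit. The
reported calibrations, available as `published_model()`, are

```{r published}
published_model("pKa1")
published_model("pKa2")
```

## Tautomer resolution

These compounds typically exist as several tautomers per charge state
(a uracil-like compound can have three cationic, six neutral and two
anionic forms). The calibration convention represents each charge state
by its **most stable tautomer**:

```{r tautomers}
ens <- data.frame(compound_id = "u", charge = 0L,
                  tautomer_id = c("t1", "t2", "t3"), phase = "aqueous",
                  energy = c(-1000, -1030, -1010))
select_representative(ens)
```

Exact ties are broken by the lexicographically smallest `tautomer_id`, so
pipelines are reproducible regardless of input order. The approximation
is safest when the gap to the next tautomer is large; `energy_gap()`
reports the gap and warns when it does not exceed 25 kJ/mol (the
customary threshold for "substantial", configurable via `warn_below`).
The warning is informational: nothing is dropped or altered.

As a sensitivity check, `policy = "boltzmann"` replaces each state's
minimum energy by the ensemble free energy
$-RT\log\sum_i e^{-E_i/RT}$ (computed shifted by the minimum for
stability; $R = 8.31446\times10^{-3}$ kJ mol⁻¹ K⁻¹, default 298.15 K).
It is always at or below the minimum and coincides with it as gaps grow;
at a 25 kJ/mol gap the two policies differ by about $10^{-4}$ kJ/mol, which
is why the most-stable rule is the default and the Boltzmann option is
opt-in.

## From tables to calibration

The packaged fixtures transcribe the published study tables:
a 31-compound literature/external-predictor compendium (`table1`), a
six-compound gas-phase validation set (`table2`), and the per-step
calibration tables (`table3`, `table4`).

**Consolidation.** Where several literature values exist for one
compound and step, the calibration uses their arithmetic mean over
*distinct* values (a value cited twice counts once), rounded half-up to
two decimals — the compendium's printing precision:

```{r consolidate}
consolidate_pka(c(7.15, 6.99, 6.99))  # two distinct values
```

Median and first-cited policies are available. Two sentinels are kept
apart throughout: a compound with no reported measurement (`"-"`) can
still receive predictions, while one with no dissociable proton
(`"N/A"`) cannot have that step at all. Three consolidation cells in the
source tables cannot be reproduced by any deterministic rounding rule
(the tables round 8.015 down but 9.755 up, and print one value that
differs from its own sources by exactly 1); the reproduction tests
therefore require agreement on at least 15 of 17 (pKa1) and 11 of 12
(pKa2) calibration cells and log the exceptions.

**Fit membership.** The pKa1 table contains 19 numeric experimental
values but the published calibration used 17: compounds whose estimates
fall in the hard-to-measure negative range are reported only
qualitatively (`"<0"` modestly negative, `"<<0"` significantly negative)
and were excluded from the fit. The boundary between the two markers is
not stated in the source; $-7$ separates all printed cases and is the
package default (`qualitative_cut`, configurable). Because no
self-contained rule recovers the exclusion (one excluded compound has a
positive experimental value), fixture fit membership is taken from the
printed residual column — a row with a residual is a calibration point —
exposed by `calibration_points()`.

```{r fit}
tabs <- fixture_tables()
fit2 <- pka_qsar(exp ~ delta_e, calibration_points(tabs$table4),
                 step = "pKa2")
summary(fit2)
```

Diagnostics are computed from the closed-form simple-regression
formulas (`stats::lm` is used only as an independent cross-check in the
test suite). Refitting the *printed* (integer-rounded) descriptor tables
does not exactly reproduce the published coefficients — the original fit
evidently used unrounded energies, and for the neutral-to-anion step the
published residual standard error (0.612) is irreconcilable with the
table's own printed residuals (which imply 1.02) — so the package treats
the published coefficients as given constants for prediction
(`published_model()`) and the refit as a separate, fully diagnosable
object. A `round_de_for_fit` switch in the pipeline reproduces
table-based fits explicitly. Printed F statistics of the source are
likewise documented rather than asserted: the one-regressor identity
$F = (n-2)R^2/(1-R^2)$, which the package enforces by construction, is
inconsistent with the printed pKa1 value.

**Prediction and reporting.** Predictions are reported to two decimals
with half-away-from-zero rounding (an epsilon guard handles binary
representations that sit a hair below a decimal tie); residuals are
experimental minus predicted, absent — never zero — when either side is
missing. `build_report()` mirrors the published table layout and can
annotate (not remove) points whose externally studentized residual
exceeds 2.5, the "outliers may signal unusual chemistry" reading of the
QSAR literature.

## External-predictor agreement

The compendium carries predictions from a commercial empirical package
with printed uncertainties. `external_agreement()` regresses
experimental on external values with the same OLS machinery. The source
reports n = 19 (pKa1) and n = 13 (pKa2) for these regressions but its
own table contains 21 and 14 complete pairs without identifying the
exclusions; this package uses all complete pairs and documents the
discrepancy rather than guessing.

## Gas-phase validation

Before trusting the solution-phase descriptor, the level of theory is
checked against tabulated gas-phase acidities for six compounds:
$\Delta_r G^\circ = |G(\mathrm{A^-}) + G(\mathrm{H^+}) - G(\mathrm{AH})|$
with the fixed proton free energy $G^\circ(\mathrm{H^+}) = -26.3$ kJ/mol
at 298.15 K. The magnitude convention matches the positive tabulated
values (~1400–1600 kJ/mol); the source uses the association direction in
one caption and the dissociation direction elsewhere, so the module
stores magnitudes and documents the ambiguity instead of asserting a
sign.

```{r thermo}
tab2 <- fixture_tables()$table2
agreement_r2(tab2$exp_drG, tab2$calc_drG)
deviation_report(tab2)
```

Experimental uncertainties are not printed in the source, so "within
experimental error" is reported qualitatively; the package's checks are
the squared correlation (0.998 on this set) and the identity of the
largest deviator.

## The synthetic generator

`simulate_pka_dataset()` emulates the assumed data-generating process so
the whole pipeline is testable with known truth: per compound a true
$\Delta E$ drawn uniformly, tautomer ensembles whose representative
energies encode that $\Delta E$ exactly (excited tautomers offset by
exponential gaps), a true pKa on the line, Gaussian observation noise,
and 1–3 literature replicates with their own smaller noise. Defaults are
the study conditions of the cation-to-neutral calibration: 17 compounds,
slope $-0.131$, intercept $-151.54$, observation noise 1.25 (the
calibration's residual standard error), $\Delta E \in [-1254, -872]$
kJ/mol (the span of the fixture tables), gap scale 25 kJ/mol, replicate
spread 0.05 (the typical disagreement between literature sources in the
compendium, e.g. 7.98 vs 8.05). Absolute energy baselines are arbitrary
because only differences matter — the pipeline is translation-invariant,
and a test asserts it.

What the generator does *not* emulate: systematic quantum-chemistry
error (basis-set or solvent-model bias), correlated literature errors,
and the real, irregular spacing of compounds along $\Delta E$. Passing
recovery tests therefore demonstrate statistical correctness of the
estimator and pipeline plumbing, not accuracy of any particular
quantum-chemical protocol on new chemistry.

```{r recovery, eval = FALSE}
rec <- parameter_recovery(n_sims = 500, seed = 11, n_compounds = 17,
                          slope = -0.131, intercept = -151.54,
                          noise_sd = 1.25)
c(mean_slope = rec$mean_slope, coverage = rec$coverage)
```

Five hundred replicates at the study size run in a few seconds; the test
suite uses 150 replicates per size for the consistency checks at
n = 17, 50 and 200, which keeps the full suite around a minute on one
core while leaving Monte-Carlo envelopes tight enough to be meaningful.

## Numerical choices, in one place

* Internal energy unit kJ/mol; hartree input columns converted by
  2625.5 kJ/mol per hartree at load.
* Rounding of reported values: half away from zero with a $10^{-9}$
  guard; fitting always consumes unrounded values unless
  `round_de_for_fit` is set.
* Tautomer ties: lexicographic `tautomer_id`.
* Qualitative cut: $-7$; gap warning: 25 kJ/mol; both configurable in
  `run_pipeline()`.
* Descriptor sanity range for aqueous fixtures ($[-1500, -800]$ kJ/mol)
  and literature plausibility range ($[-10, 25]$) are enforced when
  parsing experimental compendium data, not on synthetic datasets, whose
  model-implied values may legitimately fall outside the measurable
  window.
* `run_pipeline()` writes no timestamps, so identical config and input
  give byte-identical outputs.

## Known limitations

* The package consumes microstate energies; it does not run
  quantum-chemistry engines or enumerate tautomer structures.
* No microconstant (microspecies-resolved) model: one representative per
  charge state.
* The aqueous descriptor is a raw electronic-energy difference — no
  zero-point or thermal corrections in solution, by design of the
  underlying protocol.
* Calibrations are univariate; no multi-descriptor QSAR, and
  cross-validation support is limited to the closed-form leave-one-out
  utility `loo_cv()`.
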