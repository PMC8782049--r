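test_that("representative selection returns the minimum-energy tautomer", {
  single <- make_ensemble(-1000)
  expect_equal(select_representative(single)$tautomer_id, "t01")

  ens <- make_ensemble(c(-1000, -1030, -1010))
  expect_equal(select_representative(ens)$tautomer_id, "t02")
  expect_equal(select_representative(ens)$energy, -1030)

  # exact ties broken by lexicographically smallest tautomer_id
  tie <- make_ensemble(c(-5, -5), tautomer_id = c("tb", "ta"))
  expect_equal(select_representative(tie)$tautomer_id, "ta")

  expect_error(select_representative(make_ensemble(numeric())),
               "missing-state")
  expect_error(select_representative(rbind(make_ensemble(-1, charge = 0L),
                                           make_ensemble(-2, charge = 1L))),
               "charge")
})

test_that("representative matches the brute-force argmin on random ensembles", {
  set.seed(101)
  for (i in 1:200) {
    ens <- random_ensemble()
    rep <- select_representative(ens)
    # exhaustive scan oracle with the same deterministic tie-break
    best <- ens[order(ens$energy, ens$tautomer_id)[1L], ]
    expect_identical(rep$tautomer_id, best$tautomer_id)
    expect_identical(rep$energy, best$energy)
    # permutation invariance
    perm <- ens[sample(nrow(ens)), ]
    expect_identical(select_representative(perm)$tautomer_id,
                     rep$tautomer_id)
  }
})

test_that("energy gap is second-lowest minus lowest, warning when small", {
  expect_warning(g <- energy_gap(make_ensemble(c(-1000, -1030, -1010))),
                 "small tautomer gap")
  expect_equal(g, 20)  # -1010 - (-1030)

  expect_silent(expect_equal(energy_gap(make_ensemble(-1000)), Inf))
  expect_silent(expect_equal(energy_gap(make_ensemble(c(0, -30))), 30))
  # threshold is configurable
  expect_warning(energy_gap(make_ensemble(c(0, -30)), warn_below = 40),
                 "small tautomer gap")
})

test_that("a realistic multi-tautomer ensemble is accepted per charge state", {
  # e.g. uracil: three cationic, six neutral, two anionic tautomers
  ms <- rbind(make_ensemble(c(-100, -70, -60), "uracil", 1L),
              make_ensemble(c(-1300, -1260, -1250, -1240, -1230, -1220),
                            "uracil", 0L),
              make_ensemble(c(-2500, -2460), "uracil", -1L))
  cs <- compound_set(data.frame(compound_id = "uracil", name = "uracil",
                                formula = "C4H4N2O2"),
                     microstates = ms)
  expect_equal(nrow(cs$microstates), 11L)
  expect_equal(select_representative(
    ms[ms$charge == 0L, ])$energy, -1300)
})

test_that("Boltzmann effective energy has the closed-form limits", {
  rt <- 8.31446e-3 * 298.15

  one <- make_ensemble(-1234.5)
  expect_equal(boltzmann_effective_energy(one), -1234.5)

  pair <- make_ensemble(c(-800, -800))
  expect_equal(boltzmann_effective_energy(pair), -800 - rt * log(2))

  gap25 <- make_ensemble(c(-1000, -975))
  eff <- boltzmann_effective_energy(gap25)
  expect_lt(abs(eff - (-1000)), 0.11)
  expect_lte(eff, -1000)

  expect_error(boltzmann_effective_energy(pair, temperature = 0), "positive")
  expect_error(boltzmann_effective_energy(pair, temperature = -3), "positive")
})

test_that("effective energy is below the minimum and approaches it as gaps grow", {
  set.seed(7)
  for (i in 1:50) {
    ens <- random_ensemble(n = sample(2:6, 1L))
    eff <- boltzmann_effective_energy(ens)
    expect_lte(eff, min(ens$energy))
  }
  base <- -1500
  gaps <- c(5, 10, 25, 50, 100)
  dev <- vapply(gaps, function(g) {
    abs(boltzmann_effective_energy(make_ensemble(c(base, base + g))) - base)
  }, numeric(1L))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[length(dev)], 1e-12)
})
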