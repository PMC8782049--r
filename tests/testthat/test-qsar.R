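test_that("a perfect line is fitted exactly", {
  fit <- pka_qsar(y ~ x, data.frame(x = 0:2, y = 0:2))
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$s, 0)
  expect_equal(loo_cv(fit)$press, 0)
})

test_that("degenerate inputs raise fit errors", {
  expect_error(pka_qsar(y ~ x, data.frame(x = 1:2, y = 1:2)),
               "insufficient data")
  expect_error(pka_qsar(y ~ x, data.frame(x = rep(1, 5), y = rnorm(5))),
               "zero variance")
})

test_that("closed-form fit matches the lm oracle on the printed tables", {
  tabs <- fixture_tables()
  for (tab in list(tabs$table3, tabs$table4)) {
    pts <- calibration_points(tab)
    fit <- pka_qsar(exp ~ delta_e, pts)
    oracle <- lm(exp ~ delta_e, pts)
    expect_equal(fit$intercept, unname(coef(oracle)[1L]), tolerance = 1e-9)
    expect_equal(fit$slope, unname(coef(oracle)[2L]), tolerance = 1e-9)
    sm <- summary(oracle)
    expect_equal(fit$slope_se, sm$coefficients[2L, 2L], tolerance = 1e-9)
    expect_equal(fit$intercept_se, sm$coefficients[1L, 2L], tolerance = 1e-9)
    expect_equal(fit$r_squared, sm$r.squared, tolerance = 1e-12)
    expect_equal(fit$s, sm$sigma, tolerance = 1e-12)
    expect_equal(fit$f_stat, unname(sm$fstatistic[1L]), tolerance = 1e-9)
  }
})

test_that("OLS identities hold on random datasets", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(5:40, 1L)
    x <- runif(n, -1300, -900)
    y <- -0.14 * x - 160 + rnorm(n, 0, runif(1, 0.1, 3))
    fit <- pka_qsar(y ~ x, data.frame(x = x, y = y))

    # residuals sum to zero
    expect_lt(abs(sum(fit$residuals)), 1e-9 * n)
    # the line passes through the sample means
    expect_equal(predict(fit, mean(x)), mean(y), tolerance = 1e-9)
    # R^2 equals the squared Pearson correlation
    expect_equal(fit$r_squared, cor(x, y)^2, tolerance = 1e-12)
    # F = (n-2) R^2 / (1 - R^2) by construction
    expect_equal(fit$f_stat,
                 (n - 2) * fit$r_squared / (1 - fit$r_squared),
                 tolerance = 1e-12)
    # swapping axes: product of the two slopes equals R^2
    swap <- pka_qsar(x ~ y, data.frame(x = x, y = y))
    expect_equal(fit$slope * swap$slope, fit$r_squared, tolerance = 1e-9)
  }
})

test_that("published coefficients reproduce the printed estimates", {
  eq1 <- published_model("pKa1")
  eq2 <- published_model("pKa2")

  p1 <- pka_predict(eq1, -1216)
  expect_equal(p1$pka, 7.76)
  expect_equal(pka_predict(eq2, -1200)$pka, 9.78)
  # qualitative convention for negative-range estimates
  expect_equal(pka_predict(eq1, -872)$qualitative, "<<0")
  expect_equal(pka_predict(eq1, -1115)$qualitative, "<0")
})

test_that("residuals follow experimental minus calculated, absent when unmeasured", {
  expect_equal(pka_residual(8.01, 7.756), 0.25)
  expect_equal(pka_residual(14.4, 12.036), 2.36)
  expect_equal(pka_residual(5, 5), 0)
  expect_true(is.na(pka_residual(NA_real_, 7.76)))
})

test_that("classification boundaries are respected", {
  expect_equal(classify_pka(c(0, -0.01, -7, -7.01)),
               c("numeric", "<0", "<0", "<<0"))
  # configurable cut
  expect_equal(classify_pka(-6, cut = -5), "<<0")
})

test_that("external agreement regression uses the same OLS machinery", {
  expect_equal(external_agreement(1:5, 1:5)$slope, 1)
  expect_equal(external_agreement(1:5, 1:5)$intercept, 0)
  expect_equal(external_agreement(1:5, 1:5)$r_squared, 1)
  expect_equal(external_agreement(c(0, 1, 2), c(2, 1, 0))$slope, -1)

  # all complete (external, experimental) pairs from the compendium
  tabs <- fixture_tables()
  cons <- consolidate_dataset(tabs$table1, "pKa1")
  ext <- tabs$table1$external
  ext <- ext[ext$step == "pKa1", ]
  df <- merge(cons[!is.na(cons$exp), c("compound_id", "exp")],
              ext[, c("compound_id", "value")], by = "compound_id")
  fit <- external_agreement(df$value, df$exp, step = "pKa1")
  oracle <- lm(exp ~ value, df)
  expect_equal(fit$slope, unname(coef(oracle)[2L]), tolerance = 1e-9)
  expect_equal(fit$intercept, unname(coef(oracle)[1L]), tolerance = 1e-9)
  # the agreement is strong and near-unity, as reported
  expect_gt(fit$r_squared, 0.95)
  expect_equal(fit$slope, 1.07, tolerance = 0.1)
})

test_that("result tables mirror the published layout", {
  eq2 <- published_model("pKa2")
  dat <- data.frame(compound_id = c("flucytosine", "5-nitrouracil"),
                    delta_e = c(-1254, -1159),
                    exp = c(NA, 5.3))
  rep <- build_report(dat, eq2)
  expect_equal(rep$calc, c(17.39, 4.00))
  expect_true(is.na(rep$residual[1L]))
  expect_equal(rep$residual[2L], 1.30)

  empty <- build_report(data.frame(compound_id = character(),
                                   delta_e = numeric(), exp = numeric()),
                        eq2)
  expect_equal(nrow(empty), 0L)

  # qualitative rows have no numeric calc and no residual
  eq1 <- published_model("pKa1")
  r3 <- build_report(data.frame(compound_id = "oxazole", delta_e = -872,
                                exp = 0.8), eq1)
  expect_true(is.na(r3$calc))
  expect_true(is.na(r3$residual))
  expect_equal(r3$display, "<<0")
})

test_that("studentized-residual flag annotates but never removes", {
  tabs <- fixture_tables()
  tab4 <- tabs$table4[, c("compound_id", "delta_e", "exp")]
  fit <- pka_qsar(exp ~ delta_e, calibration_points(tabs$table4))
  rep <- build_report(tab4, fit, flag_outliers = TRUE)
  expect_equal(nrow(rep), 21L)
  # the grossest deviator in the neutral->anion table is imidazole
  expect_true(rep$outlier[rep$compound_id == "imidazole"])
  expect_false(any(rep$outlier[rep$compound_id %in%
                                 c("uracil", "thymine")], na.rm = TRUE))
})

test_that("fitted slopes on the printed tables respect the thermodynamic bound", {
  # |slope| < 1/(RT ln 10) = 0.175 pKa per kJ/mol at 298.15 K
  bound <- 1 / (8.31446e-3 * 298.15 * log(10))
  expect_equal(bound, 0.1752, tolerance = 1e-3)
  tabs <- fixture_tables()
  for (tab in list(tabs$table3, tabs$table4)) {
    fit <- pka_qsar(exp ~ delta_e, calibration_points(tab))
    expect_lt(abs(fit$slope), bound)
  }
})

test_that("models serialize to JSON and back", {
  tabs <- fixture_tables()
  fit <- pka_qsar(exp ~ delta_e, calibration_points(tabs$table4),
                  step = "pKa2")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(back$slope, fit$slope, tolerance = 1e-12)
  expect_equal(back$intercept, fit$intercept, tolerance = 1e-12)
  expect_equal(back$n, fit$n)
  expect_equal(back$s, fit$s, tolerance = 1e-12)
  expect_equal(back$step, "pKa2")
  expect_equal(pka_predict(back, -1200)$pka, pka_predict(fit, -1200)$pka)
})

test_that("simulate() draws responses around the fitted line", {
  fit <- pka_qsar(exp ~ delta_e, calibration_points(fixture_tables()$table3))
  sims <- simulate(fit, nsim = 200, seed = 1)
  expect_equal(dim(sims), c(fit$n, 200L))
  mu <- rowMeans(as.matrix(sims))
  expect_lt(max(abs(mu - fit$fitted.values)), 4 * fit$s / sqrt(200))
})
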