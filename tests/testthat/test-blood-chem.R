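test_that("partition splits at the lactate criterion and filters the lactate regression", {
  s <- make_samples(ph = c(7.45, 7.35, 7.33, 7.31),
                    lactate = c(0.8, 5.0, 1.5, 2.2),
                    pco2 = c(45, 85, 50, 55))
  expect_message(g <- partition_samples(s), "assigned to the dive group")
  expect_equal(nrow(g$dive_group), 2L)        # 0.8 and the exact-1.5 sample
  expect_equal(nrow(g$surface_group), 2L)
  # pco2 85 sample stays in the surface group but is dropped from the
  # lactate-regression subset (pco2 < 70 rule)
  expect_equal(nrow(g$lactate_regression), 1L)
  expect_equal(g$lactate_regression$lactate, 2.2)
  # exhaustive and disjoint over samples with lactate != criterion
  expect_equal(nrow(g$dive_group) + nrow(g$surface_group), nrow(s))
  empty <- partition_samples(make_samples(numeric(0)))
  expect_equal(nrow(empty$dive_group), 0L)
  expect_equal(nrow(empty$surface_group), 0L)
})

test_that("random-intercept fit recovers generating slopes", {
  # noise-free: exact interpolation (lactate effect zeroed so the single
  # predictor carries all signal; lmer convergence gripes are expected on
  # degenerate zero-variance data)
  sp0 <- panel_spec(n_penguins = 4, samples_per_penguin = 3,
                    slope_pco2 = -0.0034, slope_lactate = 0,
                    penguin_sd = 0, residual_sd = 0, seed = 11)
  fit0 <- suppressWarnings(fit_random_intercept(gen_blood_panel(sp0), "pco2"))
  expect_equal(fit0$slope, -0.0034, tolerance = 1e-10)

  # pco2 panel at study scale (32 samples)
  sp <- panel_spec(n_penguins = 16, samples_per_penguin = 2, seed = 42)
  fit <- fit_random_intercept(gen_blood_panel(sp), "pco2")
  expect_lt(abs(fit$slope - (-0.0034)), 0.0008)
  expect_lt(abs(fit$slope - (-0.0034)), 2 * fit$se_slope + 1e-12)
  expect_lt(fit$slope, 0)

  # lactate panel spanning the post-dive range (single-predictor world,
  # mirroring the surface-group model where PCO2 is restricted)
  spl <- panel_spec(n_penguins = 8, samples_per_penguin = 4,
                    lactate_range = c(2, 17), pco2_range = c(35, 65),
                    slope_pco2 = 0, seed = 7)
  fitl <- fit_random_intercept(gen_blood_panel(spl), "lactate")
  expect_lt(abs(fitl$slope - (-0.009)), 0.002)
})

test_that("fit reports a coherent variance decomposition", {
  for (seed in 1:5) {
    fit <- fit_random_intercept(
      gen_blood_panel(panel_spec(seed = seed, penguin_sd = 0.03)), "pco2")
    expect_gte(fit$var_fixed, 0)
    expect_gte(fit$var_random, 0)
    expect_gt(fit$var_residual, 0)
    expect_lte(fit$r2_marginal, fit$r2_conditional)
    expect_lte(fit$r2_conditional, 1)
  }
})

test_that("single-penguin panels fall back to OLS with a warning", {
  s <- make_samples(ph = c(7.45, 7.41, 7.34, 7.30),
                    pco2 = c(40, 55, 70, 85), penguin_id = "P01")
  expect_warning(fit <- fit_random_intercept(s, "pco2"), "single penguin")
  expect_identical(fit$var_random, 0)
  expect_lt(fit$slope, 0)
  expect_error(fit_random_intercept(s[1:2, ], "pco2"), "at least 3")
})

test_that("candidate-model comparison applies the delta-AIC < 2 rule", {
  panel <- gen_blood_panel(panel_spec(n_penguins = 20,
                                      samples_per_penguin = 4,
                                      slope_lactate = 0, seed = 5))
  cmp <- compare_ph_models(panel, list("pco2", c("pco2", "site"),
                                       c("pco2", "lactate", "site")))
  # site carries no generating signal: pco2-only must be eligible & simplest
  expect_equal(cmp$best, 1L)
  expect_equal(nrow(cmp$table), 3L)
  expect_true(all(cmp$table$delta_aic >= 0))
})

test_that("pH lower bound applies exclusions then rounds to one decimal", {
  dive <- make_samples(ph = c(7.42, 7.30, 7.22, 7.25),
                       pco2 = c(50, 80, 95, 74),
                       condition = c("dive", "dive", "dive", "anesthesia"))
  surf <- make_samples(ph = c(7.36, 7.29, 7.23), pco2 = c(45, 55, 85),
                       lactate = c(4, 9, 3),
                       condition = c("restraint", "restraint", "anesthesia"))
  # retained minima: dive 7.30 (95 excluded by pco2, 7.25 by anesthesia>70),
  # surface 7.29 (anesthesia 85 excluded) -> both round to 7.3
  b <- select_ph_lower_bound(dive, surf)
  expect_equal(as.numeric(b), 7.3)
  expect_equal(attr(b, "details")$retained_min[["surface"]], 7.29)

  # order and duplication invariance
  b2 <- select_ph_lower_bound(dive[c(3, 1, 4, 2), ], surf[c(2, 1, 3, 2), ])
  expect_equal(as.numeric(b2), 7.3)

  # uniform 7.45 rounds to 7.4
  u <- make_samples(ph = rep(7.45, 3))
  expect_equal(as.numeric(select_ph_lower_bound(u, u)), 7.4)

  # exclusions emptying a group is an error
  all_high <- make_samples(ph = c(7.2, 7.25), pco2 = c(95, 99))
  expect_error(select_ph_lower_bound(all_high, surf), "no pH bound")
  expect_error(select_ph_lower_bound(make_samples(numeric(0)), surf), "empty")
})

test_that("resting pH summary filters to the rest condition", {
  set.seed(101)
  rest <- make_samples(ph = rnorm(12, 7.51, 0.03))
  out <- resting_ph_summary(rest)
  expect_lt(abs(out[["mean"]] - 7.51), 0.02)
  expect_gt(out[["sd"]], 0)

  single <- make_samples(ph = 7.5)
  expect_equal(unname(resting_ph_summary(single)), c(7.5, 0))

  mixed <- make_samples(ph = c(7.5, 7.1 + 0.8), condition = c("rest", "dive"))
  expect_equal(resting_ph_summary(mixed)[["mean"]], 7.5)
  expect_error(resting_ph_summary(make_samples(7.4, condition = "dive")),
               "no resting")
})

test_that("blood sample validation enforces physiological invariants", {
  expect_error(make_samples(ph = 8.2), "range")
  expect_error(make_samples(ph = 7.4, pco2 = 0), "PCO2")
  expect_error(make_samples(ph = 7.4, lactate = -1), "lactate")
  expect_error(make_samples(ph = 7.4, condition = "swimming"), "condition")
})
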