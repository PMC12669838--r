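test_that("saturation at P50 is exactly 0.5 and boundary cases hold", {
  for (p50 in c(28, 31, 35, 37, 44.3)) {
    for (n in c(2.5, 3, 3.5)) {
      cv <- dissociation_curve(p50, n)
      expect_identical(hb_saturation(p50, cv), 0.5)
      expect_identical(hb_saturation(0, cv), 0)
    }
  }
  expect_error(hb_saturation(-1, dissociation_curve(35)), "non-negative")
  expect_error(dissociation_curve(0), "p50")
  expect_error(dissociation_curve(35, -1), "hill_n")
})

test_that("fulmar curve matches its printed Hill-plot equation", {
  fc <- fulmar_curve()
  # oracle: evaluate the printed regression directly at PO2 = 80
  odds <- 10^(2.74683 * log10(80) - 4.52219)
  expect_equal(hb_saturation(80, fc), odds / (1 + odds), tolerance = 1e-12)
  expect_equal(hb_saturation(80, fc), 0.8354, tolerance = 5e-4)
  expect_equal(round(po2_at_saturation(0.5, fc)), 44)
  expect_equal(po2_at_saturation(0.5, fc), 10^(4.52219 / 2.74683),
               tolerance = 1e-12)
})

test_that("po2_at_saturation inverts hb_saturation", {
  bm <- emperor_bohr()
  cv74 <- curve_at_ph(7.4, bm)
  expect_equal(po2_at_saturation(0.5, cv74), 31, tolerance = 1e-9)
  for (cv in list(cv74, fulmar_curve(), dissociation_curve(28, 3))) {
    for (x in c(5, 20, 80)) {
      expect_equal(po2_at_saturation(hb_saturation(x, cv), cv), x,
                   tolerance = 1e-9)
    }
  }
  expect_error(po2_at_saturation(0, cv74), "strictly within")
  expect_error(po2_at_saturation(1, cv74), "strictly within")
})

test_that("Bohr model reproduces anchors and interpolates log-linearly", {
  bm <- emperor_bohr()
  expect_equal(p50_at_ph(7.5, bm), 28)
  expect_equal(p50_at_ph(7.4, bm), 31)
  expect_equal(p50_at_ph(7.3, bm), 35)
  expect_equal(p50_at_ph(7.2, bm), 37)
  # oracle: least-squares slope of log10 P50 on pH over the four anchors
  ph <- c(7.5, 7.4, 7.3, 7.2)
  y <- log10(c(28, 31, 35, 37))
  slope <- sum((ph - mean(ph)) * (y - mean(y))) / sum((ph - mean(ph))^2)
  expect_equal(bm$bohr_slope, slope, tolerance = 1e-12)
  expect_equal(bm$bohr_slope, -0.4158, tolerance = 1e-3)
  # between anchors: linear in log10(P50)
  expect_equal(log10(p50_at_ph(7.35, bm)),
               mean(log10(c(31, 35))), tolerance = 1e-12)
  # extrapolation flagged, hard range enforced
  expect_message(p50_at_ph(7.1, bm), "extrapolating")
  expect_error(suppressMessages(p50_at_ph(6.9, bm)), "range")
  expect_error(suppressMessages(p50_at_ph(7.8, bm)), "range")
})

test_that("bohr_model rejects non-Bohr anchor sets", {
  expect_error(bohr_model(7.5, 28), "length")
  expect_error(bohr_model(c(7.5, 7.4), c(28, 28)), "decrease")
  expect_error(bohr_model(c(7.5, 7.4), c(31, 28)), "decrease")
})

test_that("saturation is monotone in po2, p50 and pH (Bohr direction)", {
  bm <- emperor_bohr()
  po2 <- seq(1, 150, by = 1)
  for (ph in c(7.2, 7.3, 7.4, 7.5)) {
    s <- hb_saturation(po2, curve_at_ph(ph, bm))
    expect_true(all(diff(s) > 0))
  }
  for (p in c(5, 20, 31, 40, 80, 150)) {
    sat_by_ph <- vapply(c(7.2, 7.3, 7.4, 7.5),
                        function(ph) hb_saturation(p, curve_at_ph(ph, bm)),
                        numeric(1L))
    expect_true(all(diff(sat_by_ph) > 0))  # saturation rises with pH
    sat_by_p50 <- vapply(c(28, 31, 35, 37),
                         function(p50) hb_saturation(p, dissociation_curve(p50)),
                         numeric(1L))
    expect_true(all(diff(sat_by_p50) < 0))
  }
})

test_that("the fulmar curve lies below every emperor curve at physiological PO2", {
  # the fulmar Hill exponent (2.747) differs from the emperor's (3.0), so
  # the curves necessarily cross near 5 mmHg where saturations are < 0.5%;
  # the published ordering holds over the physiological range
  bm <- emperor_bohr()
  po2 <- seq(6, 150, by = 0.5)
  s_f <- hb_saturation(po2, fulmar_curve())
  for (ph in c(7.2, 7.3, 7.4, 7.5)) {
    expect_true(all(s_f < hb_saturation(po2, curve_at_ph(ph, bm))))
  }
})

test_that("saturation_difference behaves like the Bohr-shift gap", {
  bm <- emperor_bohr()
  expect_equal(saturation_difference(0, 7.5, 7.3, bm), 0)
  expect_lt(saturation_difference(1e5, 7.5, 7.3, bm), 1e-4)
  po2 <- seq(1, 150, by = 1)
  expect_true(all(saturation_difference(po2, 7.5, 7.3, bm) >= 0))
  # direct evaluation at the geometric mean of the two P50s, n = 3
  p <- sqrt(28 * 35)
  expect_equal(saturation_difference(p, 7.5, 7.3, bm, hill_n = 3),
               100 * (hill_oracle(p, 28, 3) - hill_oracle(p, 35, 3)),
               tolerance = 1e-12)
  expect_error(saturation_difference(30, 7.3, 7.5, bm), "exceed")
})

test_that("curve config files round-trip through read_curve_config", {
  f1 <- withr::local_tempfile(fileext = ".dcf")
  writeLines(c("anchors_ph: 7.5 7.4 7.3 7.2",
               "anchors_p50: 28 31 35 37"), f1)
  bm <- read_curve_config(f1)
  expect_s3_class(bm, "bohr_model")
  expect_equal(p50_at_ph(7.3, bm), 35)
  f2 <- withr::local_tempfile(fileext = ".dcf")
  writeLines(c("p50: 44.3", "hill_n: 2.74683", "label: fulmar-like"), f2)
  cv <- read_curve_config(f2)
  expect_s3_class(cv, "dissociation_curve")
  expect_equal(cv$hill_n, 2.74683)
  f3 <- withr::local_tempfile(fileext = ".dcf")
  writeLines("label: nothing-else", f3)
  expect_error(read_curve_config(f3), "anchors")
})
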