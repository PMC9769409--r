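test_that("standard-curve fitting recovers known coefficients", {
  # exact line
  cv <- fit_standard_curve(data.frame(concentration = 0:2, absorbance = 0:2))
  expect_equal(cv$slope, 1)
  expect_equal(cv$intercept, 0)
  expect_equal(cv$r2, 1)

  # noiseless series at arbitrary coefficients: closed-form OLS recovers them
  std <- synthetic_standards("iaa", slope = 0.05, intercept = 0.02,
                             n_points = 8, noise_sd = 0)
  cv2 <- fit_standard_curve(std)
  expect_equal(cv2$slope, 0.05, tolerance = 1e-12)
  expect_equal(cv2$intercept, 0.02, tolerance = 1e-12)

  # independent closed-form OLS oracle on a noisy series
  std3 <- synthetic_standards("phosphate", slope = 0.003, intercept = 0.05,
                              n_points = 10, noise_sd = 0.004, seed = 11)
  cv3 <- fit_standard_curve(std3)
  x <- std3$concentration; y <- std3$absorbance
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  expect_equal(cv3$slope, b, tolerance = 1e-12)
  expect_equal(cv3$intercept, a, tolerance = 1e-12)

  expect_error(fit_standard_curve(data.frame(concentration = c(1, 1, 1),
                                             absorbance = c(.3, .4, .5))),
               "degenerate")
  expect_error(fit_standard_curve(data.frame(concentration = 0:1,
                                             absorbance = 0:1)),
               "at least 3")
  expect_warning(fit_standard_curve(
    data.frame(concentration = c(0, 1, 2, 3),
               absorbance = c(0, 0.9, 0.1, 1))), "below 0.98")
})

test_that("curve inversion maps absorbance back to concentration", {
  ident <- fit_standard_curve(data.frame(concentration = 0:3,
                                         absorbance = 0:3))
  expect_equal(as.numeric(concentration_from_absorbance(ident, 0.5)), 0.5)

  cv <- fit_standard_curve(synthetic_standards("iaa", slope = 0.05,
                                               intercept = 0.02,
                                               noise_sd = 0))
  expect_equal(as.numeric(concentration_from_absorbance(cv, 0.27)), 5,
               tolerance = 1e-9)
  # perfect-fit curves invert every standard point
  rec <- concentration_from_absorbance(cv, cv$standards$absorbance)
  expect_equal(as.numeric(rec), cv$standards$concentration, tolerance = 1e-9)

  # negatives flagged, censored companion attached, never clamped in place
  shifted <- fit_standard_curve(data.frame(concentration = 0:3,
                                           absorbance = 0.2 + 0:3))
  out <- concentration_from_absorbance(shifted, 0.1)
  expect_equal(as.numeric(out), -0.1)
  expect_true(attr(out, "flagged_negative"))
  expect_equal(attr(out, "censored"), 0)

  zero <- fit_standard_curve(data.frame(concentration = 0:3,
                                        absorbance = rep(1, 4)))
  expect_error(concentration_from_absorbance(zero, 0.5), "slope is zero")
})

test_that("percent inhibition follows 100*(C - T)/C with its boundary cases", {
  expect_equal(percent_inhibition(10, 10), 0)
  expect_equal(percent_inhibition(10, 0), 100)
  expect_equal(percent_inhibition(8.0, 4.1), 48.75)
  expect_error(percent_inhibition(0, 1), "positive")
  expect_warning(out <- percent_inhibition(5, 6), "negative inhibition")
  expect_lt(out, 0)

  # strictly decreasing in T; 0 iff T = C; 100 iff T = 0
  C <- 9.7
  Ts <- seq(0, C, length.out = 25)
  vals <- percent_inhibition(rep(C, 25), Ts)
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[c(1, 25)], c(100, 0))
})

test_that("siderophore percentage follows 100*(Ar - As)/Ar", {
  expect_equal(siderophore_percent(0.5, 0.5), 0)
  expect_equal(siderophore_percent(0.5, 0), 100)
  expect_equal(siderophore_percent(0.5, 0.25), 50)
  expect_error(siderophore_percent(0, 0.1), "positive")
  # strictly decreasing in As, bounded above by 100 for As >= 0
  as_vals <- seq(0, 1, length.out = 30)
  v <- siderophore_percent(rep(0.8, 30), as_vals)
  expect_true(all(diff(v) < 0))
  expect_true(all(v <= 100))
})

test_that("germination percentage handles full, zero and partial plates", {
  expect_equal(germination_percent(10, 10), 100)
  expect_equal(germination_percent(0, 10), 0)
  expect_equal(germination_percent(8, 10), 80)
  expect_error(germination_percent(1, 0), "positive")
  expect_error(germination_percent(11, 10), "outside")
})

test_that("chlorophyll equations are applied verbatim and are linear", {
  unit_a <- chlorophyll_ab(1, 0)
  expect_equal(unit_a$chl_a, 11.75)
  expect_equal(unit_a$chl_b, -3.96)
  expect_true(unit_a$flagged)
  unit_b <- chlorophyll_ab(0, 1)
  expect_equal(unit_b$chl_a, -2.35)
  expect_equal(unit_b$chl_b, 18.61)
  expect_true(unit_b$flagged)

  mid <- chlorophyll_ab(0.5, 0.2)
  expect_equal(mid$chl_a, 5.405)
  expect_equal(mid$chl_b, 1.742)
  expect_false(mid$flagged)

  # linearity: doubling both absorbances doubles both pigments
  dbl <- chlorophyll_ab(1.0, 0.4)
  expect_equal(dbl$chl_a, 2 * mid$chl_a)
  expect_equal(dbl$chl_b, 2 * mid$chl_b)
})

test_that("replicate summaries use SE = sd/sqrt(n)", {
  m <- measurement_with_error(c(1, 2, 3))
  expect_equal(m$mean, 2)
  expect_equal(m$se, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(m$se, 0.5773503, tolerance = 1e-6)
  expect_equal(measurement_with_error(c(2, 2, 2))$se, 0)
  expect_error(measurement_with_error(5), "insufficient")
})
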