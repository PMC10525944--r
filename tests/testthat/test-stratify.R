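test_that("fit_line matches the closed-form normal equations", {
  pts <- data.frame(qf = c(0, 0.5, 1), hr = c(30, 50, 72))
  exact <- fit_line(pts, "qf", "hr")
  # algebraic oracle on the packaged minimum-HR points
  fit <- regress_clinical_vs_qf(modality = "holter_min")
  x <- fit$points$x
  y <- fit$points$y
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept_oracle <- mean(y) - slope_oracle * mean(x)
  expect_equal(fit$slope, slope_oracle, tolerance = 1e-12)
  expect_equal(fit$intercept, intercept_oracle, tolerance = 1e-12)
  expect_equal(fit$r_squared, stats::cor(x, y)^2, tolerance = 1e-12)

  on_line <- data.frame(x = 1:5, y = 2 + 3 * (1:5))
  f1 <- suppressWarnings(fit_line(on_line, "x", "y"))
  expect_equal(f1$r_squared, 1)
  expect_equal(stats::residuals(f1$model), rep(0, 5),
               ignore_attr = TRUE, tolerance = 1e-12)

  sym <- data.frame(x = c(0, 1, 2), y = c(0, 1, 0))
  f2 <- fit_line(sym, "x", "y")
  expect_equal(f2$slope, 0)
  expect_equal(f2$r_squared, 0)

  expect_error(fit_line(data.frame(x = c(1, 1, 1), y = 1:3), "x", "y"),
               "degenerate")
  expect_error(fit_line(data.frame(x = 1, y = 2), "x", "y"), "at least 2")
})

test_that("two-point fits report no p-value but still fit", {
  f <- fit_line(data.frame(x = c(0, 1), y = c(1, 3)), "x", "y")
  expect_true(is.na(f$p_value))
  expect_equal(f$slope, 2)
  expect_true(f$no_clear_correlation)
})

test_that("tidy, glance and autoplot expose the fit", {
  f <- regress_clinical_vs_qf(modality = "resting")
  td <- tidy(f)
  expect_equal(nrow(td), 2)
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(f)
  expect_equal(gl$r.squared, f$r_squared)
  expect_s3_class(autoplot(f), "ggplot")
})

test_that("R-squared is invariant under affine rescaling of either axis", {
  rec <- load_clinical_tables()
  base <- regress_clinical_vs_qf(rec, modality = "holter_avg")
  rec2 <- rec
  rec2$hr_mean <- 3.2 * rec2$hr_mean - 11
  scaled_y <- regress_clinical_vs_qf(rec2, modality = "holter_avg")
  expect_equal(base$r_squared, scaled_y$r_squared, tolerance = 1e-12)
  qf2 <- load_reference_qf()
  qf2$qf_pC <- 0.4 * qf2$qf_pC + 0.05
  scaled_x <- regress_clinical_vs_qf(rec, modality = "holter_avg", qf = qf2)
  expect_equal(base$r_squared, scaled_x$r_squared, tolerance = 1e-12)
})

test_that("clinical pairing policy resolves every record to a Qf", {
  f_ex <- regress_clinical_vs_qf(modality = "holter_min", brunet = "exclude")
  f_a <- regress_clinical_vs_qf(modality = "holter_min", brunet = "a")
  f_b <- regress_clinical_vs_qf(modality = "holter_min", brunet = "b")
  expect_equal(f_a$n_points, f_ex$n_points + 1)
  expect_equal(f_b$n_points, f_ex$n_points + 1)
  # exercise heart rates: fit exists but is flagged uncorrelated
  f_exc <- regress_clinical_vs_qf(modality = "exercise_max")
  expect_true(f_exc$no_clear_correlation)
  expect_gte(f_exc$p_value, 0.05)
  # collapsing to a single x is rejected
  rec <- load_clinical_tables()
  wt_only <- rec[rec$qf_key %in% "WT" & rec$modality == "holter_min", ]
  expect_error(regress_clinical_vs_qf(wt_only, modality = "holter_min"),
               "degenerate")
})

test_that("model-rate regression accepts cached rates and computed Qf", {
  rates <- vagal_rate_table()
  f_tab <- regress_rate_vs_qf(tone = "vagal", qf_source = "table",
                              rates = rates)
  expect_equal(f_tab$n_points, 14)
  expect_gt(f_tab$slope, 0)
  w <- surrogate_waveform()
  f_cmp <- regress_rate_vs_qf(tone = "vagal", qf_source = "computed",
                              waveform = w, rates = rates)
  # the correlation is robust to the waveform stand-in
  expect_lt(abs(f_cmp$r_squared - f_tab$r_squared), 0.05)
  expect_error(
    regress_rate_vs_qf(tone = "vagal", qf_source = "computed", rates = rates),
    "waveform"
  )
})
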