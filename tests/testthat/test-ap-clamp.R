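test_that("trains tile the command cycle periodically", {
  w <- surrogate_waveform()
  cl <- attr(w, "cycle_length_ms")
  expect_equal(cl, 813)
  train <- build_train(w, 100)
  expect_equal(max(train$time_ms) + (cl - max(w$time_ms)), 100 * 813)
  expect_identical(build_train(w, 1), w)
  two <- build_train(w, 2)
  n <- nrow(w)
  expect_identical(two$vm_mV[seq_len(n) + n], two$vm_mV[seq_len(n)])
  # endpoint mismatch beyond 1 mV is flagged as non-periodic
  broken <- as_command_waveform(
    tibble::tibble(time_ms = seq(0, 100, by = 1),
                   vm_mV = seq(-60, -40, length.out = 101))
  )
  expect_error(build_train(broken, 2), "mismatch")
})

test_that("the DD window runs from the cycle minimum to the take-off", {
  # piecewise-linear toy: 0.02 V/s foot for 300 ms, then 1.5 V/s
  t_ramp <- seq(0, 320, by = 0.5)
  v_ramp <- ifelse(t_ramp <= 300, -80 + 0.02 * t_ramp,
                   -80 + 0.02 * 300 + 1.5 * (t_ramp - 300))
  toy <- as_command_waveform(tibble::tibble(time_ms = t_ramp, vm_mV = v_ramp))
  dd <- detect_dd_window(toy, top_threshold = 0.5)
  expect_equal(dd$t_mdp, 0)
  expect_lt(abs(dd$t_top - 300), 0.5 + 1e-9)  # within one sample
  expect_equal(dd$dd_duration, dd$t_top - dd$t_mdp)

  flat <- as_command_waveform(
    tibble::tibble(time_ms = seq(0, 500, by = 1), vm_mV = rep(-50, 501))
  )
  expect_error(detect_dd_window(flat), "no take-off")
})

test_that("Qf integrates the inward If charge with exact conductance linearity", {
  w <- surrogate_waveform()
  wt <- run_ap_clamp(w, if_parameters())
  expect_gt(wt$qf_pC, 0)
  expect_lt(wt$stability, 0.001)

  expect_equal(run_ap_clamp(w, if_parameters(g_f_scale = 0))$qf_pC, 0)
  half <- run_ap_clamp(w, if_parameters(g_f_scale = 0.5))
  expect_equal(half$qf_pC * 2, wt$qf_pC, tolerance = 1e-12)

  # independent quadrature oracle on the exported trace
  tr <- wt$if_trace
  win <- wt$window
  idx <- tr$time_ms >= win$t_mdp & tr$time_ms < win$t_mdp + win$dd_duration
  trapz <- -sum(diff(tr$time_ms[idx]) *
                (utils::head(tr$i_f_pA[idx], -1) + utils::tail(tr$i_f_pA[idx], -1)) / 2) / 1000
  expect_lt(abs(trapz - wt$qf_pC) / wt$qf_pC, 0.001)
})

test_that("Qf is insensitive to integration step and gate initialization", {
  w <- surrogate_waveform()
  q10 <- run_ap_clamp(w, if_parameters(), dt_us = 10)$qf_pC
  q20 <- run_ap_clamp(w, if_parameters(), dt_us = 20)$qf_pC
  expect_lt(abs(q20 - q10) / q10, 0.005)
  q_y0 <- run_ap_clamp(w, if_parameters(), y0 = 0)$qf_pC
  q_y1 <- run_ap_clamp(w, if_parameters(), y0 = 1)$qf_pC
  expect_lt(abs(q_y1 - q_y0) / q_y0, 0.001)
})

test_that("the Qf table reproduces conductance ratios and shift ordering", {
  w <- surrogate_waveform()
  lib <- hcn4_mutations()
  tab <- cached("qf_table", qf_table(lib, w))
  expect_equal(tab$name[1], "WT")
  expect_equal(nrow(tab), 14)
  # conductance-only mutants: ratio equals the scaling factor exactly
  expect_equal(tab$qf_ratio[tab$name == "R666Q"], 0.46, tolerance = 1e-9)
  expect_equal(tab$qf_ratio[tab$name == "G482R_b"], 0.35, tolerance = 1e-9)
  # growing hyperpolarizing shift monotonically erodes the charge
  shifts <- c(0, -5, -10, -20, -30, -44)
  qs <- vapply(shifts, function(s) {
    run_ap_clamp(w, if_parameters(shift_yinf = s, shift_tau = s))$qf_pC
  }, numeric(1))
  expect_true(all(diff(qs) < 0))
  # empty library: wild-type row only
  empty <- lib[0, ]
  expect_equal(qf_table(empty, w)$name, "WT")
})
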