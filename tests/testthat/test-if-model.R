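test_that("voltage shifts displace the base curves exactly", {
  v_grid <- seq(-140, 20, by = 0.5)
  for (shift in c(-44, -19.9, -14, -4.9, 5)) {
    p <- if_parameters(shift_yinf = shift, shift_tau = shift)
    expect_identical(steady_state_activation(v_grid, p),
                     steady_state_activation(v_grid - shift))
    expect_identical(time_constant(v_grid, p), time_constant(v_grid - shift))
  }
  # R375C: curve displaced 14 mV toward hyperpolarized potentials
  r375c <- apply_mutation(if_parameters(), "R375C")
  expect_equal(steady_state_activation(v_grid, r375c),
               steady_state_activation(v_grid + 14), tolerance = 1e-12)
})

test_that("steady-state activation is a decreasing fraction; tau is a positive bell", {
  v <- seq(-90, 40, by = 0.25)
  y <- steady_state_activation(v)
  expect_true(all(y > 0 & y < 1))
  # decreasing on each branch; the piecewise seam at -80 mV carries a small
  # (< 0.005) discontinuity inherited from the base-model formulation
  expect_true(all(diff(y[v < -80]) < 0))
  expect_true(all(diff(y[v >= -79.75]) < 0))
  expect_lt(abs(steady_state_activation(-79.999) -
                steady_state_activation(-80.001)), 0.005)
  tau <- time_constant(seq(-140, 0, by = 1))
  expect_true(all(tau > 0))
  # single interior maximum over the physiological range
  peak <- which.max(tau)
  expect_gt(peak, 1)
  expect_lt(peak, length(tau))
  expect_true(all(diff(tau[1:peak]) > 0) && all(diff(tau[peak:length(tau)]) < 0))
  # hyperpolarizing tau shift slows activation at -130 mV
  shifted <- if_parameters(shift_tau = -14)
  expect_gt(time_constant(-130, shifted), time_constant(-130))
  expect_error(steady_state_activation(NA_real_), "finite")
  expect_error(time_constant(Inf), "finite")
})

test_that("A414G applies its two shifts independently", {
  p <- apply_mutation(if_parameters(), "A414G")
  expect_equal(p$g_f_scale, 1)
  v <- seq(-120, -40, by = 1)
  expect_identical(steady_state_activation(v, p),
                   steady_state_activation(v + 19.9))
  expect_identical(time_constant(v, p), time_constant(v + 11.9))
})

test_that("the current is linear in conductance and reverses near -22 mV", {
  v <- seq(-90, 40, by = 1)
  y <- 0.5
  wt <- if_current(v, y)
  expect_identical(if_current(v, y, if_parameters(g_f_scale = 0)), rep(0, length(v)))
  expect_equal(if_current(v, y, if_parameters(g_f_scale = 0.5)), wt / 2)
  # R666Q: pure conductance mutant, current is 0.46 x wild type pointwise
  r666q <- apply_mutation(if_parameters(), "R666Q")
  expect_equal(if_current(v, y, r666q), 0.46 * wt)
  # inward below the effective reversal potential, outward above
  e_rev <- stats::uniroot(function(x) if_current(x, 1), c(-60, 20))$root
  expect_lt(e_rev, -15)
  expect_gt(e_rev, -30)
  expect_true(all(wt[v < e_rev - 1] < 0) && all(wt[v > e_rev + 1] > 0))
  expect_error(if_current(-60, 1.2), "\\[0, 1\\]")
})

test_that("the Euler gate update matches the analytic relaxation", {
  # closed-form oracle: y(T) = y_inf + (y0 - y_inf) exp(-T / tau)
  for (v in c(-100, -70)) {
    y_inf <- steady_state_activation(v)
    tau <- time_constant(v)
    y0 <- 0.9
    t_total <- 10 * tau
    n <- ceiling(t_total / 0.01)
    y <- y0
    for (i in seq_len(n)) y <- step_gate(y, v, dt = 0.01)
    exact <- y_inf + (y0 - y_inf) * exp(-n * 0.01 / tau)
    expect_lt(abs(y - exact), 1e-4)
    expect_lt(abs(y - exact) / exact, 1e-3)
  }
  # fixed point
  v <- -65
  expect_equal(step_gate(steady_state_activation(v), v), steady_state_activation(v))
  expect_error(step_gate(0.5, -65, dt = 0), "positive")
})

test_that("the gate stays within [0, 1] for arbitrary bounded commands", {
  set.seed(42)
  for (rep in 1:5) {
    v_seq <- stats::runif(400, -90, 40)
    y <- stats::runif(1)
    for (v in v_seq) y <- step_gate(y, v, dt = 5)  # coarse step stresses clamping
    expect_gte(y, 0)
    expect_lte(y, 1)
  }
})

test_that("mutation transforms follow the library and tone rules", {
  r375c <- apply_mutation(if_parameters(), "R375C", tone = "vagal")
  expect_equal(r375c$g_f_scale, 0.5)
  expect_equal(r375c$shift_yinf, -14)
  expect_equal(r375c$shift_tau, -14)
  # K530N: +5 mV extra depolarizing shift only under high iso
  k530n_hi <- apply_mutation(if_parameters(), "K530N", tone = "high_iso")
  expect_equal(k530n_hi$shift_yinf, -9)
  k530n_lo <- apply_mutation(if_parameters(), "K530N", tone = "vagal")
  expect_equal(k530n_lo$shift_yinf, -14)
  # 695X: fixed -10.9 mV at every tone, full conductance
  for (tone in c("vagal", "default", "high_iso")) {
    x695 <- apply_mutation(if_parameters(), "695X", tone = tone)
    expect_equal(x695$shift_yinf, -10.9)
    expect_equal(x695$g_f_scale, 1)
    expect_true(x695$fixed_kinetics)
  }
  expect_error(apply_mutation(if_parameters(), "Q999Z"), "unknown mutation")
  expect_error(apply_mutation(if_parameters(), "R375C", tone = "sympathetic"))
})

test_that("the mutation library loads, validates, and round-trips", {
  lib <- hcn4_mutations()
  expect_equal(nrow(lib), 13)
  expect_equal(sum(lib$name %in% c("G482R_a", "G482R_b")), 2)
  expect_false(anyDuplicated(lib$name) > 0)
  expect_true(all(lib$g_f_scale >= 0 & lib$g_f_scale <= 1))

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste("name,g_f_scale,shift_yinf_mV,shift_tau_mV,",
                   "shift_iso_extra_mV,source", sep = ""), empty)
  expect_equal(nrow(load_mutation_library(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,g_f_scale,shift_yinf_mV,shift_tau_mV,shift_iso_extra_mV,source",
               "X1,1.2,0,0,0,s"), bad)
  expect_error(load_mutation_library(bad), "g_f_scale")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,g_f_scale,shift_yinf_mV,shift_tau_mV,shift_iso_extra_mV,source",
               "X1,1,0,0,0,s", "X1,0.5,0,0,0,s"), dup)
  expect_error(load_mutation_library(dup), "duplicate")

  expect_error(if_parameters(g_f_scale = 1.5), "\\[0, 1\\]")
  expect_error(if_parameters(shift_yinf = Inf), "finite")
})
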