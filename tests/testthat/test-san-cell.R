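test_that("pacing metrics recover rates from constructed spike trains", {
  # regular train at exactly 813 ms spacing -> 60000/813 beats/min
  spike_times <- seq(0.5, 9.5, by = 0.813)
  tt <- seq(0, 10, by = 0.001)
  v <- rep(-60, length(tt))
  for (s in spike_times) {
    idx <- which(tt >= s & tt < s + 0.01)
    v[idx] <- 20  # brief suprathreshold deflection
  }
  m <- extract_pacing_metrics(tibble::tibble(time_s = tt, vm_mV = v),
                              window_s = 10)
  expect_equal(m$beating_rate, 60000 / 813, tolerance = 1e-6)
  expect_equal(m$flag, "ok")

  # jittered train: rate equals 60 / mean interval of the known spike times
  set.seed(7)
  jit <- sort(seq(0.5, 9.5, by = 0.7) + stats::runif(13, -0.05, 0.05))
  v2 <- rep(-60, length(tt))
  for (s in jit) v2[tt >= s & tt < s + 0.01] <- 20
  m2 <- extract_pacing_metrics(tibble::tibble(time_s = tt, vm_mV = v2),
                               window_s = 10)
  expect_equal(m2$beating_rate, 60 / mean(diff(jit)), tolerance = 1e-3)

  flat <- tibble::tibble(time_s = tt, vm_mV = rep(-55, length(tt)))
  mf <- extract_pacing_metrics(flat, window_s = 10)
  expect_equal(mf$beating_rate, 0)
  expect_equal(mf$flag, "quiescent")
})

test_that("the wild-type cell paces on a tight limit cycle", {
  sim <- cached("wt_default_20s",
                simulate_cell(cell_config(duration_s = 20), keep_states = TRUE))
  m <- sim$metrics
  expect_equal(m$flag, "ok")
  expect_gt(m$beating_rate, 50)
  expect_lt(m$beating_rate, 90)
  expect_lt(m$cl_sd_ms, 1)
  expect_lt(m$mdp_mV, -50)
  # gating variables stay in [0, 1]; concentrations stay positive
  gates <- c("y", "m", "h", "dL", "fL", "fCa", "dT", "fT", "paF", "paS",
             "piy", "n", "a", "q", "r", "rKur", "sKur")
  for (g in gates) {
    expect_gte(min(sim$trace[[g]]), 0)
    expect_lte(max(sim$trace[[g]]), 1)
  }
  for (conc in c("Cai", "Casub", "Cansr", "Cajsr"))
    expect_gt(min(sim$trace[[conc]]), 0)
})

test_that("adaptive and fixed-step integrations agree", {
  m_lsoda <- simulate_cell(cell_config(duration_s = 20))$metrics
  m_euler <- simulate_cell(cell_config(duration_s = 20, method = "euler",
                                       euler_dt_us = 5))$metrics
  expect_lt(abs(m_lsoda$beating_rate - m_euler$beating_rate), 0.2)
})

test_that("the final-window metrics describe a settled limit cycle", {
  r100 <- sim_rate(NULL, "default", 100)
  r200 <- sim_rate(NULL, "default", 200)
  expect_lt(abs(r200 - r100), 0.1)
})

test_that("autonomic tone orders the rate and mutants slow it at every tone", {
  expect_identical(set_autonomic_tone("default")$ach_mM, 0)
  expect_identical(set_autonomic_tone("default")$iso, 0)
  expect_equal(set_autonomic_tone("vagal")$ach_mM, 2e-5)
  expect_error(set_autonomic_tone("sympathetic"))

  rate30 <- function(mut, tone) {
    simulate_cell(cell_config(mutation = mut, tone = tone,
                              duration_s = 30))$metrics$beating_rate
  }
  wt <- vapply(c("vagal", "default", "high_iso"), rate30,
               numeric(1), mut = NULL)
  expect_true(wt["vagal"] < wt["default"] && wt["default"] < wt["high_iso"])
  for (mut in c("R375C", "Y481H", "G482R_b")) {
    mrate <- vapply(c("vagal", "default", "high_iso"), rate30,
                    numeric(1), mut = mut)
    expect_true(all(mrate < wt))
  }
})

test_that("removing If slows but does not stop default-tone pacing", {
  knockout <- tibble::tibble(
    name = "If_null", g_f_scale = 0, shift_yinf_mV = 0, shift_tau_mV = 0,
    shift_iso_extra_mV = 0, fixed_kinetics = FALSE, source = "synthetic"
  )
  m <- simulate_cell(cell_config(mutation = knockout,
                                 duration_s = 30))$metrics
  wt <- cached("wt_default_20s",
               simulate_cell(cell_config(duration_s = 20)))$metrics
  expect_gt(m$beating_rate, 0)
  expect_equal(m$flag, "ok")
  expect_lt(m$beating_rate, wt$beating_rate)
})
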