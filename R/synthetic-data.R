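# Stand-ins for the study's non-deposited inputs: a human-SAN-like command
# AP waveform matching the printed landmarks (the original prerecorded
# single-cell AP is not publicly available), and synthetic clinical cohorts
# with the statistical structure of the packaged heart-rate tables.

#' Landmark features of a surrogate SAN action potential
#'
#' @param cycle_length_ms Cycle length (default 813 ms).
#' @param dd_duration_ms Diastolic-depolarization duration, MDP to take-off
#'   (default 538 ms).
#' @param dd_amplitude_mV Depolarization during that window (default 23 mV).
#' @param mdp_mV Maximum diastolic potential.  Not a printed landmark; the
#'   default (-62 mV) is an assumption consistent with isolated human SAN
#'   cell recordings and is configurable.
#' @param peak_mV AP peak (same status as `mdp_mV`; default +15 mV).
#' @param tau_dd_frac Curvature of the saturating-exponential diastolic
#'   depolarization, as a fraction of `dd_duration_ms`.
#' @param upstroke_width_ms Width parameter of the sigmoidal upstroke.
#' @param repol_shape Exponent shaping the repolarization (larger = faster
#'   early repolarization).
#' @return A list of class `waveform_features`.
#' @export
waveform_features <- function(cycle_length_ms = 813, dd_duration_ms = 538,
                              dd_amplitude_mV = 23, mdp_mV = -62,
                              peak_mV = 15, tau_dd_frac = 0.6,
                              upstroke_width_ms = 2, repol_shape = 1.5) {
  f <- list(cycle_length_ms = cycle_length_ms, dd_duration_ms = dd_duration_ms,
            dd_amplitude_mV = dd_amplitude_mV, mdp_mV = mdp_mV,
            peak_mV = peak_mV, tau_dd_frac = tau_dd_frac,
            upstroke_width_ms = upstroke_width_ms, repol_shape = repol_shape)
  if (!all(vapply(f, function(x) is.numeric(x) && length(x) == 1 &&
                  is.finite(x), logical(1))))
    stop("all waveform features must be single finite numbers", call. = FALSE)
  if (dd_amplitude_mV <= 0)
    stop("dd_amplitude must be positive", call. = FALSE)
  if (dd_duration_ms <= 0 || dd_duration_ms > 0.8 * cycle_length_ms)
    stop("dd_duration must be positive and leave room for the AP ",
         "(at most 80% of the cycle length)", call. = FALSE)
  if (mdp_mV + dd_amplitude_mV >= peak_mV)
    stop("take-off potential (mdp + dd_amplitude) must lie below the peak",
         call. = FALSE)
  if (mdp_mV < -90 || peak_mV > 40)
    stop("waveform landmarks outside the [-90, 40] mV sanity range",
         call. = FALSE)
  if (tau_dd_frac <= 0 || upstroke_width_ms <= 0 || repol_shape <= 1)
    stop("shape parameters out of range (repol_shape must exceed 1)",
         call. = FALSE)
  structure(f, class = "waveform_features")
}

#' Generate a surrogate SAN command waveform
#'
#' Deterministically builds a smooth periodic action potential: a
#' saturating-exponential diastolic depolarization spanning exactly
#' `dd_amplitude_mV` over `dd_duration_ms`, a sigmoidal upstroke, and a
#' smooth repolarization returning to the MDP at the end of the cycle.  The
#' upstroke position and diastolic span are calibrated so that
#' [detect_dd_window()] with the given take-off threshold recovers the
#' requested window within one sample.
#'
#' @param f A [waveform_features()] object.
#' @param dt_ms Sampling interval (must be at most 0.1 ms).
#' @param top_threshold Take-off threshold the calibration targets, V/s.
#' @return A `command_waveform` tibble.
#' @examples
#' w <- generate_waveform()
#' detect_dd_window(w)
#' @export
generate_waveform <- function(f = waveform_features(), dt_ms = 0.1,
                              top_threshold = 0.5) {
  stopifnot(inherits(f, "waveform_features"),
            "dt must be positive and at most 0.1 ms" =
              dt_ms > 0 && dt_ms <= 0.1)
  T_cyc <- f$cycle_length_ms
  t1 <- f$dd_duration_ms
  tau <- f$tau_dd_frac * t1
  # the diastolic limb itself must stay well below the take-off threshold
  dd_slope0 <- f$dd_amplitude_mV / (tau * (1 - exp(-t1 / tau)))
  if (dd_slope0 > 0.8 * top_threshold)
    stop("infeasible features: diastolic slope approaches the take-off ",
         "threshold; increase dd_duration or tau_dd_frac", call. = FALSE)

  grid <- seq(0, T_cyc - dt_ms / 2, by = dt_ms)
  w_up <- f$upstroke_width_ms

  compose <- function(a, t_up) {
    t_peak <- t_up + 6 * w_up
    dd <- f$mdp_mV + a * (1 - exp(-grid / tau)) / (1 - exp(-t1 / tau))
    dd_peak <- f$mdp_mV + a * (1 - exp(-t_peak / tau)) / (1 - exp(-t1 / tau))
    a_up <- (f$peak_mV - dd_peak) / stats::plogis(6)
    v <- dd + a_up * stats::plogis((grid - t_up) / w_up)
    rep_idx <- grid > t_peak
    u <- (grid[rep_idx] - t_peak) / (T_cyc - t_peak)
    v[rep_idx] <- f$mdp_mV +
      (f$peak_mV - f$mdp_mV) * ((1 + cos(pi * u)) / 2)^f$repol_shape
    v
  }
  measure <- function(v) {
    w <- as_command_waveform(tibble::tibble(time_ms = grid, vm_mV = v),
                             cycle_length_ms = T_cyc)
    detect_dd_window(w, top_threshold = top_threshold)
  }

  # calibrate upstroke position and diastolic span against the discrete
  # detector (deterministic fixed-point iteration)
  a <- f$dd_amplitude_mV
  t_up <- t1 + 4 * w_up
  for (i in 1:40) {
    det <- measure(compose(a, t_up))
    dt_err <- t1 - det$dd_duration
    da_err <- f$dd_amplitude_mV - det$dd_amplitude
    if (abs(dt_err) <= dt_ms / 2 && abs(da_err) < 1e-9) break
    t_up <- t_up + dt_err
    a <- a + da_err
  }
  v <- compose(a, t_up)
  det <- measure(v)
  if (abs(det$dd_duration - t1) > dt_ms || det$dd_amplitude <= 0)
    stop("calibration failed for the requested feature combination",
         call. = FALSE)
  as_command_waveform(tibble::tibble(time_ms = grid, vm_mV = v),
                      cycle_length_ms = T_cyc)
}

#' Extract a command waveform from a cell simulation
#'
#' Runs (or reuses) a wild-type cell simulation and extracts one
#' steady-state AP cycle, from MDP to MDP, for use as a clamp command: an
#' alternative surrogate to [generate_waveform()].
#'
#' @param config A [cell_config()]; defaults to a wild-type, default-tone
#'   run of 60 s.
#' @param sim Optionally a precomputed `san_sim` (overrides `config`).
#' @return A single-cycle `command_waveform`.
#' @export
waveform_from_model <- function(config = cell_config(duration_s = 60),
                                sim = NULL) {
  if (is.null(sim)) sim <- simulate_cell(config)
  if (sim$metrics$flag != "ok" || sim$metrics$beating_rate <= 0)
    stop("quiescent simulation: no AP cycle to extract", call. = FALSE)
  tr <- sim$trace
  v <- tr$vm_mV
  up <- which(v[-length(v)] < -20 & v[-1] >= -20)
  if (length(up) < 3)
    stop("too few APs to extract a steady-state cycle", call. = FALSE)
  # MDP = minimum between the last three threshold crossings
  seg1 <- up[length(up) - 2]:up[length(up) - 1]
  seg2 <- up[length(up) - 1]:up[length(up)]
  i0 <- seg1[which.min(v[seg1])]
  i1 <- seg2[which.min(v[seg2])]
  if (abs(v[i0] - v[i1]) > 0.5)
    warning("extracted cycle endpoints differ by more than 0.5 mV")
  cl <- (tr$time_s[i1] - tr$time_s[i0]) * 1000
  # one period, excluding the duplicated end MDP sample
  vc <- pmin(pmax(v[i0:(i1 - 1)], -90), 40)
  # rotate so the cycle minimum sits at the start (limit-cycle wobble can
  # place the true minimum a few samples before the duplicated endpoint)
  im <- which.min(vc)
  if (im > 1) vc <- vc[c(im:length(vc), 1:(im - 1))]
  dt_ms <- 1000 * (tr$time_s[i0 + 1] - tr$time_s[i0])
  out <- tibble::tibble(time_ms = (seq_along(vc) - 1) * dt_ms, vm_mV = vc)
  as_command_waveform(out, cycle_length_ms = cl)
}

#' Generate a synthetic clinical cohort around a known Qf-to-heart-rate line
#'
#' Draws per-mutation carrier groups (and non-carrier groups at the
#' wild-type Qf) whose individual heart rates scatter around the linear
#' truth `hr = intercept + slope * qf`, then summarizes them as group mean
#' and SEM in the same schema as the packaged clinical tables.  Used for
#' end-to-end parameter-recovery checks of the regression layer.
#'
#' @param slope,intercept Truth line (beats/min per pC; beats/min).
#' @param qf Tibble of `name`, `qf_pC` anchoring the x-positions (default
#'   [load_reference_qf()]).
#' @param group_size Individuals per carrier group.
#' @param n_noncarrier_groups Number of non-carrier family groups at the
#'   wild-type Qf.
#' @param noise_sd Individual-level heart-rate SD, beats/min.
#' @param modality Modality label stamped on the records.
#' @param seed Integer seed (required; the generator is reproducible).
#' @return A tibble in the clinical-record schema.
#' @export
generate_clinical_cohort <- function(slope, intercept,
                                     qf = load_reference_qf(),
                                     group_size = 5, n_noncarrier_groups = 3,
                                     noise_sd = 3, modality = "holter_min",
                                     seed) {
  stopifnot(
    "noise_sd must be non-negative" = is.numeric(noise_sd) && noise_sd >= 0,
    "group sizes must be positive" =
      group_size >= 1 && n_noncarrier_groups >= 0,
    "a seed is required" = !missing(seed)
  )
  set.seed(seed)
  mut <- qf[qf$name != "WT", ]
  wt_qf <- qf$qf_pC[qf$name == "WT"]
  one_group <- function(name, key, x, group) {
    hr <- intercept + slope * x + stats::rnorm(group_size, 0, noise_sd)
    tibble::tibble(
      mutation = name, group = group, paired_mutation = name, qf_key = key,
      hr_mean = mean(hr),
      hr_sem = if (group_size > 1) stats::sd(hr) / sqrt(group_size) else 0,
      n = group_size, study = "synthetic", excluded = FALSE
    )
  }
  carriers <- purrr::map_dfr(seq_len(nrow(mut)), function(i) {
    one_group(mut$name[i], mut$name[i], mut$qf_pC[i], "carrier")
  })
  noncarriers <- purrr::map_dfr(seq_len(n_noncarrier_groups), function(i) {
    g <- one_group("non_carrier", "WT", wt_qf, "non_carrier")
    g$study <- paste0("synthetic_", i)
    g
  })
  out <- dplyr::bind_rows(carriers, noncarriers)
  out$modality <- modality
  out
}
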