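# Single-cell simulations of a human sinoatrial-node pacemaker cell.
#
# The ordinary-differential-equation system (32 states: membrane potential,
# gating variables, intracellular Ca2+ concentrations, SR release machinery
# and Ca2+ buffers) is the Fabbri et al. (2017) human SAN cell model,
# implemented in C (src/fs_model.c) and integrated either with deSolve's
# adaptive stiff solver (reference path) or with fixed-step forward Euler
# (verification path).  Intracellular Na+ is held at its model value, as in
# the original formulation.

# published steady-state starting point of the base model
.fs_initial_state <- c(
  Vm = -47.787168, y = 0.009508, m = 0.447724, h = 0.003058,
  dL = 0.001921, fL = 0.846702, fCa = 0.844449, dT = 0.268909, fT = 0.020484,
  paF = 0.011068, paS = 0.322999, piy = 0.873161, n = 0.003278, a = 0.00277,
  q = 0.430836, r = 0.014523, rKur = 0.011845, sKur = 0.845304,
  Cai = 9.15641e-6, Casub = 6.226104e-5, Cansr = 0.435148, Cajsr = 0.409551,
  Rr = 0.9308, O = 6.181512e-9, I = 4.595622e-10, RI = 0.069199,
  fTC = 0.017929, fTMC = 0.259947, fTMM = 0.653777, fCMi = 0.217311,
  fCMs = 0.158521, fCQ = 0.138975
)

.tone_levels <- c("default", "vagal", "high_iso")

#' Autonomic-tone overlay for the cell model
#'
#' Maps a tone label to the model-parameter overlay it engages: `"vagal"`
#' sets the acetylcholine concentration to 20 nmol/L (acting through the
#' model's ACh-dependent terms: IKACh activation, a hyperpolarizing If
#' shift, ICaL block and reduced SR Ca2+ uptake); `"default"` applies no
#' modulation; `"high_iso"` engages the base model's published 1 umol/L
#' isoprenaline overlay (If shift +7.5 mV, ICaL and IKs up-regulation with
#' gating shifts, INaK up-regulation, increased Ca2+ uptake).
#'
#' @param tone One of `"default"`, `"vagal"`, `"high_iso"`.
#' @return A tibble with columns `ach_mM` and `iso`.
#' @examples
#' set_autonomic_tone("vagal")
#' @export
set_autonomic_tone <- function(tone = .tone_levels) {
  tone <- match.arg(tone)
  tibble::tibble(
    tone = tone,
    ach_mM = if (tone == "vagal") 2e-5 else 0,
    iso = as.numeric(tone == "high_iso")
  )
}

#' Configuration for a pacemaker-cell simulation
#'
#' @param mutation `NULL` for wild type, a mutation name from
#'   [hcn4_mutations()], or a one-row mutation specification.
#' @param tone Autonomic tone, see [set_autonomic_tone()].
#' @param duration_s Total simulated time, s.
#' @param analysis_window_s Final window analyzed for pacing metrics, s.
#' @param method `"lsoda"` (adaptive stiff solver, reference) or `"euler"`
#'   (fixed-step verification path).
#' @param rtol,atol Relative/absolute solver tolerances (lsoda).
#' @param hmax_s Maximum solver step, s (lsoda).
#' @param sample_ms Output sampling interval, ms.
#' @param euler_dt_us Euler step, us (euler method only).
#' @param gks_scale Scale factor on the slow delayed-rectifier conductance
#'   (exposed for sensitivity analyses; default 1).
#' @return A list of class `cell_config`.
#' @export
cell_config <- function(mutation = NULL, tone = .tone_levels,
                        duration_s = 100, analysis_window_s = 5,
                        method = c("lsoda", "euler"),
                        rtol = 1e-7, atol = 1e-9, hmax_s = 1e-3,
                        sample_ms = 1, euler_dt_us = 5, gks_scale = 1) {
  tone <- match.arg(tone)
  method <- match.arg(method)
  stopifnot(
    "duration must cover the analysis window" =
      duration_s >= analysis_window_s && analysis_window_s > 0,
    "sampling interval must be positive" = sample_ms > 0,
    "Euler step must be positive" = euler_dt_us > 0
  )
  structure(
    list(mutation = mutation, tone = tone, duration_s = duration_s,
         analysis_window_s = analysis_window_s, method = method,
         rtol = rtol, atol = atol, hmax_s = hmax_s, sample_ms = sample_ms,
         euler_dt_us = euler_dt_us, gks_scale = gks_scale),
    class = "cell_config"
  )
}

# parameter vector handed to the C right-hand side
.fs_param_vector <- function(config) {
  tone <- set_autonomic_tone(config$tone)
  p <- if (is.null(config$mutation)) if_parameters()
       else apply_mutation(if_parameters(), config$mutation, tone = config$tone)
  c(ach = tone$ach_mM, iso = tone$iso, gf_scale = p$g_f_scale,
    shift_yinf = p$shift_yinf, shift_tau = p$shift_tau,
    fixed_kinetics = as.numeric(p$fixed_kinetics), gks_scale = config$gks_scale)
}

#' Simulate a human SAN pacemaker cell
#'
#' Integrates the full cell model for `duration_s` seconds from the base
#' model's published steady state and computes pacing metrics on the final
#' analysis window.  Mutant runs apply the mutation's If transform at the
#' configured tone (see [apply_mutation()]).
#'
#' @param config A [cell_config()].
#' @param keep_states Also return the full state matrix (gating variables,
#'   Ca2+ concentrations, buffers) as extra trace columns; supported by the
#'   `"lsoda"` method only.
#' @return A list of class `san_sim` with elements `trace` (tibble:
#'   `time_s`, `vm_mV`, plus state columns when `keep_states`), `metrics`
#'   (see [extract_pacing_metrics()]) and `config`.
#' @examples
#' \donttest{
#' sim <- simulate_cell(cell_config(tone = "default", duration_s = 20))
#' sim$metrics$beating_rate
#' }
#' @export
simulate_cell <- function(config = cell_config(), keep_states = FALSE) {
  stopifnot(inherits(config, "cell_config"))
  parms <- .fs_param_vector(config)
  if (config$method == "lsoda") {
    times <- seq(0, config$duration_s, by = config$sample_ms / 1000)
    out <- deSolve::lsoda(
      y = unname(.fs_initial_state), times = times,
      func = "fs_derivs", parms = unname(parms),
      dllname = "qfclamp", initfunc = "fs_initmod",
      rtol = config$rtol, atol = config$atol, hmax = config$hmax_s
    )
    if (attr(out, "istate")[1] < 0)
      stop("stiff solver failed to complete the simulation", call. = FALSE)
    trace <- tibble::tibble(time_s = out[, 1], vm_mV = out[, 2])
    if (keep_states) {
      states <- tibble::as_tibble(as.data.frame(out[, -(1:2), drop = FALSE]))
      names(states) <- names(.fs_initial_state)[-1]
      trace <- dplyr::bind_cols(trace, states)
    }
  } else {
    if (keep_states)
      warning("keep_states is only supported by the lsoda method")
    out <- .Call(c_fs_euler, unname(.fs_initial_state), unname(parms),
                 as.numeric(config$duration_s),
                 config$euler_dt_us * 1e-6, config$sample_ms / 1000)
    trace <- tibble::tibble(time_s = out[, 1], vm_mV = out[, 2])
  }
  metrics <- extract_pacing_metrics(trace, window_s = config$analysis_window_s)
  structure(list(trace = trace, metrics = metrics, config = config),
            class = "san_sim")
}

#' @export
print.san_sim <- function(x, ...) {
  cat("<san_sim>", x$config$tone, "tone,",
      if (is.null(x$config$mutation)) "wild type"
      else if (is.character(x$config$mutation)) x$config$mutation
      else x$config$mutation$name, "\n")
  print(x$metrics)
  invisible(x)
}

#' Pacing metrics from a voltage trace
#'
#' Action potentials are detected as upward crossings of a fixed threshold
#' (default -20 mV) separated by a refractory interval; crossing times are
#' refined by linear interpolation.  The beating rate is 60 / (mean
#' inter-AP interval in s) over the final window.
#'
#' @param trace Data frame with columns `time_s` and `vm_mV`.
#' @param window_s Final window analyzed, s.
#' @param threshold_mV AP detection threshold.
#' @param refractory_ms Minimum spacing between detected APs.
#' @return A one-row tibble: `beating_rate` (beats/min; 0 if quiescent),
#'   `cycle_length_ms`, `cl_sd_ms`, `mdp_mV`, `ap_count`, `flag`
#'   (`"ok"`, `"quiescent"`, or `"too_few_aps"`).
#' @export
extract_pacing_metrics <- function(trace, window_s = 5,
                                   threshold_mV = -20, refractory_ms = 100) {
  stopifnot(all(c("time_s", "vm_mV") %in% names(trace)))
  t_end <- max(trace$time_s)
  if (t_end - min(trace$time_s) < window_s)
    stop("trace shorter than the analysis window", call. = FALSE)
  win <- trace[trace$time_s >= t_end - window_s, ]
  v <- win$vm_mV
  tt <- win$time_s
  up <- which(v[-length(v)] < threshold_mV & v[-1] >= threshold_mV)
  no_rate <- function(flag, mdp) tibble::tibble(
    beating_rate = 0, cycle_length_ms = NA_real_, cl_sd_ms = NA_real_,
    mdp_mV = mdp, ap_count = length(up), flag = flag
  )
  if (length(up) == 0) return(no_rate("quiescent", min(v)))
  # linear interpolation of each crossing time
  frac <- (threshold_mV - v[up]) / (v[up + 1] - v[up])
  t_cross <- tt[up] + frac * (tt[up + 1] - tt[up])
  # enforce refractory spacing
  keep <- rep(TRUE, length(t_cross))
  last <- t_cross[1]
  for (i in seq_along(t_cross)[-1]) {
    if (t_cross[i] - last < refractory_ms / 1000) keep[i] <- FALSE
    else last <- t_cross[i]
  }
  t_cross <- t_cross[keep]
  if (length(t_cross) < 2) return(no_rate("too_few_aps", min(v)))
  ivl <- diff(t_cross)
  tibble::tibble(
    beating_rate = 60 / mean(ivl),
    cycle_length_ms = 1000 * mean(ivl),
    cl_sd_ms = if (length(ivl) > 1) 1000 * stats::sd(ivl) else NA_real_,
    mdp_mV = min(v),
    ap_count = length(t_cross),
    flag = "ok"
  )
}
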