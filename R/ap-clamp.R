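# Action-potential clamp: drive the reconstructed If with a command AP
# train, locate the diastolic-depolarization window of the final beat, and
# integrate the inward charge Qf.

#' Command waveform constructor
#'
#' Validates a time/voltage series for use as a voltage-clamp command.  The
#' waveform must hold at least one full cycle, start at time 0, be strictly
#' increasing in time, and stay within a sanity range of \[-90, +40\] mV.
#'
#' @param x Data frame with columns `time_ms` and `vm_mV` (or a 2-column
#'   numeric object).
#' @param cycle_length_ms Cycle length; defaults to the waveform duration
#'   plus one sample (the final sample is taken as the last point before the
#'   cycle repeats).
#' @return A tibble of class `command_waveform` with attribute
#'   `cycle_length_ms`.
#' @export
as_command_waveform <- function(x, cycle_length_ms = NULL) {
  x <- tibble::as_tibble(as.data.frame(x))
  if (!all(c("time_ms", "vm_mV") %in% names(x))) {
    if (ncol(x) >= 2) names(x)[1:2] <- c("time_ms", "vm_mV")
    else stop("waveform needs `time_ms` and `vm_mV` columns", call. = FALSE)
  }
  x <- x[, c("time_ms", "vm_mV")]
  stopifnot(
    "waveform must have at least 8 samples" = nrow(x) >= 8,
    "time must start at 0" = isTRUE(all.equal(x$time_ms[1], 0)),
    "time must be strictly increasing" = all(diff(x$time_ms) > 0),
    "Vm outside the [-90, 40] mV sanity range" =
      all(x$vm_mV >= -90 & x$vm_mV <= 40)
  )
  if (is.null(cycle_length_ms))
    cycle_length_ms <- max(x$time_ms) + stats::median(diff(x$time_ms))
  if (cycle_length_ms < max(x$time_ms))
    stop("cycle length shorter than the waveform", call. = FALSE)
  structure(x, cycle_length_ms = as.numeric(cycle_length_ms),
            class = c("command_waveform", class(x)))
}

#' Read a command waveform from CSV
#'
#' @param path Two-column CSV (`time_ms`, `vm_mV`) with a header.
#' @inheritParams as_command_waveform
#' @return A `command_waveform` tibble.
#' @export
read_waveform <- function(path, cycle_length_ms = NULL) {
  as_command_waveform(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    cycle_length_ms = cycle_length_ms
  )
}

#' Tile a single-cycle waveform into an AP train
#'
#' Repeats the command cycle periodically, as used to construct the ~82 s
#' command signal (100 cycles of an 813 ms AP) under which the reconstructed
#' current reaches stable periodic behaviour.
#'
#' @param w A `command_waveform` holding one cycle.
#' @param n_cycles Number of cycles (default 100).
#' @return A `command_waveform` of duration `n_cycles * cycle_length_ms`.
#' @export
build_train <- function(w, n_cycles = 100) {
  stopifnot(inherits(w, "command_waveform"),
            "n_cycles must be a positive count" =
              length(n_cycles) == 1 && n_cycles >= 1)
  n_cycles <- as.integer(n_cycles)
  if (n_cycles == 1) return(w)
  cl <- attr(w, "cycle_length_ms")
  # a periodic command must (nearly) return to its starting potential
  if (abs(w$vm_mV[nrow(w)] - w$vm_mV[1]) > 1)
    stop("waveform endpoint mismatch exceeds 1 mV; not periodic", call. = FALSE)
  tiled <- purrr::map_dfr(seq_len(n_cycles) - 1L, function(k) {
    tibble::tibble(time_ms = w$time_ms + k * cl, vm_mV = w$vm_mV)
  })
  structure(tiled, cycle_length_ms = cl,
            n_cycles = n_cycles,
            class = c("command_waveform", class(tibble::tibble())))
}

#' Locate the diastolic-depolarization window
#'
#' The window runs from the maximum diastolic potential (MDP; the minimum of
#' the cycle) to the take-off potential (TOP; the first subsequent point
#' where dV/dt exceeds the take-off threshold).  The search wraps across the
#' cycle boundary if the MDP sits at the end of the cycle.
#'
#' @param w A `command_waveform` (single cycle or train; the first cycle is
#'   analyzed).
#' @param top_threshold Take-off threshold on dV/dt, V/s (default 0.5).
#' @return One-row tibble: `t_mdp`, `t_top` (ms, within the cycle),
#'   `dd_duration` (ms), `dd_amplitude` (mV), `mdp_mV`, `top_mV`.
#' @export
detect_dd_window <- function(w, top_threshold = 0.5) {
  stopifnot(inherits(w, "command_waveform"), top_threshold > 0)
  cl <- attr(w, "cycle_length_ms")
  cyc <- w[w$time_ms < cl - 1e-9, ]
  tt <- cyc$time_ms
  v <- cyc$vm_mV
  n <- length(v)
  i_mdp <- which.min(v)
  # unwrap: continue the search past the cycle end if needed
  t2 <- c(tt, tt + cl)
  v2 <- c(v, v)
  dvdt <- diff(v2) / diff(t2)  # mV/ms = V/s, forward difference
  idx <- seq(i_mdp, i_mdp + n - 2)
  hit <- idx[which(dvdt[idx] > top_threshold)[1]]
  if (is.na(hit))
    stop("no take-off: dV/dt never exceeds ", top_threshold,
         " V/s after the MDP", call. = FALSE)
  t_mdp <- tt[i_mdp]
  t_top_unwrapped <- t2[hit]
  tibble::tibble(
    t_mdp = t_mdp,
    t_top = t_top_unwrapped %% cl,
    dd_duration = t_top_unwrapped - t_mdp,
    dd_amplitude = v2[hit] - v[i_mdp],
    mdp_mV = v[i_mdp],
    top_mV = v2[hit]
  )
}

# resample one command cycle onto the integration grid (linear interpolation,
# periodic: the sample at t = cycle_length wraps to t = 0)
.resample_cycle <- function(w, dt_ms) {
  cl <- attr(w, "cycle_length_ms")
  cyc <- w[w$time_ms < cl - 1e-9, ]
  grid <- seq(0, cl - dt_ms / 2, by = dt_ms)
  v <- stats::approx(
    x = c(cyc$time_ms, cl), y = c(cyc$vm_mV, cyc$vm_mV[1]),
    xout = grid, rule = 2
  )$y
  list(time_ms = grid, vm_mV = v)
}

#' Run a simulated AP-clamp experiment on If
#'
#' Integrates the If activation gate over a periodic command train (forward
#' Euler, default step 10 us), retains the final cycle, and integrates the
#' inward If over the diastolic-depolarization window to obtain the charge
#' Qf.  The gate starts at its steady state for the initial command
#' potential.  Periodic stability is asserted: the diastolic charge of the
#' final two cycles must agree within 0.1%.
#'
#' @param w A single-cycle `command_waveform` (it is tiled internally) or a
#'   train built with [build_train()] (its cycle count is reused).
#' @param p [if_parameters()] for the channel under study.
#' @param n_cycles Cycles in the train (default 100).
#' @param dt_us Integration step, microseconds (default 10).
#' @param top_threshold Take-off threshold passed to [detect_dd_window()].
#' @param y0 Optional initial gate occupancy (defaults to steady state at
#'   the initial command potential).
#' @return An object of class `qf_result`: a list with `qf_pC` (positive
#'   magnitude of inward charge), `window` (the [detect_dd_window()] row),
#'   `if_trace` (tibble `time_ms`, `vm_mV`, `i_f_pA` over the final cycle),
#'   `stability` (relative change of Qf over the last two cycles) and
#'   `n_cycles`.
#' @export
run_ap_clamp <- function(w, p = if_parameters(), n_cycles = 100, dt_us = 10,
                         top_threshold = 0.5, y0 = NULL) {
  stopifnot(inherits(w, "command_waveform"), inherits(p, "if_parameters"),
            dt_us > 0, n_cycles >= 1)
  if (!is.null(attr(w, "n_cycles"))) {
    n_cycles <- attr(w, "n_cycles")
    one <- w[w$time_ms < attr(w, "cycle_length_ms") - 1e-9, ]
    w <- as_command_waveform(one, cycle_length_ms = attr(w, "cycle_length_ms"))
  }
  dt_ms <- dt_us / 1000
  window <- detect_dd_window(w, top_threshold = top_threshold)
  rs <- .resample_cycle(w, dt_ms)
  yinf <- steady_state_activation(rs$vm_mV, p)
  tau <- time_constant(rs$vm_mV, p)
  if (is.null(y0)) y0 <- yinf[1]
  res <- .Call(c_clamp_gate, yinf, tau, dt_ms, as.integer(n_cycles),
               as.numeric(y0))
  i_f <- if_current(rs$vm_mV, res$y_final, p)
  i_prev <- if_current(rs$vm_mV, res$y_prev, p)

  # modular window: handles an MDP sitting near the end of the stored cycle
  cl <- attr(w, "cycle_length_ms")
  in_win <- ((rs$time_ms - window$t_mdp) %% cl) < window$dd_duration
  # pA * ms -> pC via 1e-3, single conversion point
  charge <- function(i) -sum(i[in_win]) * dt_ms * 1e-3
  qf <- charge(i_f)
  qf_prev <- charge(i_prev)
  stability <- if (qf == 0 && qf_prev == 0) 0 else
    abs(qf - qf_prev) / max(abs(qf), abs(qf_prev))
  if (n_cycles > 1 && is.finite(stability) && stability >= 0.001)
    stop(sprintf(paste0("unstable clamp: diastolic charge drifts %.3g%% ",
                        "between the final two cycles"), 100 * stability),
         call. = FALSE)
  structure(
    list(
      qf_pC = qf,
      window = window,
      if_trace = tibble::tibble(time_ms = rs$time_ms, vm_mV = rs$vm_mV,
                                i_f_pA = i_f),
      stability = stability,
      n_cycles = n_cycles
    ),
    class = "qf_result"
  )
}

#' @export
print.qf_result <- function(x, ...) {
  cat(sprintf("<qf_result> Qf = %.4g pC over a %.0f ms window (%.3g mV span)\n",
              x$qf_pC, x$window$dd_duration, x$window$dd_amplitude))
  invisible(x)
}

#' Diastolic If charge for every library entry
#'
#' Runs [run_ap_clamp()] for the wild type and for each mutant in the
#' library under the same command waveform.
#'
#' @param library Mutation library tibble (default [hcn4_mutations()]).
#' @param w Command waveform (single cycle).
#' @param ... Passed to [run_ap_clamp()].
#' @return A tibble `name`, `qf_pC`, `qf_ratio` (relative to wild type),
#'   wild type first, mutants in library order.
#' @export
qf_table <- function(library = hcn4_mutations(), w, ...) {
  wt <- run_ap_clamp(w, if_parameters(), ...)$qf_pC
  rows <- purrr::map_dbl(seq_len(nrow(library)), function(i) {
    p <- apply_mutation(if_parameters(), library[i, ], tone = "default")
    run_ap_clamp(w, p, ...)$qf_pC
  })
  tibble::tibble(
    name = c("WT", library$name),
    qf_pC = c(wt, rows),
    qf_ratio = c(wt, rows) / wt
  )
}
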