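# Hodgkin-Huxley description of the HCN4-mediated 'funny' current If and the
# transform layer that applies mutation-induced changes (conductance scaling,
# hyperpolarizing shifts of the activation curves).
#
# The wild-type formulation is the If component of the Fabbri et al. (2017,
# J Physiol 595:2365) human sinoatrial-node cell model, whose If equations
# derive from voltage-clamp data on isolated human SAN cells (Verkerk &
# Wilders 2010).  The fully activated conductance is split into Na+ and K+
# components; a single first-order activation gate y has a sigmoid steady
# state and a bell-shaped time constant.

# base-model constants (uS, mV, mM)
.if_const <- list(
  g_f = 0.00427,          # fully activated conductance, uS
  alpha_fna = 0.5927,     # Na:K split of the fully activated conductance
  v_half = -97.134,       # centre of the sigmoid component of y-infinity
  k_slope = 8.1752,       # slope factor of that sigmoid, mV
  nao = 140, nai = 5, ko = 5.4, ki = 140
)

.rtonf <- 8314.472 * 310 / 96485.3415  # RT/F, mV

.if_e_na <- .rtonf * log(.if_const$nao / .if_const$nai)
.if_e_k <- .rtonf * log(.if_const$ko / .if_const$ki)

#' Parameter set for the funny current
#'
#' Bundles the wild-type If formulation with the mutation transform state:
#' a conductance scaling factor and hyperpolarizing shifts applied to the
#' steady-state activation curve and to the time-constant curve.  Negative
#' shifts displace the curves toward hyperpolarized potentials (the base
#' curves are evaluated at `V - shift`).
#'
#' @param g_f_scale Fraction in \[0, 1\] scaling the fully activated
#'   conductance (1 = wild type).
#' @param shift_yinf Shift of the steady-state activation curve, mV.
#' @param shift_tau Shift of the time-constant curve, mV.
#' @param shift_iso_extra Additional shift engaged only under beta-adrenergic
#'   ('high iso') tone, mV.
#' @param fixed_kinetics If `TRUE` the voltage dependence is insensitive to
#'   the cell model's cAMP-dependent (ACh/isoprenaline) shifts, as for a
#'   channel lacking a functional cyclic-nucleotide-binding domain.
#' @return An object of class `if_parameters`.
#' @examples
#' wt <- if_parameters()
#' r375c <- if_parameters(g_f_scale = 0.5, shift_yinf = -14, shift_tau = -14)
#' @export
if_parameters <- function(g_f_scale = 1, shift_yinf = 0, shift_tau = 0,
                          shift_iso_extra = 0, fixed_kinetics = FALSE) {
  stopifnot(
    "g_f_scale must be a single number in [0, 1]" =
      is.numeric(g_f_scale) && length(g_f_scale) == 1 &&
      is.finite(g_f_scale) && g_f_scale >= 0 && g_f_scale <= 1,
    "shifts must be single finite numbers" =
      all(vapply(list(shift_yinf, shift_tau, shift_iso_extra),
                 function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                 logical(1))),
    "fixed_kinetics must be TRUE or FALSE" =
      is.logical(fixed_kinetics) && length(fixed_kinetics) == 1
  )
  structure(
    list(g_f_scale = g_f_scale, shift_yinf = shift_yinf,
         shift_tau = shift_tau, shift_iso_extra = shift_iso_extra,
         fixed_kinetics = fixed_kinetics),
    class = "if_parameters"
  )
}

#' @export
print.if_parameters <- function(x, ...) {
  wt <- x$g_f_scale == 1 && x$shift_yinf == 0 && x$shift_tau == 0
  cat("<if_parameters>", if (wt) "(wild type)" else "", "\n")
  cat(sprintf("  g_f scale: %.3g   shift y-inf: %.3g mV   shift tau: %.3g mV\n",
              x$g_f_scale, x$shift_yinf, x$shift_tau))
  if (x$shift_iso_extra != 0)
    cat(sprintf("  extra shift under high iso: %+.3g mV\n", x$shift_iso_extra))
  if (x$fixed_kinetics)
    cat("  voltage dependence fixed (cAMP-insensitive)\n")
  invisible(x)
}

.check_voltage <- function(V) {
  if (!is.numeric(V) || length(V) == 0 || any(!is.finite(V)))
    stop("`V` must be finite numeric (mV)", call. = FALSE)
}

# base curves at u = V - shift
.y_inf_base <- function(u) {
  ifelse(u < -80,
         0.01329 + 0.99921 / (1 + exp((u + 97.134) / 8.1752)),
         0.0002501 * exp(-u / 12.861))
}

.tau_y_base_s <- function(u) {
  1 / (0.36 * (u + 148.8) / (exp(0.066 * (u + 148.8)) - 1) +
       0.1 * (u + 87.3) / (1 - exp(-0.2 * (u + 87.3)))) - 0.054
}

#' Steady-state activation of If
#'
#' Evaluates the wild-type steady-state activation curve at `V - shift_yinf`;
#' the curve decreases monotonically with voltage (the channel activates on
#' hyperpolarization).
#'
#' @param V Membrane potential, mV (vectorized).
#' @param p An [if_parameters()] object.
#' @return Activation gate steady state (fraction).
#' @export
steady_state_activation <- function(V, p = if_parameters()) {
  .check_voltage(V)
  stopifnot(inherits(p, "if_parameters"))
  .y_inf_base(V - p$shift_yinf)
}

#' Time constant of If (de)activation
#'
#' Evaluates the wild-type bell-shaped time-constant curve at
#' `V - shift_tau`.
#'
#' @inheritParams steady_state_activation
#' @return Time constant, ms (strictly positive).
#' @export
time_constant <- function(V, p = if_parameters()) {
  .check_voltage(V)
  stopifnot(inherits(p, "if_parameters"))
  1000 * .tau_y_base_s(V - p$shift_tau)
}

#' Funny current at a given voltage and gate occupancy
#'
#' The fully activated conductance is split into Na+ and K+ components
#' (split ratio from the base model); the current is linear in the gate
#' occupancy `y` and in the conductance scaling factor.
#'
#' @inheritParams steady_state_activation
#' @param y Activation gate occupancy in \[0, 1\] (vectorized with `V`).
#' @return Current in pA (negative = inward).
#' @export
if_current <- function(V, y, p = if_parameters()) {
  .check_voltage(V)
  if (!is.numeric(y) || any(!is.finite(y)) || any(y < 0 | y > 1))
    stop("`y` must be within [0, 1]", call. = FALSE)
  stopifnot(inherits(p, "if_parameters"))
  g_na <- p$g_f_scale * .if_const$g_f * .if_const$alpha_fna / (1 + .if_const$alpha_fna)
  g_k <- p$g_f_scale * .if_const$g_f / (1 + .if_const$alpha_fna)
  # uS * mV = nA; reported in pA
  1000 * y * (g_na * (V - .if_e_na) + g_k * (V - .if_e_k))
}

#' One forward-Euler update of the If activation gate
#'
#' Advances `dy/dt = (y_inf(V) - y) / tau_y(V)` by one explicit Euler step,
#' clamping the result to \[0, 1\].
#'
#' @inheritParams if_current
#' @param dt Time step, ms (default 0.01 ms = 10 us).
#' @return Updated gate occupancy.
#' @export
step_gate <- function(y, V, dt = 0.01, p = if_parameters()) {
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a positive time step in ms", call. = FALSE)
  .check_voltage(V)
  y_new <- y + dt * (steady_state_activation(V, p) - y) / time_constant(V, p)
  pmin(pmax(y_new, 0), 1)
}

#' Apply a mutation to the wild-type If parameters
#'
#' Copies the conductance scaling factor and voltage-dependence shifts from a
#' mutation specification onto the wild-type parameters.  Under
#' beta-adrenergic tone (`tone = "high_iso"`) the mutation's
#' `shift_iso_extra` is added to both shifts (e.g. K530N, whose heteromeric
#' channels show a larger cAMP-induced depolarizing shift).  Vagal tone does
#' not alter mutation shifts.
#'
#' @param base Wild-type [if_parameters()].
#' @param m A mutation name (looked up in [hcn4_mutations()]) or a one-row
#'   data frame with the mutation-library columns.
#' @param tone One of `"default"`, `"vagal"`, `"high_iso"`.
#' @return An [if_parameters()] object with the mutation applied.
#' @examples
#' apply_mutation(if_parameters(), "R375C", tone = "vagal")
#' @export
apply_mutation <- function(base = if_parameters(), m,
                           tone = c("default", "vagal", "high_iso")) {
  tone <- match.arg(tone)
  stopifnot(inherits(base, "if_parameters"))
  if (is.character(m)) {
    lib <- hcn4_mutations()
    row <- lib[lib$name == m, ]
    if (nrow(row) != 1)
      stop("unknown mutation name: ", m, call. = FALSE)
    m <- row
  }
  if (!is.data.frame(m) || nrow(m) != 1)
    stop("`m` must be a mutation name or a one-row mutation specification",
         call. = FALSE)
  extra <- if (tone == "high_iso") m$shift_iso_extra_mV else 0
  if_parameters(
    g_f_scale = m$g_f_scale,
    shift_yinf = m$shift_yinf_mV + extra,
    shift_tau = m$shift_tau_mV + extra,
    shift_iso_extra = m$shift_iso_extra_mV,
    fixed_kinetics = isTRUE(m$fixed_kinetics)
  )
}

#' Load a mutation-parameter library
#'
#' Reads a CSV library of heteromeric mutation-induced If changes (one row
#' per in vitro characterization: conductance scaling factor and
#' voltage-dependence shifts).  The packaged default library is returned by
#' [hcn4_mutations()].
#'
#' @param path Path to a CSV file with columns `name`, `g_f_scale`,
#'   `shift_yinf_mV`, `shift_tau_mV`, `shift_iso_extra_mV`, `fixed_kinetics`,
#'   `source` (plus optional metadata columns).
#' @return A tibble, one row per mutant entry.
#' @export
load_mutation_library <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lib <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(lib) == 0) {
    return(tibble::tibble(
      name = character(), g_f_scale = numeric(), shift_yinf_mV = numeric(),
      shift_tau_mV = numeric(), shift_iso_extra_mV = numeric(),
      fixed_kinetics = logical(), source = character()
    ))
  }
  required <- c("name", "g_f_scale", "shift_yinf_mV", "shift_tau_mV",
                "shift_iso_extra_mV", "source")
  missing <- setdiff(required, names(lib))
  if (length(missing) > 0)
    stop("mutation library is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"fixed_kinetics" %in% names(lib)) lib$fixed_kinetics <- FALSE
  lib$fixed_kinetics <- as.logical(lib$fixed_kinetics)
  if (anyDuplicated(lib$name))
    stop("duplicate mutation names in library", call. = FALSE)
  bad <- !is.finite(lib$g_f_scale) | lib$g_f_scale < 0 | lib$g_f_scale > 1
  if (any(bad))
    stop("g_f_scale outside [0, 1] for: ",
         paste(lib$name[bad], collapse = ", "), call. = FALSE)
  shifts <- c(lib$shift_yinf_mV, lib$shift_tau_mV, lib$shift_iso_extra_mV)
  if (any(!is.finite(shifts)))
    stop("non-finite voltage shift in library", call. = FALSE)
  tibble::as_tibble(lib)
}

#' Packaged HCN4 loss-of-function mutation library
#'
#' The default library of heteromeric (wild type + mutant) HCN4 channel
#' characterizations: 13 entries across 12 mutations (G482R appears twice,
#' `"G482R_a"` from the Milano et al. characterization and `"G482R_b"` from
#' the Schweizer et al. one).  Wild type is implicit
#' (`if_parameters()`).
#'
#' @return A tibble with one row per mutant entry.
#' @examples
#' hcn4_mutations()
#' @export
hcn4_mutations <- function() {
  load_mutation_library(
    system.file("extdata", "hcn4_mutations.csv", package = "qfclamp",
                mustWork = TRUE)
  )
}
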