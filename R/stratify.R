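# Correlation analyses: model beating rate vs Qf and clinical heart rate vs
# Qf, with ordinary-least-squares statistics (R^2 and the regression F-test,
# equivalent to a one-way ANOVA on the fitted line).

#' Ordinary least-squares line fit
#'
#' Fits `y ~ x` by OLS and reports slope, intercept, the coefficient of
#' determination (squared Pearson correlation) and the p-value of the
#' regression F-test with (1, n-2) degrees of freedom.  With fewer than 3
#' points the line is still fitted but no p-value is reported.
#'
#' @param data Data frame of points.
#' @param x,y Column names (strings) of the predictor and response.
#' @param label Optional column name holding point labels.
#' @param weights Optional column name with case weights.
#' @return An object of class `qf_fit`; see [tidy.qf_fit()] and
#'   [glance.qf_fit()].
#' @examples
#' fit_line(data.frame(qf = c(0, 0.5, 1), hr = c(30, 50, 72)), "qf", "hr")
#' @export
fit_line <- function(data, x = "qf_pC", y = "value", label = NULL,
                     weights = NULL) {
  stopifnot(is.data.frame(data), x %in% names(data), y %in% names(data))
  pts <- tibble::tibble(
    label = if (!is.null(label)) as.character(data[[label]])
            else as.character(seq_len(nrow(data))),
    x = as.numeric(data[[x]]),
    y = as.numeric(data[[y]]),
    w = if (!is.null(weights)) as.numeric(data[[weights]]) else 1
  )
  pts <- pts[is.finite(pts$x) & is.finite(pts$y), ]
  if (nrow(pts) < 2)
    stop("need at least 2 points with finite x and y", call. = FALSE)
  if (stats::var(pts$x) == 0)
    stop("degenerate predictor: all x values are equal", call. = FALSE)
  mod <- stats::lm(y ~ x, data = pts, weights = pts$w)
  sm <- summary(mod)
  n <- nrow(pts)
  p_value <- if (n >= 3) {
    f <- sm$fstatistic
    unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE))
  } else NA_real_
  structure(
    list(
      slope = unname(stats::coef(mod)[2]),
      intercept = unname(stats::coef(mod)[1]),
      r_squared = sm$r.squared,
      p_value = p_value,
      n_points = n,
      points = pts[, c("label", "x", "y")],
      model = mod,
      no_clear_correlation = is.na(p_value) || p_value >= 0.05
    ),
    class = "qf_fit"
  )
}

#' @export
print.qf_fit <- function(x, ...) {
  cat(sprintf(
    "<qf_fit> y = %.3g + %.3g x   R^2 = %.3f   p = %s   n = %d%s\n",
    x$intercept, x$slope, x$r_squared,
    if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3),
    x$n_points,
    if (x$no_clear_correlation) "   [no clear correlation]" else ""
  ))
  invisible(x)
}

#' Tidy a Qf regression
#'
#' @param x A `qf_fit` object.
#' @param ... Unused.
#' @return One row per model term with estimates and standard errors.
#' @export
#' @method tidy qf_fit
tidy.qf_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("(Intercept)", "qf"),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' Summarize a Qf regression
#'
#' @inheritParams tidy.qf_fit
#' @return A one-row tibble: `r.squared`, `p.value` (regression F-test),
#'   `slope`, `intercept`, `n`, `no_clear_correlation`.
#' @export
#' @method glance qf_fit
glance.qf_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, p.value = x$p_value, slope = x$slope,
    intercept = x$intercept, n = x$n_points,
    no_clear_correlation = x$no_clear_correlation
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Model beating rate regressed on Qf
#'
#' Simulates the pacemaker-cell beating rate for the wild type and every
#' library mutant at one autonomic tone, pairs each with its Qf (either the
#' packaged reference values or values recomputed under AP clamp with a
#' supplied waveform), and fits an OLS line.
#'
#' @param library Mutation library (default [hcn4_mutations()]).
#' @param tone Autonomic tone for the simulations.
#' @param qf_source `"table"` for the packaged reference Qf, `"computed"`
#'   to recompute Qf with [qf_table()] on `waveform`.
#' @param waveform Command waveform, required when `qf_source = "computed"`.
#' @param rates Optional precomputed tibble (`name`, `beating_rate`)
#'   covering `"WT"` and every library entry; when supplied no simulations
#'   are run (cached-run reuse).
#' @param duration_s,analysis_window_s Simulation settings.
#' @param ... Passed to [cell_config()].
#' @return A `qf_fit` whose points carry variant labels.
#' @export
regress_rate_vs_qf <- function(library = hcn4_mutations(),
                               tone = c("vagal", "default", "high_iso"),
                               qf_source = c("table", "computed"),
                               waveform = NULL, rates = NULL,
                               duration_s = 100, analysis_window_s = 5, ...) {
  tone <- match.arg(tone)
  qf_source <- match.arg(qf_source)
  nm <- c("WT", library$name)
  if (is.null(rates)) {
    rate_of <- function(mutation) {
      cfg <- cell_config(mutation = mutation, tone = tone,
                         duration_s = duration_s,
                         analysis_window_s = analysis_window_s, ...)
      simulate_cell(cfg)$metrics$beating_rate
    }
    rates <- tibble::tibble(
      name = nm,
      beating_rate = c(rate_of(NULL),
                       purrr::map_dbl(library$name, rate_of))
    )
  }
  stopifnot(all(nm %in% rates$name))
  qf <- if (qf_source == "table") load_reference_qf(nm)
        else {
          if (is.null(waveform))
            stop("`waveform` is required when qf_source = \"computed\"",
                 call. = FALSE)
          tab <- qf_table(library, waveform)
          tab[match(nm, tab$name), c("name", "qf_pC")]
        }
  pts <- dplyr::inner_join(qf, rates, by = "name")
  fit_line(pts, x = "qf_pC", y = "beating_rate", label = "name")
}

#' Clinical heart rate regressed on Qf
#'
#' Pairs each clinical group-level record with a Qf (carriers at their
#' mutation's Qf, non-carriers at the wild-type Qf) and fits an OLS line for
#' one modality.  Records from the Brunet-Garcia G482R family carry no
#' companion in vitro characterization; by default they are excluded, or
#' they can be forced onto either G482R parameter set.
#'
#' @param records Clinical records (default [load_clinical_tables()]).
#' @param modality One of `"holter_min"`, `"holter_avg"`, `"holter_max"`,
#'   `"resting"`, `"exercise_max"`.
#' @param qf Qf lookup table (default [load_reference_qf()]); supply a
#'   recomputed [qf_table()] to use surrogate-waveform charges.
#' @param brunet `"exclude"` (default), `"a"` (pair with the Milano-based
#'   G482R_a parameters) or `"b"` (Schweizer-based G482R_b).
#' @param include_noncarriers Include non-carrier family groups at the
#'   wild-type Qf (default TRUE).
#' @param include_singletons Include single-individual (n = 1) groups
#'   (default TRUE).
#' @param weight_by_n Weight group means by group size (default FALSE,
#'   unweighted).
#' @return A `qf_fit`; `no_clear_correlation` is set when p >= 0.05.
#' @examples
#' glance(regress_clinical_vs_qf(modality = "resting"))
#' @export
regress_clinical_vs_qf <- function(records = load_clinical_tables(),
                                   modality = "holter_min",
                                   qf = load_reference_qf(),
                                   brunet = c("exclude", "a", "b"),
                                   include_noncarriers = TRUE,
                                   include_singletons = TRUE,
                                   weight_by_n = FALSE) {
  brunet <- match.arg(brunet)
  stopifnot(modality %in% .modality_levels)
  rec <- records[records$modality == modality & !records$excluded, ]
  if (!include_noncarriers) rec <- rec[rec$group != "non_carrier", ]
  if (!include_singletons) rec <- rec[rec$n > 1, ]
  if (brunet == "exclude") rec <- rec[!is.na(rec$qf_key), ]
  else rec$qf_key[is.na(rec$qf_key)] <- paste0("G482R_", brunet)
  if (nrow(rec) < 2)
    stop("fewer than 2 usable records for modality ", modality, call. = FALSE)
  rec$qf_pC <- qf$qf_pC[match(rec$qf_key, qf$name)]
  if (anyNA(rec$qf_pC))
    stop("no Qf value for key(s): ",
         paste(unique(rec$qf_key[is.na(rec$qf_pC)]), collapse = ", "),
         call. = FALSE)
  rec$point_label <- paste(rec$mutation, rec$study, sep = " / ")
  fit_line(rec, x = "qf_pC", y = "hr_mean", label = "point_label",
           weights = if (weight_by_n) "n" else NULL)
}
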