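# Packaged clinical heart-rate records and reference diastolic If charges,
# transcribed from the published group-level summaries of the clinical
# studies of each mutation (24 h Holter minimum/average/maximum, resting,
# and maximal exercise heart rates) and from the reference AP-clamp
# reconstruction performed with the original (non-public) prerecorded human
# SAN waveform.

.modality_levels <- c("holter_min", "holter_avg", "holter_max",
                      "resting", "exercise_max")

#' Load the packaged clinical heart-rate tables
#'
#' Group-level heart rates for heterozygous HCN4 mutation carriers and,
#' where reported, non-carriers from the same families.  One record per
#' (mutation, study, modality); `qf_key` names the Qf-library entry the
#' record pairs with (`NA` for the Brunet-Garcia G482R family, which has no
#' companion in vitro characterization; see [regress_clinical_vs_qf()]).
#' The R375C exercise value, obtained from an incomplete Bruce protocol, is
#' retained with `excluded = TRUE` and never used in regressions.
#'
#' @param include_excluded Keep records flagged `excluded` (default FALSE).
#' @return A tibble of clinical records.
#' @examples
#' dplyr::filter(load_clinical_tables(), modality == "holter_min")
#' @export
load_clinical_tables <- function(include_excluded = FALSE) {
  path <- system.file("extdata", "clinical_heart_rates.csv",
                      package = "qfclamp", mustWork = TRUE)
  rec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = "NA")
  stopifnot(
    "clinical fixture schema violation" = all(
      c("mutation", "group", "paired_mutation", "qf_key", "modality",
        "hr_mean", "hr_sem", "n", "study", "excluded") %in% names(rec)),
    "heart rates must be positive" = all(rec$hr_mean > 0),
    "group sizes must be at least 1" = all(rec$n >= 1),
    "unknown modality label" = all(rec$modality %in% .modality_levels),
    "(mutation, study, modality) must be unique" =
      !anyDuplicated(rec[, c("mutation", "study", "modality")])
  )
  if (!include_excluded) rec <- rec[!rec$excluded, ]
  tibble::as_tibble(rec)
}

#' Load the reference diastolic If charges
#'
#' Reference Qf values (pC) for the wild type and the 13 mutant library
#' entries, computed under AP clamp with the original prerecorded human SAN
#' waveform.  These anchor the clinical correlations; they are only
#' reproducible as mutant-to-wild-type ratios with the surrogate waveform
#' (the original recording is not deposited).
#'
#' @param name Optional entry name(s) to look up; errors on unknown names.
#' @return A tibble `name`, `qf_pC` (14 rows when `name` is NULL).
#' @examples
#' load_reference_qf("Y481H")
#' @export
load_reference_qf <- function(name = NULL) {
  path <- system.file("extdata", "qf_reference.csv",
                      package = "qfclamp", mustWork = TRUE)
  qf <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot("Qf fixture schema violation" =
              identical(names(qf), c("name", "qf_pC")) && all(qf$qf_pC > 0))
  if (!is.null(name)) {
    unknown <- setdiff(name, qf$name)
    if (length(unknown) > 0)
      stop("unknown Qf reference name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    qf <- qf[match(name, qf$name), ]
  }
  tibble::as_tibble(qf)
}
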