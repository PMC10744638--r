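# Identification criteria and sample-level exclusion rules: retention time
# +/- 0.02 min and quantifier/qualifier ion ratio +/- 20% relative to a
# processed standard, per-analyte area cutoffs, internal-standard recovery
# below 50% and Delta-8-THC interference.

#' Derive reference retention times and ion ratios from standard injections
#'
#' Processes one or more standard-solution injections (e.g. the
#' correction-factor runs of the all-analyte 2.5 ng/mL mixture) and averages
#' the observed apex retention time and quantifier/qualifier ion ratio per
#' analyte. Identification is always relative to a processed standard, never
#' to hard-coded values.
#'
#' @param chroms Long chromatogram tibble with an `injection_id` column
#'   covering the standard injections.
#' @param panel A `panel_config`.
#'
#' @return A tibble: `analyte`, `ref_rt`, `ref_ratio`, `n_injections`.
#' @export
reference_from_standards <- function(chroms, panel) {
  peaks <- chroms |>
    dplyr::group_by(.data$injection_id) |>
    dplyr::group_modify(~ process_injection(.x, panel)) |>
    dplyr::ungroup()
  quant <- dplyr::filter(peaks, .data$role == "quantifier", .data$found)
  qual <- dplyr::filter(peaks, .data$role == "qualifier") |>
    dplyr::select("injection_id", "analyte",
      qual_area = "area", qual_found = "found"
    )
  quant |>
    dplyr::left_join(qual, by = c("injection_id", "analyte")) |>
    dplyr::mutate(ratio = ifelse(.data$qual_found & .data$area > 0,
      .data$qual_area / .data$area, NA_real_
    )) |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(
      ref_rt = mean(.data$rt_apex),
      ref_ratio = mean(.data$ratio, na.rm = TRUE),
      n_injections = dplyr::n(),
      .groups = "drop"
    )
}

#' Apply the identification criteria to one analyte
#'
#' A detection is `confirmed` when all criteria pass, `partial` when the
#' quantifier peak is present but at least one other criterion fails, and
#' `absent` otherwise. Criteria (all inclusive at the tolerance edges):
#' retention time within +/- `rt_tol` of the standard's, ion ratio within
#' `(1 +/- ratio_tol)` times the standard's, quantifier area at or above the
#' analyte's cutoff.
#'
#' @param quantifier,qualifier One-row peak results ([find_peak()] /
#'   [epimer_pair_resolve()] rows).
#' @param reference A list or one-row tibble with `ref_rt` and `ref_ratio`
#'   from a processed standard.
#' @param panel A `panel_config`.
#' @param analyte Analyte id (supplies the area cutoff).
#'
#' @return A one-row tibble: `analyte`, `status` (`confirmed` / `partial` /
#'   `absent`), `failed` (comma-separated failed criteria among `RT`,
#'   `ion-ratio`, `area-cutoff`, `quantifier-missing`).
#' @export
apply_identification <- function(quantifier, qualifier, reference, panel,
                                 analyte) {
  if (is.null(reference) || length(reference) == 0 ||
    is.na(reference$ref_rt)) {
    stop("no processed standard reference for ", analyte, call. = FALSE)
  }
  cutoff <- panel$analytes$area_cutoff[panel$analytes$analyte == analyte]
  if (length(cutoff) != 1) stop("unknown analyte ", analyte, call. = FALSE)

  if (!isTRUE(quantifier$found)) {
    return(tibble::tibble(
      analyte = analyte, status = "absent", failed = "quantifier-missing"
    ))
  }
  failed <- character(0)
  eps <- 1e-9 # keep the inclusive tolerance edges robust to rounding
  if (abs(quantifier$rt_apex - reference$ref_rt) > panel$rt_tol + eps) {
    failed <- c(failed, "RT")
  }
  ratio <- ion_ratio(quantifier, qualifier)
  ratio_ok <- !is.na(ratio) && !is.na(reference$ref_ratio) &&
    ratio >= (1 - panel$ratio_tol) * reference$ref_ratio * (1 - eps) &&
    ratio <= (1 + panel$ratio_tol) * reference$ref_ratio * (1 + eps)
  if (!ratio_ok) failed <- c(failed, "ion-ratio")
  if (quantifier$area < cutoff) failed <- c(failed, "area-cutoff")

  tibble::tibble(
    analyte = analyte,
    status = if (length(failed) == 0) "confirmed" else "partial",
    failed = paste(failed, collapse = ",")
  )
}

#' Sample-level exclusion rules
#'
#' A case is excluded when the recovery of any deuterated internal standard
#' is lower than 50% of the mean calibrator IS area (strict inequality,
#' exactly 50% is retained), or when Delta-8-THC interference is confirmed.
#'
#' @param case_is_areas Named numeric: IS peak areas in the case injection.
#' @param calibrator_is_areas Named numeric: mean IS peak areas across the
#'   calibrator injections; must be positive.
#' @param delta8_confirmed Logical: confirmed Delta-8-THC (or
#'   Delta-8-THC-COOH) call in the sample.
#'
#' @return A list of class `sample_validity`: `recovery` (named numeric),
#'   `delta8`, `excluded`, `reason` (`NA`, `"IS-recovery"` or
#'   `"delta8-interference"`).
#' @export
sample_exclusions <- function(case_is_areas, calibrator_is_areas,
                              delta8_confirmed = FALSE) {
  ids <- names(calibrator_is_areas)
  if (any(calibrator_is_areas <= 0)) {
    stop("calibrator IS areas must be positive", call. = FALSE)
  }
  recovery <- case_is_areas[ids] / calibrator_is_areas[ids]
  low <- any(recovery < 0.5)
  excluded <- low || isTRUE(delta8_confirmed)
  structure(
    list(
      recovery = recovery,
      delta8 = isTRUE(delta8_confirmed),
      excluded = excluded,
      reason = if (low) {
        "IS-recovery"
      } else if (isTRUE(delta8_confirmed)) {
        "delta8-interference"
      } else {
        NA_character_
      }
    ),
    class = "sample_validity"
  )
}

#' Detect all panel analytes in one case
#'
#' Orchestrates peak picking, identification and the exclusion rules for one
#' case injection: every non-IS analyte receives a detection status, and --
#' when calibrator IS areas are supplied -- the sample validity is assessed
#' from the measured IS recoveries and the Delta-8-THC screen.
#'
#' @param chroms Long chromatogram tibble of one injection (all panel
#'   channels present; missing channels are an error).
#' @param reference Reference table from [reference_from_standards()].
#' @param panel A `panel_config`.
#' @param calibrator_is_areas Optional named numeric of mean calibrator IS
#'   areas (enables the exclusion assessment).
#'
#' @return A list: `detections` (tibble `analyte`, `status`, `failed`,
#'   `quant_area`, `quant_rt`, `ion_ratio`, `partial`), `is_areas` (named
#'   numeric), `validity` (a `sample_validity` or `NULL`).
#' @export
detect_case <- function(chroms, reference, panel, calibrator_is_areas = NULL) {
  peaks <- process_injection(chroms, panel)
  quant <- dplyr::filter(peaks, .data$role == "quantifier")
  qual <- dplyr::filter(peaks, .data$role == "qualifier")
  analytes <- panel$analytes$analyte

  detections <- purrr::map_dfr(analytes, function(a) {
    q1 <- quant[quant$analyte == a, ]
    q2 <- qual[qual$analyte == a, ]
    ref <- reference[reference$analyte == a, ]
    if (nrow(ref) == 0) {
      stop("no processed standard reference for ", a, call. = FALSE)
    }
    apply_identification(q1, q2, ref, panel, a) |>
      dplyr::mutate(
        quant_area = q1$area, quant_rt = q1$rt_apex,
        ion_ratio = ion_ratio(q1, q2), partial = q1$partial
      )
  })

  is_peaks <- dplyr::filter(peaks, .data$role == "IS")
  is_areas <- stats::setNames(is_peaks$area, is_peaks$analyte)

  validity <- NULL
  if (!is.null(calibrator_is_areas)) {
    delta8 <- any(detections$status[detections$analyte == "D8-THC"] == "confirmed")
    validity <- sample_exclusions(is_areas, calibrator_is_areas, delta8)
  }
  list(detections = detections, is_areas = is_areas, validity = validity)
}
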