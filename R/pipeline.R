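# End-to-end orchestration: standards -> calibrations and correction
# factors -> per-case detection and quantification -> case records.

#' Process many injections into a peak table
#'
#' @param chroms Long chromatogram tibble with an `injection_id` column.
#' @param panel A `panel_config`.
#' @return The [process_injection()] table with an `injection_id` column.
#' @export
process_injections <- function(chroms, panel) {
  idx <- split(seq_len(nrow(chroms)), chroms$injection_id)
  purrr::imap_dfr(idx, function(rows, id) {
    dplyr::mutate(process_injection(chroms[rows, ], panel),
      injection_id = id, .before = 1
    )
  })
}

# Per-injection response factors for every quantifiable analyte:
# quantifier area over the assigned internal standard's area.
injection_response_factors <- function(peaks, panel) {
  quant <- dplyr::filter(peaks, .data$role == "quantifier")
  is_areas <- peaks |>
    dplyr::filter(.data$role == "IS") |>
    dplyr::select("injection_id", is_id = "analyte", is_area = "area")
  quant |>
    dplyr::left_join(panel$analytes[, c("analyte", "is_id")], by = "analyte") |>
    dplyr::left_join(is_areas, by = c("injection_id", "is_id")) |>
    dplyr::mutate(rf = response_factor(.data$area, .data$is_area)) |>
    dplyr::select("injection_id", "analyte", "rf", area = "area", "is_area")
}

#' Fit calibration curves from simulated calibration runs
#'
#' Processes the calibration injections, computes response factors and fits
#' one weighted calibration model per directly calibrated analyte
#' (Delta-9-THC, 11-OH-THC, THC-COOH), carrying the panel LLOQ.
#'
#' @param cal_run Output of [simulate_calibration_runs()] (or a list with
#'   `chromatograms` and `levels`).
#' @param panel A `panel_config`.
#' @param weighting Passed to [fit_calibration()].
#'
#' @return A named list of `calibration_model` objects, plus attribute
#'   `is_means` (mean calibrator IS areas, the denominator of the recovery
#'   rule).
#' @export
fit_panel_calibrations <- function(cal_run, panel, weighting = "1/x") {
  peaks <- process_injections(cal_run$chromatograms, panel)
  rfs <- injection_response_factors(peaks, panel) |>
    dplyr::left_join(cal_run$levels, by = "injection_id") |>
    dplyr::filter(.data$level > 0)
  direct <- panel$analytes$analyte[is.na(panel$analytes$surrogate) &
    panel$analytes$analyte != "D8-THC"]
  models <- lapply(direct, function(a) {
    d <- rfs[rfs$analyte == a, ]
    fit_calibration(d$level, d$rf,
      weighting = weighting,
      lloq = panel$analytes$lloq[panel$analytes$analyte == a],
      analyte = a
    )
  })
  names(models) <- direct
  is_means <- peaks |>
    dplyr::filter(.data$role == "IS") |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(mean_area = mean(.data$area), .groups = "drop")
  attr(models, "is_means") <- stats::setNames(is_means$mean_area, is_means$analyte)
  models
}

#' Correction factors from replicate-day standard runs
#'
#' Processes the correction-factor runs of the all-analyte standard mixture,
#' computes per-day response factors, and derives one correction factor per
#' borrowed-curve analyte against its surrogate, preserving same-day pairing.
#'
#' @param corr_run Output of [simulate_correction_runs()].
#' @param panel A `panel_config`.
#' @param aggregate Passed to [correction_factor()].
#'
#' @return A named list of `correction_factor` objects (one per analyte with
#'   a surrogate in the panel).
#' @export
panel_correction_factors <- function(corr_run, panel, aggregate = "mean") {
  peaks <- process_injections(corr_run$chromatograms, panel)
  rfs <- injection_response_factors(peaks, panel) |>
    dplyr::left_join(corr_run$days, by = "injection_id") |>
    dplyr::arrange(.data$day)
  borrowed <- panel$analytes |>
    dplyr::filter(!is.na(.data$surrogate))
  cfs <- lapply(seq_len(nrow(borrowed)), function(i) {
    a <- borrowed$analyte[i]
    s <- borrowed$surrogate[i]
    correction_factor(
      rfs$rf[rfs$analyte == a], rfs$rf[rfs$analyte == s],
      target = a, surrogate = s, aggregate = aggregate
    )
  })
  stats::setNames(cfs, borrowed$analyte)
}

#' Run the full pipeline on a cohort
#'
#' Detects and quantifies every case of a simulated (or otherwise supplied)
#' cohort: peak picking, identification against the processed standard
#' reference, sample-exclusion assessment, response factors, direct and
#' borrowed-curve concentration estimation with LLOQ censoring, and group
#' assignment of the included cases.
#'
#' @param chroms Long cohort chromatogram tibble (`injection_id` = case id).
#' @param panel A `panel_config`.
#' @param reference Output of [reference_from_standards()].
#' @param calibrations Output of [fit_panel_calibrations()].
#' @param correction_factors Output of [panel_correction_factors()].
#' @param calibrator_is_areas Named numeric of mean calibrator IS areas
#'   (defaults to the `is_means` attribute of `calibrations`).
#'
#' @return A list of class `cohort_result`:
#'   `records` -- per case x analyte tibble with detection status, failed
#'   criteria, response factor, concentration `value`, `censor` and `method`;
#'   `validity` -- per-case exclusion table;
#'   `groups` -- group assignment of included cases.
#' @export
process_cohort <- function(chroms, panel, reference, calibrations,
                           correction_factors,
                           calibrator_is_areas = attr(calibrations, "is_means")) {
  idx <- split(seq_len(nrow(chroms)), chroms$injection_id)
  per_case <- purrr::imap(idx, function(rows, id) {
    detect_case(chroms[rows, ], reference, panel, calibrator_is_areas)
  })

  validity <- purrr::imap_dfr(per_case, function(res, id) {
    v <- res$validity
    tibble::tibble(
      case_id = id,
      excluded = v$excluded,
      reason = v$reason,
      min_recovery = min(v$recovery),
      delta8 = v$delta8
    )
  })

  records <- purrr::imap_dfr(per_case, function(res, id) {
    det <- dplyr::filter(res$detections, .data$analyte != "D8-THC")
    det$rf <- response_factor(
      det$quant_area,
      res$is_areas[panel$analytes$is_id[match(det$analyte, panel$analytes$analyte)]]
    )
    est <- purrr::map_dfr(seq_len(nrow(det)), function(i) {
      a <- det$analyte[i]
      surrogate <- panel$analytes$surrogate[panel$analytes$analyte == a]
      if (is.na(surrogate)) {
        estimate_concentration(det$rf[i], calibrations[[a]],
          cf = NULL, status = det$status[i]
        )
      } else {
        estimate_concentration(det$rf[i], calibrations[[surrogate]],
          cf = correction_factors[[a]], status = det$status[i]
        )
      }
    })
    dplyr::bind_cols(tibble::tibble(case_id = id), det, est)
  })

  included <- records |>
    dplyr::semi_join(dplyr::filter(validity, !.data$excluded), by = "case_id")
  groups <- group_cases(included)

  structure(
    list(records = records, validity = validity, groups = groups),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(
    "<cohort_result> ", dplyr::n_distinct(x$records$case_id), " cases (",
    sum(x$validity$excluded), " excluded); groups: ",
    paste(names(table(x$groups$group)), table(x$groups$group),
      sep = ":", collapse = " "
    ), "\n",
    sep = ""
  )
  invisible(x)
}

#' Detect metabolites across incubation series
#'
#' Runs detection on every injection of one or more incubation series
#' (typically substrate series plus their negative controls) and returns the
#' long status table consumed by [incubation_calls()].
#'
#' @param series A list of outputs of [simulate_incubation_series()].
#' @param reference Output of [reference_from_standards()].
#' @param panel A `panel_config`.
#'
#' @return A tibble: `substrate`, `timepoint`, `with_nadph`, `analyte`,
#'   `status`, `failed`.
#' @export
incubation_detections <- function(series, reference, panel) {
  purrr::map_dfr(series, function(s) {
    idx <- split(seq_len(nrow(s$chromatograms)), s$chromatograms$injection_id)
    purrr::imap_dfr(idx, function(rows, id) {
      res <- detect_case(s$chromatograms[rows, ], reference, panel)
      meta <- s$injections[s$injections$injection_id == id, ]
      res$detections |>
        dplyr::filter(.data$analyte != "D8-THC") |>
        dplyr::transmute(
          substrate = meta$substrate,
          timepoint = meta$timepoint,
          with_nadph = meta$with_nadph,
          analyte = .data$analyte,
          status = .data$status,
          failed = .data$failed
        )
    })
  })
}
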