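# Cohort grouping, prevalence and concentration summaries, the relative-
# median statistic, and qualitative incubation call matrices.

# Nearest-integer percent with round-half-up semantics (83.78 -> 84,
# 50.45 -> 50, 6.67 -> 7), consistent with the reported percentages.
round_half_up <- function(x) floor(x + 0.5)

#' Group cases by Delta-9-THC and HHC presence
#'
#' Each included case lands in exactly one group by confirmed detection
#' status: A (THC positive, HHC negative), B (both positive), C (both
#' negative), D (HHC only). HHC is positive when either the 9R or the 9S
#' epimer is confirmed.
#'
#' @param detections Tibble with columns `case_id`, `analyte`, `status`
#'   (excluded cases already removed).
#'
#' @return A tibble: `case_id`, `group`.
#' @export
group_cases <- function(detections) {
  flags <- detections |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(
      thc = any(.data$analyte == "D9-THC" & .data$status == "confirmed"),
      hhc = any(.data$analyte %in% c("9R-HHC", "9S-HHC") &
        .data$status == "confirmed"),
      .groups = "drop"
    )
  flags |>
    dplyr::mutate(group = dplyr::case_when(
      .data$thc & !.data$hhc ~ "A",
      .data$thc & .data$hhc ~ "B",
      !.data$thc & !.data$hhc ~ "C",
      TRUE ~ "D"
    )) |>
    dplyr::select("case_id", "group")
}

#' Per-analyte prevalence with nearest-integer percents
#'
#' Adds `percent = round(100 * positives / group_size)` (half-up) to a
#' grouped count skeleton, the arithmetic behind a positives table.
#'
#' @param skeleton Tibble with columns `positives` and `group_size` (and any
#'   identifying columns such as `group`, `analyte`).
#'
#' @return The input with a `percent` column.
#' @export
#' @examples
#' prevalence(tibble::tibble(analyte = "9R-HHC-COOH", positives = 186, group_size = 222))
prevalence <- function(skeleton) {
  stopifnot(all(c("positives", "group_size") %in% names(skeleton)))
  if (any(skeleton$group_size <= 0)) {
    stop("group sizes must be positive", call. = FALSE)
  }
  dplyr::mutate(skeleton,
    percent = round_half_up(100 * .data$positives / .data$group_size)
  )
}

#' Prevalence table of a detected cohort
#'
#' Builds the group x analyte positives skeleton from per-case detections
#' and group assignments, then applies [prevalence()].
#'
#' @param detections Tibble `case_id`, `analyte`, `status`.
#' @param groups Tibble `case_id`, `group` from [group_cases()].
#' @param analytes Analytes to tabulate (default: all present except the
#'   Delta-8 screen).
#'
#' @return A tibble: `group`, `group_size`, `analyte`, `positives`,
#'   `percent`.
#' @export
cohort_prevalence <- function(detections, groups,
                              analytes = setdiff(
                                unique(detections$analyte), "D8-THC"
                              )) {
  sizes <- dplyr::count(groups, .data$group, name = "group_size")
  detections |>
    dplyr::inner_join(groups, by = "case_id") |>
    dplyr::filter(.data$analyte %in% analytes) |>
    dplyr::group_by(.data$group, .data$analyte) |>
    dplyr::summarise(
      positives = sum(.data$status == "confirmed"),
      .groups = "drop"
    ) |>
    dplyr::left_join(sizes, by = "group") |>
    prevalence()
}

#' Concentration summary (medians and maxima)
#'
#' Per-analyte median and maximum concentration over all cases of a group,
#' zeros (non-detected cases) included -- so an analyte detected in half the
#' cases has a median of 0.
#'
#' @param estimates Tibble with `analyte` and `value` (ng/mL; non-detected
#'   encoded as 0), optionally a `group` column to stratify by.
#'
#' @return A tibble: (`group`,) `analyte`, `n`, `median`, `max`.
#' @export
concentration_summary <- function(estimates) {
  grp <- intersect("group", names(estimates))
  estimates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "analyte")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$value),
      max = max(.data$value),
      .groups = "drop"
    )
}

#' Relative median statistic
#'
#' The median concentration of one analyte as a nearest-integer percent of
#' another's, computed as the ratio of the group medians (not the median of
#' per-case ratios).
#'
#' @param summary A [concentration_summary()] tibble (`analyte`, `median`).
#' @param numerator,denominator Analyte ids.
#'
#' @return Integer percent.
#' @export
#' @examples
#' s <- tibble::tibble(analyte = c("9R-HHC-COOH", "THC-COOH"), median = c(1.4, 21))
#' relative_median(s, "9R-HHC-COOH", "THC-COOH") # 7
relative_median <- function(summary, numerator, denominator) {
  m_num <- summary$median[summary$analyte == numerator]
  m_den <- summary$median[summary$analyte == denominator]
  if (length(m_num) != 1 || length(m_den) != 1) {
    stop("analytes not found in summary", call. = FALSE)
  }
  if (m_den <= 0) stop("denominator median must be positive", call. = FALSE)
  round_half_up(100 * m_num / m_den)
}

#' Default impurity mask for incubation calls
#'
#' The 11-OH-THC reference material carries 11-OH-HHC as an impurity, so
#' 11-OH-HHC cells of the 11-OH-THC substrate cannot be interpreted and are
#' masked.
#'
#' @return A tibble: `substrate`, `analyte`.
#' @export
default_impurity_mask <- function() {
  tibble::tibble(
    substrate = "11-OH-THC",
    analyte = c("9R-11-OH-HHC", "9S-11-OH-HHC")
  )
}

#' Qualitative incubation call matrix
#'
#' Maps per-timepoint detection statuses to the qualitative calls `+`
#' (confirmed), `(+)` (observed peak not fulfilling all criteria) and `-`
#' (no peak). Cells listed in the impurity mask, and the substrate's own
#' rows, are rendered `masked`. A metabolite confirmed in the matching
#' negative control invalidates the call (flagged in `control_positive`).
#'
#' @param detections Tibble with `substrate`, `timepoint`, `with_nadph`,
#'   `analyte`, `status`, covering both the incubation series and the
#'   negative controls.
#' @param impurity_mask Tibble `substrate`, `analyte`; see
#'   [default_impurity_mask()].
#'
#' @return A tibble: `substrate`, `analyte`, `timepoint`, `call`
#'   (`+`, `(+)`, `-`, `masked`), `control_positive`.
#' @export
incubation_calls <- function(detections, impurity_mask = default_impurity_mask()) {
  main <- dplyr::filter(detections, .data$with_nadph)
  ctrl <- detections |>
    dplyr::filter(!.data$with_nadph) |>
    dplyr::select("substrate", "timepoint", "analyte",
      control_status = "status"
    )
  masked <- dplyr::mutate(impurity_mask, masked = TRUE)
  main |>
    dplyr::left_join(ctrl, by = c("substrate", "timepoint", "analyte")) |>
    dplyr::left_join(masked, by = c("substrate", "analyte")) |>
    dplyr::mutate(
      call = dplyr::case_when(
        .data$analyte == .data$substrate ~ "masked",
        !is.na(.data$masked) ~ "masked",
        .data$status == "confirmed" ~ "+",
        .data$status == "partial" ~ "(+)",
        TRUE ~ "-"
      ),
      control_positive = !is.na(.data$control_status) &
        .data$control_status == "confirmed" & .data$call != "masked"
    ) |>
    dplyr::select(
      "substrate", "analyte", "timepoint", "call", "control_positive"
    )
}
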