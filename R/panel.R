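# Analyte panel: monitored MRM transitions, retention times, identification
# tolerances, cutoffs, internal-standard assignments, calibration levels and
# the borrowed-curve map for analytes lacking reference material.

#' Default cannabinoid MRM panel
#'
#' The monitored transition panel for Delta-9-THC, HHC, their 11-hydroxy and
#' 11-nor-9-carboxy metabolites (both 9R/9S epimers of the HHC forms) and the
#' three deuterated internal standards, with the method's identification
#' tolerances and quantification settings:
#'
#' * retention-time tolerance +/- 0.02 min, ion-ratio tolerance +/- 20%;
#' * peak-area cutoffs 1000 (Delta-9-THC, 11-OH-THC, THC-COOH, HHC-COOH) and
#'   2000 (HHC, 11-OH-HHC);
#' * six calibration levels 0.53, 1.325, 5.3, 13.25, 26.5, 53 ng/mL;
#' * LLOQs 0.53 ng/mL (Delta-9-THC, 11-OH-THC), 1.06 ng/mL (THC-COOH), with
#'   HHC-family analytes inheriting the LLOQ of their surrogate;
#' * borrowed-curve map HHC <- Delta-9-THC, 11-OH-HHC <- 11-OH-THC,
#'   HHC-COOH <- THC-COOH.
#'
#' Epimer pairs share their precursor/product channels and are distinguished
#' chromatographically. The optional Delta-8-THC screen shares the Delta-9-THC
#' transitions at a distinct retention time and is used only for the
#' sample-exclusion rule, never quantified.
#'
#' @param swap_quantifier If `TRUE`, swap the quantifier/qualifier assignment
#'   of every analyte (the low-mass product ion is the quantifier by default).
#' @param include_delta8 Include the Delta-8-THC screening channels.
#'
#' @return A list of class `panel_config` with elements `transitions` (tibble:
#'   one row per analyte x role with `analyte`, `role`, `channel`,
#'   `precursor_mz`, `product_mz`, `rt`, `cone_v`, `collision_ev`),
#'   `analytes` (per-analyte tibble with cutoffs, IS assignment, LLOQ,
#'   surrogate), `rt_tol`, `ratio_tol`, `cal_levels`, `run_length`,
#'   `points_per_min` and `search_factor`.
#' @export
#' @examples
#' panel <- default_panel()
#' panel$transitions
default_panel <- function(swap_quantifier = FALSE, include_delta8 = TRUE) {
  tr <- tibble::tribble(
    ~analyte, ~precursor_mz, ~qual_mz, ~quant_mz, ~rt, ~cone_v, ~ce_qual, ~ce_quant,
    "D9-THC", 315.22, 193.12, 123.04, 3.60, 42, 22, 32,
    "9R-HHC", 317.25, 193.12, 123.04, 4.08, 20, 20, 40,
    "9S-HHC", 317.25, 193.12, 123.04, 4.00, 20, 20, 40,
    "9R-11-OH-HHC", 333.24, 193.12, 123.04, 1.86, 20, 25, 35,
    "9S-11-OH-HHC", 333.24, 193.12, 123.04, 1.91, 20, 25, 35,
    "9R-HHC-COOH", 347.22, 193.12, 123.04, 1.80, 20, 25, 35,
    "9S-HHC-COOH", 347.22, 193.12, 123.04, 1.97, 20, 25, 35,
    "11-OH-THC", 331.22, 193.12, 201.20, 1.71, 20, 29, 25,
    "THC-COOH", 345.20, 193.12, 299.20, 1.90, 42, 26, 20
  )
  if (include_delta8) {
    # Screening channel only; shares the THC transitions, retention time is a
    # method placeholder (not part of the published transition table).
    tr <- dplyr::bind_rows(tr, tibble::tibble(
      analyte = "D8-THC", precursor_mz = 315.22, qual_mz = 193.12,
      quant_mz = 123.04, rt = 3.40, cone_v = 42, ce_qual = 22, ce_quant = 32
    ))
  }
  if (swap_quantifier) {
    tr <- dplyr::rename(tr,
      quant_mz = "qual_mz", qual_mz = "quant_mz",
      ce_quant = "ce_qual", ce_qual = "ce_quant"
    )
  }
  long <- tr |>
    tidyr::pivot_longer(
      cols = c("quant_mz", "qual_mz"),
      names_to = "role", values_to = "product_mz"
    ) |>
    dplyr::mutate(
      role = ifelse(.data$role == "quant_mz", "quantifier", "qualifier"),
      collision_ev = ifelse(.data$role == "quantifier",
        .data$ce_quant, .data$ce_qual
      ),
      channel = sprintf("%.2f>%.2f", .data$precursor_mz, .data$product_mz)
    ) |>
    dplyr::select(
      "analyte", "role", "channel", "precursor_mz", "product_mz",
      "rt", "cone_v", "collision_ev"
    )

  is_tr <- tibble::tribble(
    ~analyte, ~role, ~precursor_mz, ~product_mz, ~rt, ~cone_v, ~collision_ev,
    "D9-THC-d3", "IS", 318.22, 196.12, 3.58, 42, 22,
    "11-OH-THC-d3", "IS", 334.27, 196.23, 1.89, 20, 29,
    "THC-COOH-d3", "IS", 348.20, 196.12, 1.70, 34, 20
  ) |>
    dplyr::mutate(channel = sprintf("%.2f>%.2f", .data$precursor_mz, .data$product_mz)) |>
    dplyr::select(
      "analyte", "role", "channel", "precursor_mz", "product_mz",
      "rt", "cone_v", "collision_ev"
    )

  transitions <- dplyr::bind_rows(long, is_tr)

  analytes <- tibble::tribble(
    ~analyte, ~area_cutoff, ~is_id, ~lloq, ~surrogate,
    "D9-THC", 1000, "D9-THC-d3", 0.53, NA_character_,
    "9R-HHC", 2000, "D9-THC-d3", 0.53, "D9-THC",
    "9S-HHC", 2000, "D9-THC-d3", 0.53, "D9-THC",
    "9R-11-OH-HHC", 2000, "11-OH-THC-d3", 0.53, "11-OH-THC",
    "9S-11-OH-HHC", 2000, "11-OH-THC-d3", 0.53, "11-OH-THC",
    "9R-HHC-COOH", 1000, "THC-COOH-d3", 1.06, "THC-COOH",
    "9S-HHC-COOH", 1000, "THC-COOH-d3", 1.06, "THC-COOH",
    "11-OH-THC", 1000, "11-OH-THC-d3", 0.53, NA_character_,
    "THC-COOH", 1000, "THC-COOH-d3", 1.06, NA_character_
  )
  if (include_delta8) {
    analytes <- dplyr::bind_rows(analytes, tibble::tibble(
      analyte = "D8-THC", area_cutoff = 1000, is_id = "D9-THC-d3",
      lloq = NA_real_, surrogate = NA_character_
    ))
  }

  structure(
    list(
      transitions = transitions,
      analytes = analytes,
      rt_tol = 0.02,
      ratio_tol = 0.20,
      cal_levels = c(0.53, 1.325, 5.3, 13.25, 26.5, 53),
      run_length = 6.8,
      points_per_min = 100,
      search_factor = 3,
      # carbons retained by the product ions, for the fragment-retention model
      fragment_carbons = c("193.12" = 14, "123.04" = 8)
    ),
    class = "panel_config"
  )
}

#' @export
print.panel_config <- function(x, ...) {
  cat(
    "<panel_config> ", nrow(x$analytes), " analytes, ",
    nrow(x$transitions), " transitions; rt_tol ", x$rt_tol,
    " min, ratio_tol ", x$ratio_tol, "\n",
    sep = ""
  )
  invisible(x)
}

# Search half-width used for windowed peak picking (wider than the
# identification tolerance so jittered peaks are still found and then judged).
search_half_width <- function(panel) panel$search_factor * panel$rt_tol

# Quantifiable (non-IS, non-screen) analytes of a panel.
panel_quant_analytes <- function(panel) {
  setdiff(panel$analytes$analyte, "D8-THC")
}

# Per-analyte lookup helpers -------------------------------------------------

panel_channel <- function(panel, analyte_id, role) {
  tr <- panel$transitions
  ch <- tr$channel[tr$analyte == analyte_id & tr$role == role]
  if (length(ch) != 1) {
    stop("no unique ", role, " channel for analyte ", analyte_id, call. = FALSE)
  }
  ch
}

panel_rt <- function(panel, analyte_id) {
  rt <- unique(panel$transitions$rt[panel$transitions$analyte == analyte_id])
  if (length(rt) != 1) stop("unknown analyte ", analyte_id, call. = FALSE)
  rt
}

# Epimer partner sharing the same channels at a different retention time
# (includes the D8/D9 THC pair used by the screening rule).
panel_channel_partner <- function(panel, analyte_id) {
  tr <- panel$transitions
  ch <- tr$channel[tr$analyte == analyte_id & tr$role == "quantifier"]
  other <- unique(tr$analyte[tr$channel == ch & tr$analyte != analyte_id &
    tr$role == "quantifier"])
  if (length(other) == 0) NA_character_ else other[[1]]
}

#' Read / write a panel configuration
#'
#' Serializes the full panel (transition table and thresholds) as YAML so a
#' method can be version-controlled as structured text.
#'
#' @param path File path.
#' @param panel A `panel_config`.
#' @return `read_panel()` returns a `panel_config`.
#' @export
write_panel <- function(panel, path) {
  out <- unclass(panel)
  out$transitions <- lapply(
    seq_len(nrow(panel$transitions)),
    function(i) as.list(panel$transitions[i, ])
  )
  out$analytes <- lapply(
    seq_len(nrow(panel$analytes)),
    function(i) {
      row <- as.list(panel$analytes[i, ])
      row[vapply(row, is.na, logical(1))] <- NULL
      row
    }
  )
  out$fragment_carbons <- as.list(out$fragment_carbons)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$transitions <- dplyr::bind_rows(lapply(raw$transitions, tibble::as_tibble))
  raw$analytes <- dplyr::bind_rows(lapply(raw$analytes, tibble::as_tibble))
  for (col in c("lloq", "surrogate")) {
    if (!col %in% names(raw$analytes)) raw$analytes[[col]] <- NA
  }
  raw$fragment_carbons <- unlist(raw$fragment_carbons)
  raw$cal_levels <- as.numeric(raw$cal_levels)
  structure(raw, class = "panel_config")
}
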