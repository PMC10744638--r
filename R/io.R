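# Delimited-text interchange for chromatograms, ground truth and result
# tables. Numeric columns are serialized with 17 significant digits (the
# shortest representation guaranteed to round-trip an IEEE double), so a
# write/read cycle is bit-exact.

fmt_double <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' Read / write chromatograms as long-format delimited text
#'
#' Columns: `injection_id`, `channel`, `time_min`, `intensity`.
#'
#' @param chroms Long chromatogram tibble.
#' @param path File path (CSV).
#' @return `read_chromatograms()` returns the tibble.
#' @export
write_chromatograms <- function(chroms, path) {
  out <- chroms[, c("injection_id", "channel", "time_min", "intensity")]
  out$time_min <- fmt_double(out$time_min)
  out$intensity <- fmt_double(out$intensity)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_chromatograms
#' @export
read_chromatograms <- function(path) {
  # base strtod parsing is correctly rounded, preserving the bit-exact
  # round-trip contract
  tibble::as_tibble(utils::read.csv(path, colClasses = c(
    injection_id = "character", channel = "character",
    time_min = "numeric", intensity = "numeric"
  )))
}

#' Read / write cohort ground truth
#'
#' Long table of true concentrations: `case_id`, `analyte`,
#' `true_conc` (ng/mL).
#'
#' @param truth Ground-truth tibble.
#' @param path File path (CSV).
#' @return `read_ground_truth()` returns the tibble.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- fmt_double(out[[col]])
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  tibble::as_tibble(utils::read.csv(path, colClasses = c(
    case_id = "character", analyte = "character", true_conc = "numeric"
  )))
}
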