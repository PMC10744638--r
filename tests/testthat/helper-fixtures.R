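# Shared fixtures, built once per test run.

fx_panel <- default_panel()

# Noisy standards processed once: calibrations, correction factors and the
# identification reference used by most pipeline tests.
fx_cal_run <- simulate_calibration_runs(fx_panel, seed = 101)
fx_corr_run <- simulate_correction_runs(fx_panel, seed = 102)
fx_ref_run <- simulate_reference_standards(fx_panel, seed = 108)
fx_reference <- reference_from_standards(fx_ref_run$chromatograms, fx_panel)
fx_calibrations <- fit_panel_calibrations(fx_cal_run, fx_panel)
fx_cfs <- panel_correction_factors(fx_corr_run, fx_panel)

# Noiseless standards for exact-arithmetic unit tests.
fx_corr_clean <- simulate_correction_runs(fx_panel,
  seed = 7, day_cv = 0, noise_sd = 0
)
fx_reference_clean <- reference_from_standards(
  fx_corr_clean$chromatograms, fx_panel
)

# Render a single injection from explicit (analyte, conc) truth, noiseless by
# default, with internal standards at nominal level; returns chromatograms.
render_case <- function(conc, panel = fx_panel, noise_sd = 0,
                        baseline_level = 0, recovery = 1,
                        response = default_response_params(),
                        interference_from = NULL, is_area = 5e4,
                        injection_id = "case-x") {
  d <- tibble::tibble(analyte = names(conc), conc = unname(conc)) |>
    dplyr::filter(conc > 0) |>
    dplyr::left_join(response, by = "analyte")
  quant_area <- d$conc * d$slope * recovery
  peaks <- tibble::tibble(
    injection_id = injection_id,
    channel = c(
      vapply(d$analyte, function(a) panel_channel(panel, a, "quantifier"), character(1)),
      vapply(d$analyte, function(a) panel_channel(panel, a, "qualifier"), character(1))
    ),
    rt = rep(vapply(d$analyte, function(a) panel_rt(panel, a), numeric(1)), 2),
    area = c(quant_area, quant_area * d$ion_ratio)
  )
  is_tr <- dplyr::filter(panel$transitions, role == "IS")
  peaks <- dplyr::bind_rows(peaks, tibble::tibble(
    injection_id = injection_id, channel = is_tr$channel, rt = is_tr$rt,
    area = is_area * recovery
  ))
  if (!is.null(interference_from)) {
    # M+2 isotopologue of THC-COOH on the HHC-COOH channels
    parent_area <- interference_from * recovery *
      response$slope[response$analyte == "THC-COOH"]
    hhc_ch <- unique(panel$transitions$channel[
      panel$transitions$analyte == "9R-HHC-COOH"
    ])
    peaks <- dplyr::bind_rows(peaks, purrr::map_dfr(hhc_ch, function(ch) {
      fc <- panel$fragment_carbons[[sub(".*>", "", ch)]]
      tibble::tibble(
        injection_id = injection_id, channel = ch,
        rt = panel_rt(panel, "THC-COOH"),
        area = parent_area *
          interference_area(1, "C21H28O4", shift = 2, fragment_carbons = fc)
      )
    }))
  }
  render_chromatograms(peaks, panel,
    injections = injection_id,
    noise_sd = noise_sd, baseline_level = baseline_level
  )
}

# Brute-force isotopologue oracle: enumerate every combination of per-element
# heavy-isotope counts and sum the multinomial probabilities per total shift.
# Independent of the convolution implementation.
enum_isotopologue <- function(formula, isotopes = default_isotope_table(),
                              max_shift = 4L) {
  if (is.character(formula)) formula <- parse_formula(formula)
  counts <- unclass(formula)
  counts <- counts[counts > 0]
  out <- numeric(max_shift + 1L)
  per_elem <- lapply(names(counts), function(el) {
    p <- isotopes[[el]]
    if (is.null(p)) p <- 1
    n <- counts[[el]]
    shifts <- seq_along(p) - 1L
    # all allocations of n atoms across the isotope classes
    alloc <- function(remaining, slots) {
      if (slots == 1) {
        return(matrix(remaining, 1, 1))
      }
      do.call(rbind, lapply(0:remaining, function(k) {
        cbind(k, alloc(remaining - k, slots - 1))
      }))
    }
    a <- alloc(n, length(p))
    prob <- apply(a, 1, function(row) stats::dmultinom(row, prob = p))
    shift <- as.vector(a %*% shifts)
    data.frame(shift = shift, prob = prob)
  })
  grids <- lapply(per_elem, function(d) seq_len(nrow(d)))
  idx <- expand.grid(grids)
  for (r in seq_len(nrow(idx))) {
    s <- 0
    pr <- 1
    for (j in seq_along(per_elem)) {
      row <- per_elem[[j]][idx[r, j], ]
      s <- s + row$shift
      pr <- pr * row$prob
    }
    if (s <= max_shift) out[s + 1L] <- out[s + 1L] + pr
  }
  out
}
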