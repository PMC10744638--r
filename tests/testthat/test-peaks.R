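gaussian_trace <- function(area, rt, sigma = 0.008, panel = fx_panel,
                           noise_sd = 0, baseline = 0) {
  ch <- panel$transitions$channel[1]
  render_chromatograms(
    tibble::tibble(injection_id = "x", channel = ch, rt = rt, area = area),
    panel,
    injections = "x", noise_sd = noise_sd, baseline_level = baseline,
    peak_sigma = sigma
  ) |>
    dplyr::filter(channel == ch)
}

test_that("a clean Gaussian integrates to its closed-form area", {
  tr <- gaussian_trace(5000, 3.60)
  pk <- find_peak(tr, 3.60, 0.06)
  expect_true(pk$found)
  expect_equal(pk$rt_apex, 3.60, tolerance = 1e-9)
  expect_lt(abs(pk$area - 5000) / 5000, 0.01)
})

test_that("flat and empty windows are not peaks", {
  tr <- gaussian_trace(0, 3.60)
  pk <- find_peak(tr, 3.60, 0.06)
  expect_false(pk$found)
  expect_equal(pk$area, 0)
  expect_error(find_peak(tr, 7.5, 0.06), "outside the time grid")
})

test_that("the larger of two resolved peaks in a window is returned", {
  ch <- fx_panel$transitions$channel[1]
  peaks <- tibble::tibble(
    injection_id = "x", channel = ch,
    rt = c(3.55, 3.65), area = c(2000, 6000)
  )
  tr <- render_chromatograms(peaks, fx_panel,
    injections = "x",
    noise_sd = 0, baseline_level = 0
  ) |> dplyr::filter(channel == ch)
  pk <- find_peak(tr, 3.60, 0.12)
  expect_equal(pk$rt_apex, 3.65, tolerance = 1e-6)
  expect_lt(abs(pk$area - 6000) / 6000, 0.01)
})

test_that("integration is linear for non-overlapping peaks", {
  a <- find_peak(gaussian_trace(3000, 3.50), 3.50, 0.06)$area
  b <- find_peak(gaussian_trace(4000, 3.70), 3.70, 0.06)$area
  ch <- fx_panel$transitions$channel[1]
  both <- render_chromatograms(
    tibble::tibble(
      injection_id = "x", channel = ch,
      rt = c(3.50, 3.70), area = c(3000, 4000)
    ),
    fx_panel,
    injections = "x", noise_sd = 0, baseline_level = 0
  ) |> dplyr::filter(channel == ch)
  a2 <- find_peak(both, 3.50, 0.06)$area
  b2 <- find_peak(both, 3.70, 0.06)$area
  expect_lt(abs((a2 + b2) - (a + b)) / (a + b), 0.001)
})

test_that("area is invariant to grid refinement", {
  coarse <- fx_panel
  fine <- fx_panel
  fine$points_per_min <- 200
  a_coarse <- find_peak(gaussian_trace(5000, 3.60, panel = coarse), 3.60, 0.06)$area
  a_fine <- find_peak(gaussian_trace(5000, 3.60, panel = fine), 3.60, 0.06)$area
  expect_lt(abs(a_fine - a_coarse) / a_coarse, 0.005)
})

test_that("ion ratios divide qualifier by quantifier and signal gaps", {
  q <- tibble::tibble(found = TRUE, area = 1000)
  l <- tibble::tibble(found = TRUE, area = 500)
  expect_equal(ion_ratio(q, l), 0.5)
  expect_true(is.na(ion_ratio(q, tibble::tibble(found = FALSE, area = 0))))
  expect_true(is.na(ion_ratio(tibble::tibble(found = TRUE, area = 0), l)))

  # constructed injection with known true ratio, noiseless
  chroms <- render_case(c("THC-COOH" = 10))
  pk <- process_injection(chroms, fx_panel)
  quant <- pk[pk$analyte == "THC-COOH" & pk$role == "quantifier", ]
  qual <- pk[pk$analyte == "THC-COOH" & pk$role == "qualifier", ]
  r <- default_response_params()
  true_ratio <- r$ion_ratio[r$analyte == "THC-COOH"]
  expect_equal(ion_ratio(quant, qual), true_ratio, tolerance = 1e-6)
})

test_that("epimer windows exclude an interference eluting between them", {
  # only the M+2 interference at 1.90 min on the HHC-COOH channel
  chroms <- render_case(c("THC-COOH" = 100), interference_from = 100)
  ch <- panel_channel(fx_panel, "9R-HHC-COOH", "quantifier")
  tr <- dplyr::filter(chroms, channel == ch)
  res <- epimer_pair_resolve(tr, 1.80, 1.97, search_half_width(fx_panel))
  expect_false(res$found[1])
  expect_false(res$found[2])
  # ... but the interference itself is a real peak at 1.90
  pk <- find_peak(tr, 1.90, 0.03)
  expect_true(pk$found)
  expect_gt(pk$area, 0)
})

test_that("baseline-resolved epimers integrate like single peaks", {
  chroms <- render_case(c("9R-HHC-COOH" = 5, "9S-HHC-COOH" = 3))
  ch <- panel_channel(fx_panel, "9R-HHC-COOH", "quantifier")
  tr <- dplyr::filter(chroms, channel == ch)
  hw <- search_half_width(fx_panel)
  res <- epimer_pair_resolve(tr, 1.80, 1.97, hw)
  single_a <- find_peak(tr, 1.80, hw)$area
  single_b <- find_peak(tr, 1.97, hw)$area
  expect_equal(res$area[1], single_a, tolerance = 1e-6)
  expect_equal(res$area[2], single_b, tolerance = 1e-6)
  expect_false(res$partial[1])
  r <- default_response_params()
  expect_lt(abs(res$area[1] - 5 * r$slope[r$analyte == "9R-HHC-COOH"]) /
    res$area[1], 0.01)
})

test_that("coeluting pairs are flagged as partially resolved", {
  ch <- fx_panel$transitions$channel[1]
  tr <- render_chromatograms(
    tibble::tibble(injection_id = "x", channel = ch, rt = 1.89, area = 5000),
    fx_panel,
    injections = "x", noise_sd = 0, baseline_level = 0
  ) |> dplyr::filter(channel == ch)
  res <- epimer_pair_resolve(tr, 1.88, 1.90, 0.06)
  expect_true(all(res$partial))
  expect_error(epimer_pair_resolve(tr, 1.88, 1.88, 0.06), "must differ")
})
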