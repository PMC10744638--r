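test_that("the same seed reproduces a cohort bit-identically", {
  cfg <- cohort_sim_config(n_cases = 3, seed = 11)
  s1 <- simulate_cohort(cfg, fx_panel)
  s2 <- simulate_cohort(cfg, fx_panel)
  expect_identical(s1$chromatograms, s2$chromatograms)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cohort(cohort_sim_config(n_cases = 3, seed = 12), fx_panel)
  expect_false(identical(s1$chromatograms$intensity, s3$chromatograms$intensity))
})

test_that("an all-negative cohort renders only baseline and IS peaks", {
  cfg <- cohort_sim_config(
    n_cases = 4, group_props = c(A = 0, B = 0, C = 1, D = 0),
    seed = 13, noise_sd = 0, delta8_rate = 0, low_recovery_rate = 0
  )
  sim <- simulate_cohort(cfg, fx_panel)
  is_channels <- fx_panel$transitions$channel[fx_panel$transitions$role == "IS"]
  analyte_traces <- dplyr::filter(
    sim$chromatograms, !(channel %in% is_channels)
  )
  expect_true(all(analyte_traces$intensity == cfg$baseline_level))
  expect_true(all(sim$truth$true_conc == 0))
})

test_that("noiseless rendering recovers injected areas within 1%", {
  cfg <- cohort_sim_config(
    n_cases = 5, seed = 14, noise_sd = 0,
    rt_jitter = 0, delta8_rate = 0, low_recovery_rate = 0
  )
  sim <- simulate_cohort(cfg, fx_panel)
  resp <- default_response_params()
  idx <- split(seq_len(nrow(sim$chromatograms)), sim$chromatograms$injection_id)
  checked <- 0
  for (cid in names(idx)) {
    pk <- process_injection(sim$chromatograms[idx[[cid]], ], fx_panel)
    truth <- sim$truth[sim$truth$case_id == cid & sim$truth$true_conc > 0 &
      sim$truth$analyte != "D8-THC", ]
    if (nrow(truth) == 0) next
    rec <- sim$recoveries[sim$recoveries$case_id == cid, ]
    for (i in seq_len(nrow(truth))) {
      a <- truth$analyte[i]
      is_id <- fx_panel$analytes$is_id[fx_panel$analytes$analyte == a]
      expected <- truth$true_conc[i] * resp$slope[resp$analyte == a] *
        rec$recovery[rec$is_id == is_id]
      got <- pk$area[pk$analyte == a & pk$role == "quantifier"]
      # interference adds to THC-COOH-positive HHC-COOH channels; skip overlap
      expect_lt(abs(got - expected) / expected, 0.011, label = paste(cid, a))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 10)
})

test_that("group proportions follow the configured multinomial", {
  cfg <- cohort_sim_config(n_cases = 400, seed = 15)
  withr::local_seed(cfg$seed)
  groups <- sample(names(cfg$group_props), 400,
    replace = TRUE, prob = cfg$group_props
  )
  sim_groups <- simulate_cohort(cfg, fx_panel)$cases$group
  for (g in c("A", "B", "C")) {
    p <- cfg$group_props[[g]]
    expect_lt(
      abs(mean(sim_groups == g) - p),
      4 * sqrt(p * (1 - p) / 400) + 1e-9
    )
  }
})

test_that("interference scales linearly with THC-COOH concentration", {
  ch <- panel_channel(fx_panel, "9R-HHC-COOH", "quantifier")
  areas <- vapply(c(50, 100, 200), function(conc) {
    tr <- dplyr::filter(
      render_case(c("THC-COOH" = conc), interference_from = conc),
      channel == ch
    )
    find_peak(tr, 1.90, 0.03)$area
  }, numeric(1))
  expect_equal(areas[2] / areas[1], 2, tolerance = 0.01)
  expect_equal(areas[3] / areas[1], 4, tolerance = 0.01)
})

test_that("cohort cases positive for THC-COOH carry the M+2 peak", {
  cp <- default_conc_params()
  cp$prev_A[cp$analyte %in% c("9R-HHC-COOH", "9S-HHC-COOH")] <- 0
  cfg <- cohort_sim_config(
    n_cases = 2, group_props = c(A = 1, B = 0, C = 0, D = 0), seed = 16,
    conc_params = cp, noise_sd = 0, rt_jitter = 0,
    delta8_rate = 0, low_recovery_rate = 0
  )
  sim <- simulate_cohort(cfg, fx_panel)
  pos <- sim$truth$case_id[sim$truth$analyte == "THC-COOH" &
    sim$truth$true_conc > 0]
  ch <- panel_channel(fx_panel, "9R-HHC-COOH", "quantifier")
  for (cid in pos) {
    tr <- dplyr::filter(sim$chromatograms, injection_id == cid, channel == ch)
    expect_true(find_peak(tr, 1.90, 0.03)$found) # between the epimers
    res <- epimer_pair_resolve(tr, 1.80, 1.97, search_half_width(fx_panel))
    expect_false(any(res$found)) # neither epimer window captures it
  }
})

test_that("calibration runs honor levels and respond linearly", {
  run <- simulate_calibration_runs(fx_panel, seed = 17, noise_sd = 0)
  expect_equal(nrow(run$levels), 6)
  expect_equal(sort(unique(run$levels$level)), sort(fx_panel$cal_levels))
  pk <- process_injections(run$chromatograms, fx_panel)
  areas <- pk |>
    dplyr::filter(analyte == "D9-THC", role == "quantifier") |>
    dplyr::inner_join(run$levels, by = "injection_id") |>
    dplyr::arrange(level)
  expect_true(all(diff(areas$area) > 0))

  blank <- simulate_calibration_runs(fx_panel, seed = 18, levels = 0, noise_sd = 0)
  pk0 <- process_injections(blank$chromatograms, fx_panel)
  cutoff <- fx_panel$analytes$area_cutoff[match(pk0$analyte, fx_panel$analytes$analyte)]
  non_is <- pk0$role != "IS"
  expect_true(all(pk0$area[non_is] < cutoff[non_is]))
})

test_that("correction runs produce one injection per day", {
  run <- simulate_correction_runs(fx_panel, n_days = 6, seed = 19)
  expect_equal(nrow(run$days), 6)
  expect_error(simulate_correction_runs(fx_panel, n_days = 1), "n_days")

  clean <- simulate_correction_runs(fx_panel,
    n_days = 3, seed = 20,
    day_cv = 0, noise_sd = 0
  )
  pk <- process_injections(clean$chromatograms, fx_panel) |>
    dplyr::filter(analyte == "THC-COOH", role == "quantifier")
  expect_equal(max(pk$area) - min(pk$area), 0, tolerance = 1e-9)

  other <- simulate_correction_runs(fx_panel, n_days = 3, seed = 21)
  same <- simulate_correction_runs(fx_panel, n_days = 3, seed = 21)
  expect_identical(
    other$chromatograms$intensity, same$chromatograms$intensity
  )
})

test_that("incubation controls and the THC-COOH substrate stay silent", {
  ctrl <- simulate_incubation_series("D9-THC",
    with_nadph = FALSE, seed = 22,
    panel = fx_panel
  )
  metabolite <- dplyr::filter(ctrl$truth, analyte != "D9-THC")
  expect_true(all(metabolite$conc_ngml == 0))

  ctrl_oh <- simulate_incubation_series("11-OH-THC",
    with_nadph = FALSE,
    seed = 23, panel = fx_panel
  )
  imp <- dplyr::filter(
    ctrl_oh$truth,
    analyte %in% c("9R-11-OH-HHC", "9S-11-OH-HHC")
  )
  expect_true(all(imp$conc_ngml > 0)) # impurity present even without NADPH
  expect_equal(length(unique(round(imp$conc_ngml, 9))), 1) # and constant

  tc <- simulate_incubation_series("THC-COOH", seed = 24, panel = fx_panel)
  hhc_cooh <- dplyr::filter(
    tc$truth, analyte %in% c("9R-HHC-COOH", "9S-HHC-COOH")
  )
  expect_true(all(hhc_cooh$conc_ngml == 0))
  expect_error(simulate_incubation_series("HHC", seed = 1), "unknown substrate")
})

test_that("the THC substrate is depleted by 180 minutes", {
  s <- simulate_incubation_series("D9-THC", seed = 25, panel = fx_panel)
  sub <- dplyr::filter(s$truth, analyte == "D9-THC")
  start <- 5 * 314.5 * 0.2 # 5 microM, diluted
  expect_lt(sub$conc_ngml[sub$injection_id == "D9-THC-t180"] / start, 0.002)
  expect_gt(sub$conc_ngml[sub$injection_id == "D9-THC-t020"] / start, 0.3)
})

test_that("chromatograms and ground truth round-trip through text files", {
  sim <- simulate_cohort(cohort_sim_config(n_cases = 2, seed = 26), fx_panel)
  path <- withr::local_tempfile(fileext = ".csv")
  write_chromatograms(sim$chromatograms, path)
  back <- read_chromatograms(path)
  expect_identical(back$intensity, sim$chromatograms$intensity)
  expect_identical(back$time_min, sim$chromatograms$time_min)
  expect_identical(back$injection_id, sim$chromatograms$injection_id)

  tpath <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(sim$truth, tpath)
  expect_identical(read_ground_truth(tpath)$true_conc, sim$truth$true_conc)
})
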