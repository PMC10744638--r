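# Synthetic MRM data generator: Gaussian peak rendering on a uniform time
# grid, whole-blood cohort simulation with recorded ground truth, calibration
# and correction-factor standard runs, and liver-microsome incubation series.

#' Default per-analyte response parameters
#'
#' Instrument response slopes (area counts per ng/mL at unit recovery) and
#' true quantifier/qualifier ion ratios used by the generator. Slopes differ
#' between surrogate pairs so that correction factors do real work. The
#' HHC-COOH ion ratio (0.30) is deliberately close to the effective ratio of
#' the 13C2-THC-COOH interference on the same channels (0.27), reflecting the
#' similar fragmentation of the two isobaric scaffolds: the ion-ratio
#' criterion alone cannot reject the interference, only the retention-time
#' criterion can.
#'
#' @return A tibble with columns `analyte`, `slope`, `ion_ratio`.
#' @export
default_response_params <- function() {
  tibble::tribble(
    ~analyte, ~slope, ~ion_ratio,
    "D9-THC", 2000, 0.55,
    "9R-HHC", 1600, 0.50,
    "9S-HHC", 1550, 0.50,
    "9R-11-OH-HHC", 1800, 0.45,
    "9S-11-OH-HHC", 1700, 0.45,
    "9R-HHC-COOH", 1500, 0.30,
    "9S-HHC-COOH", 1400, 0.30,
    "11-OH-THC", 2200, 0.60,
    "THC-COOH", 2000, 0.50,
    "D8-THC", 2000, 0.50
  )
}

#' Default cohort concentration model
#'
#' Per-analyte detection prevalences by cohort group (A: THC+/HHC-, B:
#' THC+/HHC+, C: negative, D: HHC only) and log-normal concentration
#' parameters. Where a whole-group median (zeros included) is targeted
#' (`median_all`), the log-mean is solved from the prevalence so that the
#' group median of the zero-inflated distribution equals the target; otherwise
#' the median of positive cases (`pos_median`) is specified directly.
#'
#' @return A tibble with columns `analyte`, `prev_A`, `prev_B`, `prev_C`,
#'   `prev_D`, `median_all`, `pos_median`, `sdlog`, `cap`.
#' @export
default_conc_params <- function() {
  tibble::tribble(
    ~analyte, ~prev_A, ~prev_B, ~prev_C, ~prev_D, ~median_all, ~pos_median, ~sdlog, ~cap,
    "D9-THC", 1.00, 1.00, 0, 0, 2.8, NA, 1.0, NA,
    "9R-HHC", 0.00, 1.00, 0, 1.0, NA, 2.0, 1.0, NA,
    "9S-HHC", 0.00, 1.00, 0, 1.0, NA, 1.0, 1.0, NA,
    "9R-11-OH-HHC", 0.15, 0.10, 0, 0.1, NA, 1.5, 0.8, NA,
    "9S-11-OH-HHC", 0.00, 0.10, 0, 0.1, NA, 0.8, 0.8, NA,
    "9R-HHC-COOH", 0.84, 1.00, 0.026, 1.0, 1.4, NA, 1.0, NA,
    "9S-HHC-COOH", 0.50, 0.30, 0, 0.5, NA, 0.9, 0.9, NA,
    "11-OH-THC", 0.80, 0.70, 0, 0, 1.1, NA, 1.0, NA,
    "THC-COOH", 0.92, 1.00, 0.013, 0, 21, NA, 1.0, NA
  )
}

# Solve the log-normal meanlog so that the zero-inflated group median equals
# the target: P(positive) * P(LN > m) = 0.5.
resolve_meanlog <- function(prev, median_all, pos_median, sdlog) {
  if (!is.na(median_all) && prev > 0.5) {
    log(median_all) - sdlog * stats::qnorm(1 - 0.5 / prev)
  } else if (!is.na(pos_median)) {
    log(pos_median)
  } else if (!is.na(median_all)) {
    log(median_all)
  } else {
    NA_real_
  }
}

#' Cohort simulation configuration
#'
#' Study-condition defaults: 308 cases split 222/10/76 across groups A/B/C
#' (group D, HHC only, was not observed and defaults to 0), additive Gaussian
#' detector noise with standard deviation 50 counts on a baseline of 100
#' counts (signal-to-noise about 10 for a peak at the 1000-count area cutoff),
#' Gaussian peaks of sigma 0.008 min sampled at 100 points/min, retention-time
#' jitter uniform within +/- half the identification tolerance, and
#' internal-standard recovery uniform on 0.6-1.1 with a small fraction of
#' low-recovery (< 0.5) cases to exercise the exclusion rule.
#'
#' @param n_cases Number of cases.
#' @param group_props Named proportions for groups A, B, C, D; must sum to 1.
#' @param seed Integer seed; the seed fully determines the output.
#' @param conc_params Concentration model, see [default_conc_params()].
#' @param response Response model, see [default_response_params()].
#' @param noise_sd Detector noise standard deviation (counts); 0 for noiseless.
#' @param baseline_level Constant baseline offset (counts).
#' @param peak_sigma Gaussian peak width sigma (min).
#' @param rt_jitter Maximum absolute retention-time jitter (min), uniform.
#' @param is_area Nominal internal-standard peak area at unit recovery.
#' @param low_recovery_rate Fraction of cases with one IS recovery below 0.5.
#' @param delta8_rate Fraction of cases carrying Delta-8-THC contamination.
#' @param interference Render the 13C2-THC-COOH M+2 interference on the
#'   HHC-COOH channels.
#'
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_cases = 308,
                              group_props = c(A = 222, B = 10, C = 76, D = 0) / 308,
                              seed = 1L,
                              conc_params = default_conc_params(),
                              response = default_response_params(),
                              noise_sd = 50,
                              baseline_level = 100,
                              peak_sigma = 0.008,
                              rt_jitter = 0.01,
                              is_area = 5e4,
                              low_recovery_rate = 0.02,
                              delta8_rate = 0.01,
                              interference = TRUE) {
  if (abs(sum(group_props) - 1) > 1e-8) {
    stop("group proportions must sum to 1", call. = FALSE)
  }
  if (is.null(names(group_props)) || !setequal(names(group_props), c("A", "B", "C", "D"))) {
    stop("group_props must be named A, B, C, D", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  structure(
    list(
      n_cases = n_cases, group_props = group_props[c("A", "B", "C", "D")],
      seed = as.integer(seed), conc_params = conc_params, response = response,
      noise_sd = noise_sd, baseline_level = baseline_level,
      peak_sigma = peak_sigma, rt_jitter = rt_jitter, is_area = is_area,
      low_recovery_rate = low_recovery_rate, delta8_rate = delta8_rate,
      interference = interference
    ),
    class = "cohort_sim_config"
  )
}

# Shared time grid for one run.
time_grid <- function(panel) {
  seq(0, panel$run_length, by = 1 / panel$points_per_min)
}

#' Render chromatograms from a peak specification
#'
#' Renders one intensity-vs-time trace per injection and monitored channel:
#' constant baseline, additive Gaussian noise clipped at zero, and Gaussian
#' peaks at the specified retention times whose trapezoidal, grid-rescaled
#' integral equals the specified area.
#'
#' @param peaks Tibble with columns `injection_id`, `channel`, `rt`, `area`.
#' @param panel A `panel_config` (defines the grid and the channel set).
#' @param injections Character vector of injection ids to render (defaults to
#'   those present in `peaks`).
#' @param noise_sd,baseline_level Noise model (counts).
#' @param peak_sigma Gaussian sigma (min).
#'
#' @return A long tibble: `injection_id`, `channel`, `time_min`, `intensity`.
#' @export
render_chromatograms <- function(peaks, panel,
                                 injections = unique(peaks$injection_id),
                                 noise_sd = 50, baseline_level = 100,
                                 peak_sigma = 0.008) {
  tgrid <- time_grid(panel)
  npts <- length(tgrid)
  channels <- unique(panel$transitions$channel)
  inj <- unique(injections)
  ntr <- length(inj) * length(channels)

  base <- if (noise_sd > 0) {
    matrix(stats::rnorm(npts * ntr, baseline_level, noise_sd), npts, ntr)
  } else {
    matrix(baseline_level, npts, ntr)
  }

  # trace column index: channels vary fastest within injection
  col_of <- function(inj_id, ch) {
    (match(inj_id, inj) - 1L) * length(channels) + match(ch, channels)
  }
  dt <- 1 / panel$points_per_min
  if (nrow(peaks) > 0) {
    cols <- col_of(peaks$injection_id, peaks$channel)
    for (k in seq_len(nrow(peaks))) {
      area <- peaks$area[k]
      if (is.na(area) || area <= 0) next
      rt <- peaks$rt[k]
      lo <- max(1L, ceiling((rt - 6 * peak_sigma) / dt) + 1L)
      hi <- min(npts, floor((rt + 6 * peak_sigma) / dt) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      height <- area * dt / (peak_sigma * sqrt(2 * pi))
      base[idx, cols[k]] <- base[idx, cols[k]] +
        height * exp(-0.5 * ((tgrid[idx] - rt) / peak_sigma)^2)
    }
  }
  base[base < 0] <- 0

  tibble::tibble(
    injection_id = rep(inj, each = npts * length(channels)),
    channel = rep(rep(channels, each = npts), times = length(inj)),
    time_min = rep(tgrid, times = ntr),
    intensity = as.vector(base)
  )
}

# Internal-standard peak rows for one injection.
is_peak_rows <- function(panel, injection_id, is_area, recovery = NULL) {
  is_tr <- dplyr::filter(panel$transitions, .data$role == "IS")
  rec <- if (is.null(recovery)) {
    rep(1, nrow(is_tr))
  } else {
    unname(recovery[is_tr$analyte])
  }
  tibble::tibble(
    injection_id = injection_id, channel = is_tr$channel,
    rt = is_tr$rt, area = is_area * rec
  )
}

#' Simulate a whole-blood cohort
#'
#' Draws case groups, per-analyte true concentrations, internal-standard
#' recoveries and Delta-8-THC contamination flags, then renders the full MRM
#' chromatogram set. Cases positive for THC-COOH additionally receive the
#' M+2 isotopologue interference peak on both HHC-COOH channels at the
#' THC-COOH retention time, with area from [interference_area()].
#'
#' @param config A [cohort_sim_config()].
#' @param panel A [default_panel()] (or compatible `panel_config`).
#'
#' @return A list of class `cohort_sim`: `cases` (case id, group, delta8
#'   flag), `truth` (long tibble of true concentrations, ng/mL),
#'   `recoveries` (case x IS recovery fractions), `chromatograms` (long
#'   trace tibble) and the `config`/`panel` used.
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_sim_config(n_cases = 4, seed = 7), default_panel())
#' dplyr::count(sim$chromatograms, injection_id)
simulate_cohort <- function(config, panel = default_panel()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  withr::local_seed(config$seed)

  n <- config$n_cases
  case_ids <- sprintf("case-%04d", seq_len(n))
  groups <- sample(names(config$group_props), n,
    replace = TRUE,
    prob = config$group_props
  )

  cp <- config$conc_params
  cp$meanlog <- mapply(
    resolve_meanlog, cp$prev_A, cp$median_all, cp$pos_median, cp$sdlog
  )

  # true concentrations: zero-inflated log-normal per analyte and group
  truth <- tidyr::expand_grid(case_id = case_ids, analyte = cp$analyte) |>
    dplyr::left_join(
      tibble::tibble(case_id = case_ids, group = groups),
      by = "case_id"
    ) |>
    dplyr::left_join(cp, by = "analyte")
  prev_col <- paste0("prev_", truth$group)
  prev <- vapply(seq_len(nrow(truth)), function(i) truth[[prev_col[i]]][i], numeric(1))
  present <- stats::runif(nrow(truth)) < prev
  conc <- ifelse(present,
    stats::rlnorm(nrow(truth), truth$meanlog, truth$sdlog), 0
  )
  conc <- ifelse(!is.na(truth$cap), pmin(conc, truth$cap), conc)
  truth <- tibble::tibble(
    case_id = truth$case_id, analyte = truth$analyte, true_conc = conc
  )

  # Delta-8 contamination
  delta8 <- stats::runif(n) < config$delta8_rate
  d8_conc <- ifelse(delta8, stats::rlnorm(n, log(2), 0.8), 0)
  truth <- dplyr::bind_rows(truth, tibble::tibble(
    case_id = case_ids, analyte = "D8-THC", true_conc = d8_conc
  ))

  # internal-standard recoveries
  is_ids <- panel$transitions$analyte[panel$transitions$role == "IS"]
  rec <- matrix(stats::runif(n * length(is_ids), 0.6, 1.1), n, length(is_ids),
    dimnames = list(case_ids, is_ids)
  )
  low <- stats::runif(n) < config$low_recovery_rate
  if (any(low)) {
    which_is <- sample(length(is_ids), sum(low), replace = TRUE)
    rec[cbind(which(low), which_is)] <- stats::runif(sum(low), 0.2, 0.49)
  }
  recoveries <- tibble::as_tibble(rec) |>
    dplyr::mutate(case_id = case_ids, .before = 1) |>
    tidyr::pivot_longer(-"case_id", names_to = "is_id", values_to = "recovery")

  # peak specification
  resp <- config$response
  quant_analytes <- intersect(panel$analytes$analyte, unique(truth$analyte))
  spec <- truth |>
    dplyr::filter(.data$analyte %in% quant_analytes, .data$true_conc > 0) |>
    dplyr::left_join(resp, by = "analyte") |>
    dplyr::left_join(panel$analytes[, c("analyte", "is_id")], by = "analyte") |>
    dplyr::left_join(recoveries, by = c("case_id", "is_id"))
  jitter <- stats::runif(nrow(spec), -config$rt_jitter, config$rt_jitter)
  rts <- vapply(spec$analyte, function(a) panel_rt(panel, a), numeric(1))
  quant_ch <- vapply(spec$analyte, function(a) panel_channel(panel, a, "quantifier"), character(1))
  qual_ch <- vapply(spec$analyte, function(a) panel_channel(panel, a, "qualifier"), character(1))
  quant_area <- spec$true_conc * spec$slope * spec$recovery
  analyte_peaks <- tibble::tibble(
    injection_id = rep(spec$case_id, 2),
    channel = c(quant_ch, qual_ch),
    rt = rep(rts + jitter, 2),
    area = c(quant_area, quant_area * spec$ion_ratio)
  )

  # IS peaks
  is_peaks <- purrr::map_dfr(seq_len(n), function(i) {
    is_peak_rows(panel, case_ids[i], config$is_area, recovery = rec[i, ])
  })

  # 13C2-THC-COOH interference on the HHC-COOH channels
  interference_peaks <- NULL
  if (isTRUE(config$interference)) {
    tc <- spec[spec$analyte == "THC-COOH", ]
    tc_jit <- jitter[spec$analyte == "THC-COOH"]
    if (nrow(tc) > 0) {
      parent_area <- tc$true_conc * tc$slope * tc$recovery
      hhc_cooh_ch <- unique(panel$transitions$channel[
        panel$transitions$analyte == "9R-HHC-COOH"
      ])
      interference_peaks <- purrr::map_dfr(hhc_cooh_ch, function(ch) {
        prod_key <- sub(".*>", "", ch)
        fc <- panel$fragment_carbons[[prod_key]]
        coef <- interference_area(1, "C21H28O4",
          shift = 2, fragment_carbons = fc
        )
        tibble::tibble(
          injection_id = tc$case_id, channel = ch,
          rt = panel_rt(panel, "THC-COOH") + tc_jit,
          area = parent_area * coef
        )
      })
    }
  }

  peaks <- dplyr::bind_rows(analyte_peaks, is_peaks, interference_peaks)
  chroms <- render_chromatograms(
    peaks, panel,
    injections = case_ids,
    noise_sd = config$noise_sd, baseline_level = config$baseline_level,
    peak_sigma = config$peak_sigma
  )

  structure(
    list(
      cases = tibble::tibble(case_id = case_ids, group = groups, delta8 = delta8),
      truth = truth,
      recoveries = recoveries,
      chromatograms = chroms,
      config = config,
      panel = panel
    ),
    class = "cohort_sim"
  )
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(
    "<cohort_sim> ", nrow(x$cases), " cases (",
    paste(names(table(x$cases$group)), table(x$cases$group),
      sep = ":", collapse = " "
    ), "), ",
    dplyr::n_distinct(x$chromatograms$channel), " channels\n",
    sep = ""
  )
  invisible(x)
}

#' Simulate calibration runs
#'
#' One injection per calibration level for the analytes with available
#' reference standards (Delta-9-THC, 11-OH-THC, THC-COOH), internal standards
#' at nominal level and unit recovery.
#'
#' @param panel A `panel_config`.
#' @param seed Integer seed.
#' @param levels Calibration concentrations (ng/mL); default the panel's six
#'   levels. A level of 0 renders a blank injection.
#' @param response Response model.
#' @param noise_sd,baseline_level,peak_sigma,is_area As in
#'   [cohort_sim_config()].
#'
#' @return A list: `chromatograms`, `levels` (tibble `injection_id`, `level`).
#' @export
simulate_calibration_runs <- function(panel, seed = 1L,
                                      levels = panel$cal_levels,
                                      response = default_response_params(),
                                      noise_sd = 50, baseline_level = 100,
                                      peak_sigma = 0.008, is_area = 5e4) {
  withr::local_seed(seed)
  direct <- panel$analytes$analyte[is.na(panel$analytes$surrogate) &
    panel$analytes$analyte != "D8-THC"]
  inj_ids <- sprintf("CAL-%d", seq_along(levels))
  peaks <- purrr::map_dfr(seq_along(levels), function(i) {
    lvl <- levels[i]
    rows <- is_peak_rows(panel, inj_ids[i], is_area)
    if (lvl > 0) {
      arows <- purrr::map_dfr(direct, function(a) {
        r <- response[response$analyte == a, ]
        qa <- lvl * r$slope
        tibble::tibble(
          injection_id = inj_ids[i],
          channel = c(
            panel_channel(panel, a, "quantifier"),
            panel_channel(panel, a, "qualifier")
          ),
          rt = panel_rt(panel, a),
          area = c(qa, qa * r$ion_ratio)
        )
      })
      rows <- dplyr::bind_rows(rows, arows)
    }
    rows
  })
  chroms <- render_chromatograms(peaks, panel,
    injections = inj_ids,
    noise_sd = noise_sd, baseline_level = baseline_level,
    peak_sigma = peak_sigma
  )
  list(
    chromatograms = chroms,
    levels = tibble::tibble(injection_id = inj_ids, level = levels)
  )
}

#' Simulate correction-factor standard runs
#'
#' The all-analyte standard mixture (default 2.5 ng/mL) injected on `n_days`
#' different days with day-level multiplicative response variation, used to
#' derive response factors, correction factors and the reference retention
#' times / ion ratios for identification.
#'
#' @param panel A `panel_config`.
#' @param n_days Number of replicate days (default 6, minimum 2).
#' @param seed Integer seed.
#' @param conc Mixture concentration (ng/mL).
#' @param day_cv Day-level coefficient of variation of the response (0 for
#'   identical days).
#' @param response Response model.
#' @param noise_sd,baseline_level,peak_sigma,is_area As in
#'   [cohort_sim_config()].
#'
#' @return A list: `chromatograms`, `days` (tibble `injection_id`, `day`).
#' @export
simulate_correction_runs <- function(panel, n_days = 6, seed = 1L, conc = 2.5,
                                     day_cv = 0.05,
                                     response = default_response_params(),
                                     noise_sd = 50, baseline_level = 100,
                                     peak_sigma = 0.008, is_area = 5e4) {
  stopifnot(n_days >= 2)
  withr::local_seed(seed)
  # the standard mixture carries every panel analyte, including the
  # Delta-8-THC screen, so processed standards provide references for all
  analytes <- panel$analytes$analyte
  inj_ids <- sprintf("RF-day-%d", seq_len(n_days))
  day_effect <- matrix(
    exp(stats::rnorm(n_days * length(analytes), 0, day_cv)),
    n_days, length(analytes),
    dimnames = list(NULL, analytes)
  )
  peaks <- purrr::map_dfr(seq_len(n_days), function(d) {
    arows <- purrr::map_dfr(analytes, function(a) {
      r <- response[response$analyte == a, ]
      qa <- conc * r$slope * day_effect[d, a]
      tibble::tibble(
        injection_id = inj_ids[d],
        channel = c(
          panel_channel(panel, a, "quantifier"),
          panel_channel(panel, a, "qualifier")
        ),
        rt = panel_rt(panel, a),
        area = c(qa, qa * r$ion_ratio)
      )
    })
    dplyr::bind_rows(arows, is_peak_rows(panel, inj_ids[d], is_area))
  })
  chroms <- render_chromatograms(peaks, panel,
    injections = inj_ids,
    noise_sd = noise_sd, baseline_level = baseline_level,
    peak_sigma = peak_sigma
  )
  list(
    chromatograms = chroms,
    days = tibble::tibble(injection_id = inj_ids, day = seq_len(n_days))
  )
}

#' Simulate reference-standard injections for identification
#'
#' Replicate injections of an all-analyte standard solution at a
#' mid-calibration concentration (default 25 ng/mL, three replicates), used
#' to derive the reference retention times and quantifier/qualifier ion
#' ratios that the identification criteria compare against. A higher
#' concentration than the 2.5 ng/mL correction-factor mixture keeps the
#' qualifier areas far above the noise, so the reference ratio is estimated
#' to about one percent.
#'
#' @param panel A `panel_config`.
#' @param n_injections Number of replicate injections.
#' @param conc Standard concentration (ng/mL).
#' @param seed Integer seed.
#' @param response Response model.
#' @param noise_sd,baseline_level,peak_sigma,is_area As in
#'   [cohort_sim_config()].
#'
#' @return A list: `chromatograms`, `injections`.
#' @export
simulate_reference_standards <- function(panel, n_injections = 3, conc = 25,
                                         seed = 1L,
                                         response = default_response_params(),
                                         noise_sd = 50, baseline_level = 100,
                                         peak_sigma = 0.008, is_area = 5e4) {
  withr::local_seed(seed)
  analytes <- panel$analytes$analyte
  inj_ids <- sprintf("REF-%d", seq_len(n_injections))
  peaks <- purrr::map_dfr(inj_ids, function(id) {
    arows <- purrr::map_dfr(analytes, function(a) {
      r <- response[response$analyte == a, ]
      qa <- conc * r$slope
      tibble::tibble(
        injection_id = id,
        channel = c(
          panel_channel(panel, a, "quantifier"),
          panel_channel(panel, a, "qualifier")
        ),
        rt = panel_rt(panel, a),
        area = c(qa, qa * r$ion_ratio)
      )
    })
    dplyr::bind_rows(arows, is_peak_rows(panel, id, is_area))
  })
  chroms <- render_chromatograms(peaks, panel,
    injections = inj_ids,
    noise_sd = noise_sd, baseline_level = baseline_level,
    peak_sigma = peak_sigma
  )
  list(
    chromatograms = chroms,
    injections = tibble::tibble(injection_id = inj_ids, conc = conc)
  )
}

#' Default microsome incubation kinetics
#'
#' Hand-set first-order rate constants (1/min) for the oxidative cascade with
#' double-bond reduction at the 11-oxo stage:
#' THC -> 11-OH-THC -> 11-oxo-THC, the oxo intermediate branching to THC-COOH
#' or (via reduction) to 11-oxo-HHC, which branches to HHC-COOH or 11-OH-HHC.
#' The 9R fraction of the reduction depends on the substrate material
#' (enantiopure THC-derived vs racemic 11-OH-THC reference material).
#'
#' @return A list of rate constants and branch fractions.
#' @export
default_incubation_kinetics <- function() {
  list(
    k_ox1 = 0.04, # THC -> 11-OH-THC
    k_a = 1.45e-3, # 11-OH-THC -> 11-oxo-THC
    k_b = 0.01, # 11-oxo-THC consumption
    b_cooh = 0.11, # oxo branch: oxidation to THC-COOH
    b_red = 0.89, # oxo branch: reduction to 11-oxo-HHC
    k_c = 0.05, # 11-oxo-HHC consumption
    c_cooh = 0.965, # oxo-HHC branch: oxidation to HHC-COOH
    c_oh = 0.035, # oxo-HHC branch: reduction to 11-OH-HHC (terminal)
    # 9R fraction of the reduction: near-complete for the enantiopure
    # THC-derived material, unselective for the racemic 11-OH-THC substrate
    f9r = c("D9-THC" = 0.995, "11-OH-THC" = 0.50, "THC-COOH" = 0.995)
  )
}

# Molecular weights (g/mol) for microM -> ng/mL conversion.
.analyte_mw <- c(
  "D9-THC" = 314.5, "11-OH-THC" = 330.5, "THC-COOH" = 344.4,
  "9R-11-OH-HHC" = 332.5, "9S-11-OH-HHC" = 332.5,
  "9R-HHC-COOH" = 346.5, "9S-HHC-COOH" = 346.5,
  "9R-HHC" = 316.5, "9S-HHC" = 316.5
)

# Solve the incubation ODE system; concentrations in microM.
incubation_concentrations <- function(substrate, timepoints, with_nadph,
                                      impurity_fraction, kinetics, s0 = 5) {
  f9r <- kinetics$f9r[[substrate]]
  k <- if (with_nadph) kinetics else
    utils::modifyList(kinetics, list(k_ox1 = 0, k_a = 0, k_b = 0, k_c = 0))
  species <- c(
    "thc", "oh_thc", "oxo_thc", "thc_cooh",
    "oxo_hhc_9r", "oxo_hhc_9s", "oh_hhc_9r", "oh_hhc_9s",
    "hhc_cooh_9r", "hhc_cooh_9s"
  )
  y0 <- stats::setNames(numeric(length(species)), species)
  if (substrate == "D9-THC") y0["thc"] <- s0
  if (substrate == "11-OH-THC") {
    y0["oh_thc"] <- s0
    y0["oh_hhc_9r"] <- s0 * impurity_fraction / 2
    y0["oh_hhc_9s"] <- s0 * impurity_fraction / 2
  }
  if (substrate == "THC-COOH") y0["thc_cooh"] <- s0

  deriv <- function(t, y, p) {
    with(as.list(c(y, p)), {
      d_thc <- -k_ox1 * thc
      d_oh_thc <- k_ox1 * thc - k_a * oh_thc
      d_oxo_thc <- k_a * oh_thc - k_b * oxo_thc
      d_thc_cooh <- k_b * b_cooh * oxo_thc
      d_oxo_9r <- k_b * b_red * f9r_val * oxo_thc - k_c * oxo_hhc_9r
      d_oxo_9s <- k_b * b_red * (1 - f9r_val) * oxo_thc - k_c * oxo_hhc_9s
      d_oh_9r <- k_c * c_oh * oxo_hhc_9r
      d_oh_9s <- k_c * c_oh * oxo_hhc_9s
      d_cooh_9r <- k_c * c_cooh * oxo_hhc_9r
      d_cooh_9s <- k_c * c_cooh * oxo_hhc_9s
      list(c(
        d_thc, d_oh_thc, d_oxo_thc, d_thc_cooh, d_oxo_9r, d_oxo_9s,
        d_oh_9r, d_oh_9s, d_cooh_9r, d_cooh_9s
      ))
    })
  }
  pars <- c(
    k[c("k_ox1", "k_a", "k_b", "b_cooh", "b_red", "k_c", "c_cooh", "c_oh")],
    f9r_val = f9r
  )
  times <- sort(unique(c(0, timepoints)))
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = pars)
  sol <- as.data.frame(sol)
  sol[match(timepoints, sol$time), , drop = FALSE]
}

#' Simulate a liver-microsome incubation series
#'
#' Generates chromatograms for aliquots of a pooled human liver microsome
#' incubation of one substrate (default 5 microM) at the given timepoints,
#' using the first-order cascade in [default_incubation_kinetics()]. Aliquots
#' are diluted 1:5 before injection. Without an NADPH regenerating system no
#' reaction occurs (negative control). 11-OH-THC substrate material carries a
#' constant 11-OH-HHC impurity (both epimers) in every injection, including
#' the controls.
#'
#' @param substrate One of `"D9-THC"`, `"11-OH-THC"`, `"THC-COOH"`.
#' @param timepoints Sampling times in minutes (default 20, 120, 180).
#' @param with_nadph `FALSE` renders the negative-control series.
#' @param impurity_fraction Mole fraction of 11-OH-HHC in the 11-OH-THC
#'   substrate material (ignored for other substrates).
#' @param seed Integer seed.
#' @param panel A `panel_config`.
#' @param kinetics Rate constants, see [default_incubation_kinetics()].
#' @param substrate_umol Substrate concentration in microM.
#' @param dilution Aliquot dilution factor before injection.
#' @param response Response model.
#' @param noise_sd,baseline_level,peak_sigma,is_area As in
#'   [cohort_sim_config()].
#'
#' @return A list: `chromatograms`, `injections` (tibble `injection_id`,
#'   `substrate`, `timepoint`, `with_nadph`), `truth` (injected
#'   concentrations, ng/mL).
#' @export
simulate_incubation_series <- function(substrate,
                                       timepoints = c(20, 120, 180),
                                       with_nadph = TRUE,
                                       impurity_fraction = 0.005,
                                       seed = 1L,
                                       panel = default_panel(),
                                       kinetics = default_incubation_kinetics(),
                                       substrate_umol = 5,
                                       dilution = 0.2,
                                       response = default_response_params(),
                                       noise_sd = 50, baseline_level = 100,
                                       peak_sigma = 0.008, is_area = 5e4) {
  if (!substrate %in% c("D9-THC", "11-OH-THC", "THC-COOH")) {
    stop("unknown substrate: ", substrate, call. = FALSE)
  }
  withr::local_seed(seed)
  conc_um <- incubation_concentrations(
    substrate, timepoints, with_nadph,
    if (substrate == "11-OH-THC") impurity_fraction else 0,
    kinetics, s0 = substrate_umol
  )
  species_map <- c(
    thc = "D9-THC", oh_thc = "11-OH-THC", thc_cooh = "THC-COOH",
    oh_hhc_9r = "9R-11-OH-HHC", oh_hhc_9s = "9S-11-OH-HHC",
    hhc_cooh_9r = "9R-HHC-COOH", hhc_cooh_9s = "9S-HHC-COOH"
  )
  tag <- if (with_nadph) "" else "-ctrl"
  inj_ids <- sprintf("%s-t%03d%s", substrate, timepoints, tag)

  truth <- purrr::map_dfr(seq_along(timepoints), function(i) {
    um <- unlist(conc_um[i, names(species_map)])
    tibble::tibble(
      injection_id = inj_ids[i],
      analyte = unname(species_map),
      conc_ngml = unname(um) * .analyte_mw[species_map] * dilution
    )
  })

  peaks <- truth |>
    dplyr::filter(.data$conc_ngml > 1e-9) |>
    dplyr::left_join(response, by = "analyte")
  quant_area <- peaks$conc_ngml * peaks$slope
  rts <- vapply(peaks$analyte, function(a) panel_rt(panel, a), numeric(1))
  analyte_peaks <- tibble::tibble(
    injection_id = rep(peaks$injection_id, 2),
    channel = c(
      vapply(peaks$analyte, function(a) panel_channel(panel, a, "quantifier"), character(1)),
      vapply(peaks$analyte, function(a) panel_channel(panel, a, "qualifier"), character(1))
    ),
    rt = rep(rts, 2),
    area = c(quant_area, quant_area * peaks$ion_ratio)
  )
  is_peaks <- purrr::map_dfr(inj_ids, is_peak_rows,
    panel = panel, is_area = is_area
  )
  chroms <- render_chromatograms(
    dplyr::bind_rows(analyte_peaks, is_peaks), panel,
    injections = inj_ids, noise_sd = noise_sd,
    baseline_level = baseline_level, peak_sigma = peak_sigma
  )
  list(
    chromatograms = chroms,
    injections = tibble::tibble(
      injection_id = inj_ids, substrate = substrate,
      timepoint = timepoints, with_nadph = with_nadph
    ),
    truth = truth
  )
}
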