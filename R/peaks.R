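# Windowed chromatographic peak picking and baseline-subtracted trapezoidal
# integration, with valley-splitting for partially resolved epimer pairs.

# Robust baseline/noise estimate from the samples outside the given windows.
# windows: list of c(lo, hi) in minutes.
baseline_stats <- function(time, intensity, windows) {
  outside <- rep(TRUE, length(time))
  for (w in windows) outside[time >= w[1] & time <= w[2]] <- FALSE
  ref <- intensity[outside]
  if (length(ref) < 10) ref <- intensity
  list(
    baseline = stats::median(ref),
    noise = stats::mad(ref)
  )
}

# Indices in [win] that are local maxima of the trace (ties included).
local_max_candidates <- function(intensity, win) {
  n <- length(intensity)
  cand <- win[win > 1L & win < n]
  cand[intensity[cand] >= intensity[cand - 1L] &
    intensity[cand] >= intensity[cand + 1L]]
}

# Core picker on an index window [lo_i, hi_i]; returns a one-row tibble.
pick_peak <- function(time, intensity, lo_i, hi_i, baseline, noise, dt) {
  win <- lo_i:hi_i
  empty <- tibble::tibble(
    found = FALSE, rt_apex = NA_real_, area = 0, snr = NA_real_,
    baseline = baseline, noise = noise
  )
  if (length(win) < 3) {
    return(empty)
  }
  # candidate apexes are local maxima: a trace merely decaying through the
  # window (e.g. the tail of a peak centered outside it) has none
  cand <- local_max_candidates(intensity, win)
  if (length(cand) == 0) {
    return(empty)
  }
  apex <- cand[which.max(intensity[cand])]
  height <- intensity[apex] - baseline
  threshold <- if (noise > 0) 3 * noise else 0
  if (!(height > threshold)) {
    return(empty)
  }
  # a single sample above threshold is not a peak: both neighbours must also
  # rise above baseline (by one noise SD), which rejects isolated noise spikes
  nb <- c(apex - 1L, apex + 1L)
  if (!all(intensity[nb] - baseline > (if (noise > 0) noise else 0))) {
    return(empty)
  }
  # contiguous region above baseline around the apex (within the window),
  # trimmed back to the valley minima so that a neighbouring peak merging
  # into this one contributes only up to the valley
  left <- apex
  while (left > win[1] && intensity[left - 1L] > baseline) left <- left - 1L
  right <- apex
  while (right < win[length(win)] && intensity[right + 1L] > baseline) {
    right <- right + 1L
  }
  if (left < apex) {
    seg <- left:apex
    left <- seg[which.min(intensity[seg])]
  }
  if (right > apex) {
    seg <- apex:right
    right <- seg[which.min(intensity[seg])]
  }
  region <- left:right
  y <- pmax(intensity[region] - baseline, 0)
  area <- if (length(region) >= 2) {
    sum((y[-1] + y[-length(y)]) / 2 * diff(time[region])) / dt
  } else {
    0
  }
  tibble::tibble(
    found = TRUE, rt_apex = time[apex], area = area,
    snr = if (noise > 0) height / noise else Inf,
    baseline = baseline, noise = noise
  )
}

#' Find and integrate a peak in a retention-time window
#'
#' Locates the largest maximum within `expected_rt +/- search_half_width`,
#' and integrates the baseline-subtracted trace trapezoidally over the
#' contiguous region above baseline around the apex. The baseline is the
#' median -- and the noise the MAD -- of the samples outside the search
#' window. The integral is rescaled by the sampling step, so areas are in
#' counts and invariant to grid refinement. A peak is `found` only when the
#' apex rises more than three noise standard deviations above baseline.
#'
#' @param chrom A single-trace tibble with columns `time_min`, `intensity`.
#' @param expected_rt Window center (min).
#' @param search_half_width Window half width (min), `> 0`.
#'
#' @return A one-row tibble: `found`, `rt_apex`, `area`, `snr`, `baseline`,
#'   `noise`.
#' @export
find_peak <- function(chrom, expected_rt, search_half_width) {
  stopifnot(search_half_width > 0)
  time <- chrom$time_min
  intensity <- chrom$intensity
  dt <- stats::median(diff(time))
  lo <- expected_rt - search_half_width
  hi <- expected_rt + search_half_width
  if (lo < min(time) - dt / 2 || hi > max(time) + dt / 2) {
    stop("search window [", lo, ", ", hi, "] outside the time grid",
      call. = FALSE
    )
  }
  bs <- baseline_stats(time, intensity, list(c(lo, hi)))
  idx <- which(time >= lo & time <= hi)
  pick_peak(
    time, intensity, idx[1], idx[length(idx)],
    bs$baseline, bs$noise, dt
  )
}

#' Compute a quantifier/qualifier ion ratio
#'
#' @param quantifier,qualifier One-row peak results from [find_peak()].
#' @return The qualifier/quantifier area ratio, or `NA` (undefined-ratio
#'   signal) when either peak is missing or the quantifier area is zero.
#' @export
ion_ratio <- function(quantifier, qualifier) {
  if (!isTRUE(quantifier$found) || !isTRUE(qualifier$found) ||
    is.na(quantifier$area) || quantifier$area <= 0) {
    return(NA_real_)
  }
  qualifier$area / quantifier$area
}

#' Resolve an epimer pair on a shared channel
#'
#' Integrates each epimer of a pair monitored on the same transition in its
#' own `+/- tolerance` window. Overlapping windows are split at the valley
#' minimum between the two apexes; when the valley does not return to
#' baseline (or no valley exists), both results carry a partial-resolution
#' flag. A peak centered between the two windows -- such as the
#' 13C2-THC-COOH interference eluting between the HHC-COOH epimers --
#' contributes to neither area.
#'
#' @param chrom A single-trace tibble (`time_min`, `intensity`).
#' @param rt_a,rt_b Expected epimer retention times (min), distinct.
#' @param tolerance Window half width (min).
#'
#' @return A two-row tibble (rows in the order `rt_a`, `rt_b`) with the
#'   [find_peak()] columns plus `expected_rt` and `partial`.
#' @export
epimer_pair_resolve <- function(chrom, rt_a, rt_b, tolerance) {
  if (rt_a == rt_b) stop("epimer retention times must differ", call. = FALSE)
  time <- chrom$time_min
  intensity <- chrom$intensity
  dt <- stats::median(diff(time))
  swap <- rt_a > rt_b
  r1 <- min(rt_a, rt_b)
  r2 <- max(rt_a, rt_b)
  w1 <- c(r1 - tolerance, r1 + tolerance)
  w2 <- c(r2 - tolerance, r2 + tolerance)
  bs <- baseline_stats(time, intensity, list(w1, w2))

  idx1 <- which(time >= w1[1] & time <= w1[2])
  idx2 <- which(time >= w2[1] & time <= w2[2])
  if (length(idx1) == 0 || length(idx2) == 0) {
    stop("epimer windows outside the time grid", call. = FALSE)
  }
  partial <- FALSE

  if (w1[2] >= w2[1]) {
    # assign local maxima to the epimer whose expected retention time they
    # are nearer; each window's apex is the largest maximum assigned to it,
    # so a window holding only the other peak (or its tail) claims nothing
    c1 <- local_max_candidates(intensity, idx1)
    c2 <- local_max_candidates(intensity, idx2)
    c1 <- c1[abs(time[c1] - r1) <= abs(time[c1] - r2) + 1e-9]
    c2 <- c2[abs(time[c2] - r2) <= abs(time[c2] - r1) + 1e-9]
    apex1 <- if (length(c1) > 0) c1[which.max(intensity[c1])] else NA_integer_
    apex2 <- if (length(c2) > 0) c2[which.max(intensity[c2])] else NA_integer_
    if (!is.na(apex1) && !is.na(apex2) && identical(apex1, apex2)) {
      # a single apex equidistant from both expected retention times:
      # treat as coeluting and split halfway between them
      partial <- TRUE
      split <- which.min(abs(time - (r1 + r2) / 2))
      idx1 <- idx1[idx1 <= split]
      idx2 <- idx2[idx2 >= split]
    } else if (!is.na(apex1) && !is.na(apex2)) {
      if (abs(apex2 - apex1) >= 2) {
        between <- (min(apex1, apex2) + 1L):(max(apex1, apex2) - 1L)
        split <- between[which.min(intensity[between])]
        partial <- intensity[split] > bs$baseline +
          (if (bs$noise > 0) 3 * bs$noise else 0)
      } else {
        partial <- TRUE
        split <- min(apex1, apex2)
      }
      idx1 <- idx1[idx1 <= split]
      idx2 <- idx2[idx2 >= split]
    } else if (!is.na(apex1)) {
      idx2 <- integer(0)
    } else if (!is.na(apex2)) {
      idx1 <- integer(0)
    }
  }

  p1 <- if (length(idx1) >= 3) {
    pick_peak(time, intensity, idx1[1], idx1[length(idx1)],
      bs$baseline, bs$noise, dt
    )
  } else {
    tibble::tibble(
      found = FALSE, rt_apex = NA_real_, area = 0, snr = NA_real_,
      baseline = bs$baseline, noise = bs$noise
    )
  }
  p2 <- if (length(idx2) >= 3) {
    pick_peak(time, intensity, idx2[1], idx2[length(idx2)],
      bs$baseline, bs$noise, dt
    )
  } else {
    tibble::tibble(
      found = FALSE, rt_apex = NA_real_, area = 0, snr = NA_real_,
      baseline = bs$baseline, noise = bs$noise
    )
  }
  out <- dplyr::bind_rows(p1, p2) |>
    dplyr::mutate(expected_rt = c(r1, r2), partial = partial)
  if (swap) out <- out[2:1, ]
  out
}

#' Extract the peak table of one injection
#'
#' Runs windowed peak picking for every panel analyte (quantifier and
#' qualifier transitions) and internal standard on one injection's
#' chromatograms. Analytes sharing a channel with a partner (epimer pairs and
#' the Delta-8/Delta-9 screen) are integrated with [epimer_pair_resolve()];
#' all others with [find_peak()]. The search half width is
#' `search_factor * rt_tol` (0.06 min by default) so that retention-time
#' jitter does not preclude detection before the identification criteria are
#' applied.
#'
#' @param chroms Long chromatogram tibble for a single injection
#'   (`channel`, `time_min`, `intensity`).
#' @param panel A `panel_config`.
#'
#' @return A tibble with one row per analyte x role: `analyte`, `role`,
#'   `channel`, plus the [find_peak()] columns and `partial`.
#' @export
process_injection <- function(chroms, panel) {
  hw <- search_half_width(panel)
  traces <- split(
    chroms[, c("time_min", "intensity")],
    chroms$channel
  )
  tr <- panel$transitions
  # analytes sharing a channel in the same role form a pair resolved jointly
  key <- paste(tr$channel, tr$role)
  out <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    if (!is.null(out[[i]])) next
    ch <- tr$channel[i]
    trace <- traces[[ch]]
    if (is.null(trace)) {
      stop("missing chromatogram for channel ", ch, " (", tr$analyte[i], ")",
        call. = FALSE
      )
    }
    mates <- which(key == key[i])
    if (tr$role[i] != "IS" && length(mates) == 2) {
      j <- setdiff(mates, i)
      res <- epimer_pair_resolve(trace, tr$rt[i], tr$rt[j], hw)
      out[[i]] <- res[1, ]
      out[[j]] <- res[2, ]
    } else {
      out[[i]] <- dplyr::mutate(
        find_peak(trace, tr$rt[i], hw),
        expected_rt = tr$rt[i], partial = FALSE
      )
    }
  }
  dplyr::bind_cols(
    tr[, c("analyte", "role", "channel")],
    dplyr::bind_rows(out)
  )
}
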