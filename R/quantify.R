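# Quantification: internal-standard response factors, weighted calibration
# fits with back-calculation acceptance, correction-factor semi-quantification
# for analytes lacking reference material, and LLOQ censoring.

#' Response factor
#'
#' Analyte peak area divided by the internal-standard peak area of the same
#' injection; the quantity all downstream quantification uses.
#'
#' @param analyte_area,is_area Peak areas (counts). Vectorized.
#' @return Numeric response factor(s); `NA` (undefined-response signal) where
#'   the IS area is zero, negative or missing.
#' @export
#' @examples
#' response_factor(2000, 1000)
response_factor <- function(analyte_area, is_area) {
  ifelse(!is.na(is_area) & is_area > 0, analyte_area / is_area, NA_real_)
}

#' Fit a calibration curve
#'
#' Weighted least-squares fit of response factor on concentration (default
#' 1/x weighting, the bioanalytical standard). The fit is accepted only when
#' every back-calculated calibrator concentration is within +/- 20% of
#' nominal (+/- 25% at the lowest level) and the slope is positive;
#' otherwise a rejected-fit error names the offending level.
#'
#' @param levels Calibrator concentrations (ng/mL); at least 5.
#' @param responses Response factors at those levels.
#' @param weighting `"1/x"`, `"1/x^2"` or `"none"`.
#' @param lloq Lower limit of quantification carried by the model (ng/mL).
#' @param analyte Analyte id (metadata).
#'
#' @return An object of class `calibration_model`: `analyte`, `slope`,
#'   `intercept`, `weighting`, `lloq`, `residuals` (tibble with per-level
#'   back-calculation), and the underlying `lm` fit.
#' @export
#' @examples
#' fit_calibration(c(0.53, 1.325, 5.3, 13.25, 26.5, 53),
#'   0.1 * c(0.53, 1.325, 5.3, 13.25, 26.5, 53),
#'   lloq = 0.53, analyte = "D9-THC"
#' )
fit_calibration <- function(levels, responses, weighting = "1/x",
                            lloq = NA_real_, analyte = NA_character_) {
  stopifnot(length(levels) == length(responses))
  ok <- !is.na(responses)
  levels <- levels[ok]
  responses <- responses[ok]
  if (length(levels) < 5) {
    stop("calibration requires at least 5 accepted levels", call. = FALSE)
  }
  w <- switch(weighting,
    "1/x" = 1 / levels,
    "1/x^2" = 1 / levels^2,
    "none" = rep(1, length(levels)),
    stop("unknown weighting scheme: ", weighting, call. = FALSE)
  )
  df <- data.frame(conc = levels, response = responses)
  fit <- stats::lm(response ~ conc, data = df, weights = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0) {
    stop("rejected fit: non-positive calibration slope", call. = FALSE)
  }
  back <- (responses - intercept) / slope
  rel_err <- back / levels - 1
  tol <- ifelse(levels == min(levels), 0.25, 0.20)
  bad <- which(abs(rel_err) > tol)
  if (length(bad) > 0) {
    stop(
      "rejected fit: back-calculated concentration off by ",
      sprintf("%.1f%%", 100 * rel_err[bad[1]]), " at level ",
      levels[bad[1]], " ng/mL",
      call. = FALSE
    )
  }
  structure(
    list(
      analyte = analyte, slope = slope, intercept = intercept,
      weighting = weighting, lloq = lloq,
      residuals = tibble::tibble(
        level = levels, response = responses,
        back_calculated = back, rel_err = rel_err
      ),
      fit = fit
    ),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(
    "<calibration_model> ", x$analyte, ": response = ",
    format(x$slope, digits = 4), " * conc + ",
    format(x$intercept, digits = 3),
    " (", x$weighting, " weighting, LLOQ ", x$lloq, " ng/mL)\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a calibration model
#'
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @return `tidy()`: the coefficient table of the weighted fit;
#'   `glance()`: a one-row model summary with slope, intercept, R squared,
#'   the worst back-calculation error and the LLOQ.
#' @export
tidy.calibration_model <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    analyte = x$analyte,
    term = c("intercept", "slope"),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @rdname tidy.calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(
    analyte = x$analyte,
    slope = x$slope,
    intercept = x$intercept,
    r.squared = suppressWarnings(summary(x$fit))$r.squared,
    max_backcalc_err = max(abs(x$residuals$rel_err)),
    n_levels = nrow(x$residuals),
    weighting = x$weighting,
    lloq = x$lloq
  )
}

#' Correction factor between a target and a surrogate analyte
#'
#' Computed from paired same-day response factors of the all-analyte
#' standard mixture analyzed on replicate days: the mean over days of the
#' surrogate/target response-factor ratio. Multiplying the target analyte's
#' response factor by the correction factor places it on the surrogate's
#' response scale, so the surrogate's calibration curve can be borrowed
#' (a self-correction factor is exactly 1).
#'
#' @param target_rfs,surrogate_rfs Per-day response factors (equal length,
#'   at least 2 days, same day order).
#' @param target,surrogate Analyte ids (metadata).
#' @param aggregate `"mean"` (default) or `"median"` across days.
#'
#' @return An object of class `correction_factor`: `target`, `surrogate`,
#'   `value`, `cv` (coefficient of variation of the per-day ratios),
#'   `n_days`.
#' @export
#' @examples
#' correction_factor(c(0.5, 0.5, 0.5), c(1, 1, 1))$value # 2
correction_factor <- function(target_rfs, surrogate_rfs,
                              target = NA_character_,
                              surrogate = NA_character_,
                              aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (length(target_rfs) != length(surrogate_rfs)) {
    stop("target and surrogate must have the same number of days",
      call. = FALSE
    )
  }
  if (length(target_rfs) < 2) {
    stop("correction factors require at least 2 replicate days", call. = FALSE)
  }
  if (any(is.na(target_rfs)) || any(is.na(surrogate_rfs)) ||
    any(target_rfs <= 0) || any(surrogate_rfs <= 0)) {
    stop("response factors must be positive on every day", call. = FALSE)
  }
  ratios <- surrogate_rfs / target_rfs
  value <- if (aggregate == "mean") mean(ratios) else stats::median(ratios)
  structure(
    list(
      target = target, surrogate = surrogate, value = value,
      cv = stats::sd(ratios) / mean(ratios), n_days = length(ratios)
    ),
    class = "correction_factor"
  )
}

#' @export
print.correction_factor <- function(x, ...) {
  cat(
    "<correction_factor> ", x$target, " -> ", x$surrogate, ": ",
    format(x$value, digits = 4), " (CV ",
    sprintf("%.1f%%", 100 * x$cv), ", ", x$n_days, " days)\n",
    sep = ""
  )
  invisible(x)
}

#' Estimate a concentration from a response factor
#'
#' Direct analytes invert their own calibration curve. Borrowed-curve
#' analytes first multiply their response factor by the correction factor
#' (placing it on the surrogate's response scale) and then invert the
#' surrogate's calibration. Censoring: a non-confirmed detection status
#' yields `not-detected` with value 0; an inverted value below the LLOQ is
#' reported but flagged `below-LLOQ`; a negative inversion is clamped to 0
#' and flagged.
#'
#' @param rf Response factor of the case injection.
#' @param model A `calibration_model` (the analyte's own, or the surrogate's
#'   for borrowed-curve analytes).
#' @param cf A `correction_factor`, or `NULL` for direct quantification.
#' @param status Detection status (`confirmed` / `partial` / `absent`).
#'
#' @return A one-row tibble: `value` (ng/mL), `censor` (`quantified`,
#'   `below-LLOQ`, `not-detected`), `method` (`direct`, `borrowed-curve`).
#' @export
estimate_concentration <- function(rf, model, cf = NULL, status = "confirmed") {
  method <- if (is.null(cf)) "direct" else "borrowed-curve"
  if (!identical(status, "confirmed")) {
    return(tibble::tibble(value = 0, censor = "not-detected", method = method))
  }
  eff_rf <- if (is.null(cf)) rf else rf * cf$value
  value <- (eff_rf - model$intercept) / model$slope
  censor <- "quantified"
  if (is.na(value)) {
    value <- 0
    censor <- "not-detected"
  } else if (value < 0) {
    value <- 0
    censor <- "below-LLOQ"
  } else if (!is.na(model$lloq) && value < model$lloq) {
    censor <- "below-LLOQ"
  }
  tibble::tibble(value = value, censor = censor, method = method)
}
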