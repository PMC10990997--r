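## Conversion of raw measurements into the kinetic model's inputs:
## autoradiogram optical densities -> tissue activity via precalibrated
## isotope standards, and scintillation counts -> blood concentration with
## quench correction.

DPM_PER_NCI <- 2220  # disintegrations per minute in one nanocurie

#' Fit an optical-density to activity calibration curve
#'
#' Autoradiogram optical densities are converted to tissue tracer activity
#' by reference to precalibrated isotope standards exposed alongside the
#' sections (eight standards spanning 40-1069 nCi/g in the assay this
#' package models). The default is monotone piecewise-linear interpolation
#' through the standards, which reproduces every standard exactly without
#' assuming a film-response model; an ordinary least-squares linear fit is
#' available as an alternative (its R-squared is reported).
#'
#' @param standards A data frame with columns `activity_nci_g` (or
#'   `activity`) and `od`: known activity (> 0, nCi/g) and measured optical
#'   density (> 0, arbitrary units) of each standard. At least two standards
#'   with distinct optical densities, co-monotone with activity.
#' @param mode `"interpolating"` (default) or `"linear"`.
#' @param extrapolation `"error"` (default) to refuse queries outside the
#'   standards' range, or `"clamp"` to clip them to the range limits.
#' @return An object of class `calibration_curve`.
#' @examples
#' std <- data.frame(activity_nci_g = c(40, 100, 400, 1069),
#'                   od = c(0.04, 0.10, 0.40, 1.069))
#' cal <- fit_calibration(std)
#' predict(cal, 0.5)  # 500 nCi/g
#' @export
fit_calibration <- function(standards,
                            mode = c("interpolating", "linear"),
                            extrapolation = c("error", "clamp")) {
  mode <- match.arg(mode)
  extrapolation <- match.arg(extrapolation)
  if (!is.data.frame(standards))
    iap_validation_error("standards must be a data frame")
  act_col <- intersect(c("activity_nci_g", "activity"), names(standards))[1]
  if (is.na(act_col) || !"od" %in% names(standards))
    iap_validation_error("standards must have columns 'activity_nci_g' (or 'activity') and 'od'")
  activity <- as.numeric(standards[[act_col]])
  od <- as.numeric(standards[["od"]])
  if (length(activity) < 2)
    iap_validation_error("at least 2 calibration standards are required")
  if (anyNA(activity) || anyNA(od))
    iap_validation_error("calibration standards contain missing values")
  if (any(activity <= 0) || any(od <= 0))
    iap_validation_error("standard activities and optical densities must be positive")
  if (anyDuplicated(od))
    iap_validation_error("duplicate optical density values among the standards")
  ord <- order(od)
  activity <- activity[ord]
  od <- od[ord]
  if (any(diff(activity) < 0))
    iap_stop("standards are not co-monotone: activity must not decrease with optical density",
             "iap_calibration_error")

  fit <- NULL
  r_squared <- NULL
  if (mode == "linear") {
    fit <- stats::lm(activity ~ od)
    if (stats::coef(fit)[["od"]] <= 0)
      iap_stop("linear calibration has a non-positive slope; the fitted map would not be monotone",
               "iap_calibration_error")
    r_squared <- 1 - sum(stats::residuals(fit)^2) /
      sum((activity - mean(activity))^2)
  }

  structure(list(mode = mode,
                 extrapolation = extrapolation,
                 od_range = range(od),
                 activity_range = range(activity),
                 standards = data.frame(activity_nci_g = activity, od = od),
                 coefficients = if (mode == "linear") stats::coef(fit) else NULL,
                 r_squared = r_squared),
            class = "calibration_curve")
}

#' Map optical densities to tissue activity
#'
#' @param object A `calibration_curve` from [fit_calibration()].
#' @param od Optical density value(s) to convert.
#' @param ... Unused.
#' @return Calibrated activity in nCi/g, same length as `od`.
#' @export
predict.calibration_curve <- function(object, od, ...) {
  if (!is.numeric(od) || anyNA(od))
    iap_validation_error("od must be numeric without missing values")
  lo <- object$od_range[1]; hi <- object$od_range[2]
  out <- od < lo | od > hi
  if (any(out)) {
    if (object$extrapolation == "error")
      iap_range_error(sprintf(
        "optical density %.6g outside the calibrated range [%.6g, %.6g] (activities %.6g-%.6g nCi/g); refit with wider standards or use extrapolation = \"clamp\"",
        od[out][1], lo, hi, object$activity_range[1], object$activity_range[2]))
    od <- pmin(pmax(od, lo), hi)
  }
  if (object$mode == "interpolating") {
    stats::approx(object$standards$od, object$standards$activity_nci_g, xout = od)$y
  } else {
    val <- object$coefficients[[1]] + object$coefficients[[2]] * od
    bad <- val < object$activity_range[1] | val > object$activity_range[2]
    if (any(bad)) {
      if (object$extrapolation == "error")
        iap_range_error(sprintf(
          "calibrated activity %.6g nCi/g outside the standards' range [%.6g, %.6g]",
          val[bad][1], object$activity_range[1], object$activity_range[2]))
      val <- pmin(pmax(val, object$activity_range[1]), object$activity_range[2])
    }
    val
  }
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve (%s): %d standards, OD [%.4g, %.4g] -> activity [%.4g, %.4g] nCi/g%s\n",
              x$mode, nrow(x$standards),
              x$od_range[1], x$od_range[2],
              x$activity_range[1], x$activity_range[2],
              if (!is.null(x$r_squared)) sprintf(", R^2 = %.4f", x$r_squared) else ""))
  invisible(x)
}

#' Calibrated activity of a region's density readings
#'
#' Each brain region contributes several replicate optical-density readings
#' (at least eight in the assay this package models); the region's tissue
#' concentration is the calibrated activity of their mean density.
#' Per-reading calibrated values and their SD are returned as a dispersion
#' check.
#'
#' @param readings Numeric vector of optical densities for one region.
#' @param curve A `calibration_curve`.
#' @param min_readings Minimum number of readings required (default 8).
#' @return A list with `activity` (nCi/g, from the mean OD), `per_reading`
#'   (calibrated individual readings), `sd` (their SD) and `n`.
#' @examples
#' cal <- fit_calibration(data.frame(activity_nci_g = c(40, 1069), od = c(40, 1069)))
#' region_activity(rep(300, 8), cal)$activity  # 300
#' @export
region_activity <- function(readings, curve, min_readings = 8) {
  if (!is.numeric(readings) || anyNA(readings))
    iap_validation_error("readings must be numeric without missing values")
  if (length(readings) < min_readings)
    iap_validation_error(sprintf(
      "only %d density readings supplied; at least %d are required per region",
      length(readings), min_readings))
  if (!inherits(curve, "calibration_curve"))
    iap_validation_error("curve must be a calibration_curve")
  per <- predict(curve, readings)
  list(activity = predict(curve, mean(readings)),
       per_reading = per,
       sd = stats::sd(per),
       n = length(readings))
}

#' Convert scintillation counts to blood tracer concentration
#'
#' Arterial samples (10 ul by default) are counted by liquid scintillation;
#' counts per minute are quench-corrected to disintegrations per minute by
#' dividing by the counting efficiency, converted to nCi (2220 dpm per nCi)
#' and divided by the sample volume:
#' `conc = (cpm / efficiency) / 2220 / volume_ml` nCi per ml blood.
#'
#' The efficiency may be given directly, or computed from a linear quench
#' curve `efficiency = a + b * quench_index` (clipped to at most 1). With
#' neither supplied, efficiency 1 is assumed (no quench correction) and a
#' warning is issued.
#'
#' @param cpm Raw counts per minute, >= 0 (vectorized).
#' @param efficiency Counting efficiency in (0, 1], or `NULL`.
#' @param quench_index Quench indicator value(s), used with `quench_coef`.
#' @param quench_coef Numeric `c(a, b)` of the linear quench curve.
#' @param volume_ml Sample volume in ml (default 0.010, i.e. 10 ul).
#' @return Blood concentration in nCi per ml.
#' @examples
#' counts_to_concentration(2220, efficiency = 1)    # 100 nCi/ml
#' counts_to_concentration(1110, efficiency = 0.5)  # 100 nCi/ml
#' @export
counts_to_concentration <- function(cpm, efficiency = NULL,
                                    quench_index = NULL, quench_coef = NULL,
                                    volume_ml = 0.010) {
  if (!is.numeric(cpm) || anyNA(cpm))
    iap_validation_error("cpm must be numeric without missing values")
  if (any(cpm < 0))
    iap_validation_error("counts must be non-negative")
  if (is.null(efficiency)) {
    if (!is.null(quench_index) && !is.null(quench_coef)) {
      if (length(quench_coef) != 2L || anyNA(quench_coef))
        iap_validation_error("quench_coef must be c(a, b)")
      efficiency <- pmin(quench_coef[1] + quench_coef[2] * quench_index, 1)
      if (any(efficiency <= 0))
        iap_validation_error("the quench curve yields a non-positive counting efficiency")
    } else {
      warning("no counting efficiency or quench curve supplied; assuming efficiency 1.0 (no quench correction)")
      efficiency <- 1
    }
  }
  if (any(efficiency <= 0) || any(efficiency > 1))
    iap_validation_error("counting efficiency must lie in (0, 1]")
  if (any(volume_ml <= 0))
    iap_validation_error("sample volume must be positive")
  (cpm / efficiency) / DPM_PER_NCI / volume_ml
}
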