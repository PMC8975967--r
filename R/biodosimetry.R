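#' Fit a linear dose-response calibration curve
#'
#' Ordinary least squares of mean foci per cell (y) on absorbed dose (x),
#' y = a x + b. Unweighted OLS via [stats::lm()]; the returned curve
#' carries the coefficients, their standard errors, the fit R^2 and the
#' dose range spanned by the calibration points (estimates outside it are
#' flagged as extrapolated by [estimateDose()]).
#'
#' @param points data.frame with columns `dose_gy` and `mean_foci` (one
#'   row per dose group), or a 2-column matrix in that order.
#' @return A [CalibrationCurve-class].
#' @examples
#' pts <- data.frame(dose_gy = c(0, 1, 2, 4),
#'                   mean_foci = 2 * c(0, 1, 2, 4) + 1)
#' fitCalibration(pts)   # recovers a = 2, b = 1, R^2 = 1
#' @export
fitCalibration <- function(points) {
  if (is.matrix(points))
    points <- data.frame(dose_gy = points[, 1L], mean_foci = points[, 2L])
  if (!all(c("dose_gy", "mean_foci") %in% names(points)))
    stop("points must have columns dose_gy and mean_foci", call. = FALSE)
  if (nrow(points) < 3L)
    stop("fit error: at least 3 calibration points are required",
         call. = FALSE)
  if (length(unique(points$dose_gy)) < 2L)
    stop("fit error: calibration doses must not all be equal",
         call. = FALSE)
  fit <- stats::lm(mean_foci ~ dose_gy, data = points)
  # summary.lm warns on exact-line input; an exact fit is fine here
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  r2 <- sm$r.squared
  new("CalibrationCurve",
      slopeA = unname(co["dose_gy", "Estimate"]),
      interceptB = unname(co["(Intercept)", "Estimate"]),
      rSquared = if (is.finite(r2)) max(0, min(1, r2)) else NA_real_,
      seA = unname(co["dose_gy", "Std. Error"]),
      seB = unname(co["(Intercept)", "Std. Error"]),
      doseRangeGy = range(points$dose_gy),
      nPoints = nrow(points))
}

#' Predict the mean focus count at a dose
#'
#' The forward calibration model: `a * dose + b`.
#'
#' @param curve a [CalibrationCurve-class].
#' @param doseGy dose(s) in Gy.
#' @return Predicted mean foci per cell.
#' @export
predictFoci <- function(curve, doseGy) {
  stopifnot(is(curve, "CalibrationCurve"))
  curve@slopeA * doseGy + curve@interceptB
}

#' Estimate absorbed dose from a mean focus count
#'
#' Inverts the calibration curve: `dose = (mean_foci - b) / a`. Negative
#' estimates are preserved (a measured count below the background
#' intercept legitimately inverts to a small negative dose); set
#' `truncateAtZero = TRUE` to clamp them to 0. Estimates outside the
#' curve's calibration range are flagged as extrapolated. When the true
#' dose is supplied, the absolute difference `|estimated - actual|` (see
#' [doseMAD()]) is filled in.
#'
#' @param curve a [CalibrationCurve-class] with non-zero slope.
#' @param meanFoci measured mean foci per cell (vectorised).
#' @param actualDoseGy optional true dose(s) for error reporting.
#' @param truncateAtZero clamp negative estimates to 0 (default `FALSE`).
#' @return data.frame with columns `mean_foci`, `estimated_dose_gy`,
#'   `actual_dose_gy`, `mad_gy`, `extrapolated`.
#' @export
estimateDose <- function(curve, meanFoci, actualDoseGy = NA_real_,
                         truncateAtZero = FALSE) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (curve@slopeA == 0)
    stop("inversion error: calibration slope is zero", call. = FALSE)
  est <- (meanFoci - curve@interceptB) / curve@slopeA
  if (truncateAtZero) est <- pmax(est, 0)
  actual <- rep_len(as.numeric(actualDoseGy), length(est))
  data.frame(
    mean_foci = meanFoci,
    estimated_dose_gy = est,
    actual_dose_gy = actual,
    mad_gy = ifelse(is.na(actual), NA_real_, abs(est - actual)),
    extrapolated = est < curve@doseRangeGy[1L] | est > curve@doseRangeGy[2L])
}

#' Absolute dose-estimation error
#'
#' The mean absolute difference between an estimated and the actual dose,
#' `|estimated - actual|`, in Gy.
#'
#' @param estimatedDoseGy,actualDoseGy doses in Gy (vectorised).
#' @return Non-negative absolute difference(s).
#' @examples
#' doseMAD(2.75, 2)    # 0.75
#' doseMAD(-0.52, 0)   # 0.52
#' @export
doseMAD <- function(estimatedDoseGy, actualDoseGy) {
  if (any(!is.finite(estimatedDoseGy)) || any(!is.finite(actualDoseGy)))
    stop("doses must be finite", call. = FALSE)
  abs(estimatedDoseGy - actualDoseGy)
}

#' Average MAD across dose groups
#'
#' Arithmetic mean of per-group absolute dose errors; printed dose tables
#' round it half-up to 2 decimals ([roundHalfUp()]).
#'
#' @param mads non-empty vector of non-negative MADs (Gy).
#' @return Their mean.
#' @examples
#' averageMAD(c(0.27, 0.75, 0.31, 0.89))             # 0.555
#' roundHalfUp(averageMAD(c(0.27, 0.75, 0.31, 0.89)), 2)  # 0.56
#' @export
averageMAD <- function(mads) {
  if (length(mads) == 0L)
    stop("averageMAD needs at least one value", call. = FALSE)
  if (any(!is.finite(mads)) || any(mads < 0))
    stop("MADs must be finite and non-negative", call. = FALSE)
  mean(mads)
}

#' Write / read a calibration curve as JSON
#'
#' @param curve a [CalibrationCurve-class].
#' @param path JSON file path.
#' @return `writeCalibration` invisibly returns `path`; `readCalibration`
#'   returns the [CalibrationCurve-class].
#' @name calibration-io
NULL

#' @rdname calibration-io
#' @export
writeCalibration <- function(curve, path) {
  stopifnot(is(curve, "CalibrationCurve"))
  jsonlite::write_json(list(
    slope_a = curve@slopeA, intercept_b = curve@interceptB,
    r_squared = curve@rSquared, se_a = curve@seA, se_b = curve@seB,
    dose_range_gy = curve@doseRangeGy, n_points = curve@nPoints),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname calibration-io
#' @export
readCalibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CalibrationCurve", slopeA = j$slope_a, interceptB = j$intercept_b,
      rSquared = j$r_squared, seA = j$se_a, seB = j$se_b,
      doseRangeGy = as.numeric(j$dose_range_gy),
      nPoints = as.integer(j$n_points))
}
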