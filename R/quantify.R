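#' Fit a standards calibration line
#'
#' Ordinary least squares of peak area on concentration over a series of
#' fluoride standards. The returned object carries the sufficient statistics
#' (residual SD, mean concentration, concentration sum of squares) needed for
#' classical inverse-prediction intervals.
#'
#' @param concentration Standard concentrations in uM (at least 3 distinct
#'   values).
#' @param area Measured (typically normalised) peak areas, same length.
#' @return An object of class `calibration_fit` with fields `slope`,
#'   `intercept`, `n`, `residual_sd`, `x_mean`, `sxx`, `r_squared`,
#'   `se_slope` and the input data.
#' @examples
#' cal <- fit_calibration(c(1, 5, 10), 2 * c(1, 5, 10) + 1)
#' cal$slope; cal$intercept
#' @export
fit_calibration <- function(concentration, area) {
  if (length(concentration) != length(area)) {
    stop("concentration and area must have equal length")
  }
  if (length(unique(concentration)) < 3) {
    stop("calibration needs at least 3 distinct concentrations")
  }
  fit <- stats::lm(area ~ concentration)
  # exact standards (residual ~ 0) are legitimate here; summary.lm warns
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  n <- length(area)
  sxx <- sum((concentration - mean(concentration))^2)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      n = n,
      residual_sd = sm$sigma,
      x_mean = mean(concentration),
      sxx = sxx,
      r_squared = sm$r.squared,
      se_slope = sm$sigma / sqrt(sxx),
      data = data.frame(concentration = concentration, area = area)
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "Calibration: area = %.4g * conc + %.4g  (n = %d, R^2 = %.4f, s = %.3g)\n",
    x$slope, x$intercept, x$n, x$r_squared, x$residual_sd))
  invisible(x)
}

#' Estimate an unknown concentration by inverse prediction
#'
#' Inverts the calibration line: `x_hat = (y_bar - intercept) / slope` for
#' the mean of `m_reps` replicate area measurements, with the classical
#' inverse-prediction interval
#' `x_hat +/- t * (s/|slope|) * sqrt(1/m + 1/n + (x_hat - x_mean)^2 / sxx)`.
#' An optional Fieller construction is available for slopes close to zero.
#'
#' @param cal A [fit_calibration()] result.
#' @param measured_area Area measurement(s) of the unknown; a vector is
#'   averaged and sets `m_reps`.
#' @param m_reps Number of replicate measurements behind `measured_area`
#'   (defaults to `length(measured_area)`).
#' @param confidence Coverage of the interval (default 0.95).
#' @param method `"classical"` (default) or `"fieller"`.
#' @return An object of class `concentration_estimate` with fields
#'   `estimate`, `interval` (`c(low, high)`) and `confidence`.
#' @export
invert_calibration <- function(cal, measured_area,
                               m_reps = length(measured_area),
                               confidence = 0.95,
                               method = c("classical", "fieller")) {
  method <- match.arg(method)
  if (!inherits(cal, "calibration_fit")) stop("cal must be a calibration_fit")
  if (!all(is.finite(measured_area))) stop("measured_area must be finite")
  if (m_reps < 1) stop("m_reps must be >= 1")
  if (cal$slope == 0) stop("calibration slope is zero; cannot invert")
  tcrit <- stats::qt(1 - (1 - confidence) / 2, df = cal$n - 2)
  if (abs(cal$slope) <= tcrit * cal$se_slope) {
    stop("slope is indistinguishable from zero at this confidence; ",
         "the inverse-prediction interval is unbounded")
  }
  ybar <- mean(measured_area)
  xhat <- (ybar - cal$intercept) / cal$slope
  if (method == "classical") {
    half <- tcrit * (cal$residual_sd / abs(cal$slope)) *
      sqrt(1 / m_reps + 1 / cal$n + (xhat - cal$x_mean)^2 / cal$sxx)
    interval <- c(xhat - half, xhat + half)
  } else {
    # Fieller: exact interval for the ratio of normal quantities; reduces to
    # the classical interval as g -> 0
    g <- (tcrit * cal$se_slope / cal$slope)^2
    if (g >= 1) {
      stop("slope too uncertain for a bounded Fieller interval")
    }
    d <- xhat - cal$x_mean
    rad <- (tcrit * cal$residual_sd / abs(cal$slope)) *
      sqrt((1 / m_reps + 1 / cal$n) * (1 - g) + d^2 / cal$sxx)
    interval <- sort(cal$x_mean + (d + c(-rad, rad)) / (1 - g))
  }
  structure(
    list(estimate = xhat, interval = interval, confidence = confidence,
         m_reps = m_reps, method = method),
    class = "concentration_estimate"
  )
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf("Concentration: %.3g uM, %d%% interval [%.3g, %.3g] uM (%s)\n",
              x$estimate, round(100 * x$confidence), x$interval[1],
              x$interval[2], x$method))
  invisible(x)
}

#' Calibration-slope limit of detection
#'
#' The smallest concentration whose expected peak area equals `k` (default 3)
#' times the standard error of a noise-only numeric integration over a
#' window proportional to the linewidth:
#' `LOD = k * sd * sqrt(n_pts) * d_nu / (slope * reference_area)`, where
#' `n_pts = 2 * window_mult * fwhm / d_nu` is the number of points in a
#' `+/- window_mult * fwhm` window. Used to certify "below X uM" statements
#' for spectra in which no fluoride peak is detected.
#'
#' @param cal A [fit_calibration()] result; its slope is in (normalised)
#'   area per uM.
#' @param noise A [estimate_noise()] result from a blank or signal-free
#'   region.
#' @param fwhm Assumed fluoride linewidth in Hz (after processing).
#' @param reference_area The raw area corresponding to one unit of the
#'   calibration's area scale (the top-standard area when areas were
#'   normalised; 1 when raw areas were used).
#' @param k Detection multiple (default 3, the conventional 3-sigma rule).
#' @param window_mult Integration half-width in linewidths (default 2).
#' @return Limit of detection in uM.
#' @export
limit_of_detection <- function(cal, noise, fwhm, reference_area = 1,
                               k = 3, window_mult = 2) {
  if (!inherits(cal, "calibration_fit")) stop("cal must be a calibration_fit")
  if (!inherits(noise, "noise_estimate")) stop("noise must be a noise_estimate")
  if (cal$slope <= 0) stop("LOD requires a positive calibration slope")
  if (fwhm <= 0) stop("fwhm must be > 0")
  f0 <- noise$spectrometer_frequency
  dnu <- noise$ppm_resolution * f0
  n_pts <- max(2, ceiling(2 * window_mult * fwhm / dnu))
  area_se <- noise$sd * sqrt(n_pts) * dnu
  k * (area_se / reference_area) / cal$slope
}
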