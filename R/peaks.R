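#' Robust noise estimate from a signal-free region
#'
#' Estimates the spectral noise standard deviation as 1.4826 times the median
#' absolute deviation of the real part over a region chosen to contain no
#' signal. The MAD is insensitive to the occasional outlier but the region
#' must still be peak-free; a gross signal in the region raises an error.
#'
#' @param spec An `nmr_spectrum`.
#' @param region `c(lo, hi)` ppm interval inside the spectral window.
#' @return An object of class `noise_estimate` with fields `sd`, `region`,
#'   `n_points`, `ppm_resolution` and `spectrometer_frequency`.
#' @export
estimate_noise <- function(spec, region = c(-105, -95)) {
  if (!inherits(spec, "nmr_spectrum")) stop("spec must be an nmr_spectrum")
  lo <- min(region); hi <- max(region)
  sel <- spec$ppm >= lo & spec$ppm <= hi
  if (!any(sel)) stop("noise region lies outside the spectral window")
  re <- Re(spec$intensity)[sel]
  sd <- stats::mad(re)  # 1.4826 * MAD
  peak_floor <- 1e-6 * max(abs(Re(spec$intensity)))
  if (max(abs(re - stats::median(re))) > pmax(10 * sd, peak_floor) &&
      sd > 0) {
    stop("noise region appears to contain signal; choose a peak-free region")
  }
  structure(
    list(sd = sd, region = c(lo, hi), n_points = sum(sel),
         ppm_resolution = ppm_resolution(spec),
         spectrometer_frequency = spec$acq$spectrometer_frequency),
    class = "noise_estimate"
  )
}

#' Detect peaks above a signal-to-noise threshold
#'
#' Local maxima of the real part whose height is at least
#' `snr_threshold * noise$sd`, returned in decreasing height order. To
#' suppress single-point noise spikes, both neighbours of a candidate
#' maximum must also exceed half the height threshold — a real line always
#' spans several points at the digital resolutions used here. Maxima closer
#' together than `min_separation` ppm are coalesced to the tallest.
#'
#' @param spec An `nmr_spectrum`.
#' @param snr_threshold Detection threshold as a multiple of the noise SD
#'   (default 3).
#' @param noise A [estimate_noise()] result; computed from `noise_region`
#'   when omitted.
#' @param noise_region Region used when `noise` is missing.
#' @param min_separation Minimum separation between reported peaks in ppm.
#' @return Numeric vector of candidate centers (ppm), possibly empty, with
#'   the corresponding heights and SNRs as attributes `height` and `snr`.
#' @export
detect_peaks <- function(spec, snr_threshold = 3, noise = NULL,
                         noise_region = c(-105, -95), min_separation = 0.05) {
  if (snr_threshold <= 0) stop("snr_threshold must be > 0")
  if (is.null(noise)) noise <- estimate_noise(spec, noise_region)
  re <- Re(spec$intensity)
  n <- length(re)
  if (n < 3) return(numeric(0))
  is_max <- c(FALSE, re[2:(n - 1)] > re[1:(n - 2)] &
                re[2:(n - 1)] >= re[3:n], FALSE)
  idx <- which(is_max & re >= snr_threshold * noise$sd)
  if (noise$sd > 0 && length(idx) > 0) {
    half <- snr_threshold * noise$sd / 2
    ok <- re[pmax(idx - 1, 1)] >= half & re[pmin(idx + 1, n)] >= half
    idx <- idx[ok]
  }
  if (length(idx) == 0) {
    out <- numeric(0)
    attr(out, "height") <- numeric(0)
    attr(out, "snr") <- numeric(0)
    return(out)
  }
  ord <- idx[order(re[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(spec$ppm[i] - spec$ppm[kept]) >= min_separation)) {
      kept <- c(kept, i)
    }
  }
  out <- spec$ppm[kept]
  attr(out, "height") <- re[kept]
  attr(out, "snr") <- if (noise$sd > 0) re[kept] / noise$sd else rep(Inf, length(kept))
  out
}

lorentz_eval <- function(x, A, w, x0, b) (2 * A / pi) * w / (4 * (x - x0)^2 + w^2) + b

#' Fit a Lorentzian lineshape to one peak
#'
#' Nonlinear least squares of
#' `L(d) = (2A/pi) * w / (4 (d - d0)^2 + w^2) + b`
#' to the real part over a window around `center_guess`, where `A` is the
#' full-line integral of `L - b` (in ppm units internally), `w` the FWHM in
#' ppm and `b` a local baseline. Areas and widths are reported on the Hz
#' scale (`area = A * spectrometer_frequency`, `fwhm = w *
#' spectrometer_frequency`) so they match the simulator's units. Parameter
#' standard errors come from the Jacobian at the optimum.
#'
#' @param spec An `nmr_spectrum` (phased; the real part is fit).
#' @param center_guess Approximate peak position in ppm.
#' @param window Half-width of the fit window in ppm (default 1.0).
#' @param max_fwhm Upper bound on the fitted width in ppm (default 0.2,
#'   i.e. ~150 Hz at 752.75 MHz — far above any liquid-state 19F line here).
#'   The bound keeps low-SNR fits from degenerating into a broad
#'   pseudo-baseline; a fit pinned at the bound sets the `width_at_bound`
#'   flag.
#' @return An object of class `peak_fit` with fields `center` (ppm), `area`,
#'   `fwhm` (Hz), `baseline`, standard errors `se_center`, `se_area`,
#'   `se_fwhm`, plus `rss`, `n_points`, `fit_window` and a `width_at_bound`
#'   flag set when the fitted width runs into the window edge.
#' @export
fit_lorentzian <- function(spec, center_guess, window = 1.0,
                           max_fwhm = 0.2) {
  if (!inherits(spec, "nmr_spectrum")) stop("spec must be an nmr_spectrum")
  sel <- spec$ppm >= center_guess - window & spec$ppm <= center_guess + window
  if (sum(sel) < 5) stop("fit window contains fewer than 5 points")
  x <- spec$ppm[sel]
  y <- Re(spec$intensity)[sel]
  f0 <- spec$acq$spectrometer_frequency

  # starting values from the tallest point and its half-height width
  i_max <- which.max(y)
  x0_0 <- x[i_max]
  b0 <- stats::median(y[abs(x - x0_0) > window / 2])
  if (!is.finite(b0)) b0 <- min(y)
  h0 <- y[i_max] - b0
  if (h0 <= 0) stop("no positive excursion in the fit window")
  above <- which(y - b0 > h0 / 2)
  w_min <- ppm_resolution(spec) / 100
  w0 <- min(max(abs(diff(range(x[above]))), ppm_resolution(spec)),
            max_fwhm)
  A0 <- h0 * pi * w0 / 2

  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ (2 * A / pi) * w / (4 * (x - x0)^2 + w^2) + b,
      data = dat,
      start = list(A = A0, w = w0, x0 = x0_0, b = b0),
      lower = c(-Inf, w_min, min(x), -Inf),
      upper = c(Inf, max_fwhm, max(x), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    stop(sprintf("Lorentzian fit failed near %.2f ppm: %s",
                 center_guess, conditionMessage(fit)))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  if (cf[["x0"]] < min(x) || cf[["x0"]] > max(x)) {
    stop(sprintf("fitted center %.3f ppm escaped the window around %.2f ppm",
                 cf[["x0"]], center_guess))
  }
  w_ppm <- abs(cf[["w"]])
  structure(
    list(
      center = cf[["x0"]],
      area = cf[["A"]] * f0,
      fwhm = w_ppm * f0,
      baseline = cf[["b"]],
      se_center = unname(se["x0"]),
      se_area = unname(se["A"]) * f0,
      se_fwhm = unname(se["w"]) * f0,
      rss = sum(stats::resid(fit)^2),
      n_points = length(x),
      fit_window = c(center_guess - window, center_guess + window),
      width_at_bound = w_ppm >= 0.99 * max_fwhm
    ),
    class = "peak_fit"
  )
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("Lorentzian fit: center %.4f ppm (se %.2g), area %.4g (se %.2g), fwhm %.3g Hz (se %.2g)\n",
              x$center, x$se_center, x$area, x$se_area, x$fwhm, x$se_fwhm))
  invisible(x)
}

#' Jointly fit several overlapping Lorentzian peaks
#'
#' Used when candidate centers fall closer together than twice the fit
#' window, where independent single-peak fits would each absorb the
#' neighbour's tails. Shares a single local baseline.
#'
#' @param spec An `nmr_spectrum`.
#' @param center_guesses Numeric vector of approximate centers (ppm).
#' @param window Half-width in ppm of the window around the span of the
#'   guesses.
#' @return A list of `peak_fit` objects, one per guess, in input order.
#' @export
fit_lorentzians <- function(spec, center_guesses, window = 1.0,
                            max_fwhm = 0.2) {
  k <- length(center_guesses)
  if (k == 1) {
    return(list(fit_lorentzian(spec, center_guesses, window, max_fwhm)))
  }
  lo <- min(center_guesses) - window
  hi <- max(center_guesses) + window
  sel <- spec$ppm >= lo & spec$ppm <= hi
  x <- spec$ppm[sel]
  y <- Re(spec$intensity)[sel]
  f0 <- spec$acq$spectrometer_frequency
  b0 <- stats::quantile(y, 0.1, names = FALSE)
  w_min <- ppm_resolution(spec) / 100
  w0 <- min(max(4 * ppm_resolution(spec), 1e-4), max_fwhm)
  starts <- list(b = b0)
  lower <- c(-Inf)
  upper <- c(Inf)
  for (j in seq_len(k)) {
    hj <- max(y[which.min(abs(x - center_guesses[j]))] - b0, 1e-12)
    starts[[paste0("A", j)]] <- hj * pi * w0 / 2
    starts[[paste0("w", j)]] <- w0
    starts[[paste0("x", j)]] <- center_guesses[j]
    lower <- c(lower, -Inf, w_min, lo)
    upper <- c(upper, Inf, max_fwhm, hi)
  }
  terms <- paste0("(2*A", seq_len(k), "/pi)*w", seq_len(k),
                  "/(4*(x - x", seq_len(k), ")^2 + w", seq_len(k), "^2)",
                  collapse = " + ")
  form <- stats::as.formula(paste("y ~", terms, "+ b"))
  fit <- minpack.lm::nlsLM(form, data = data.frame(x = x, y = y),
                           start = starts, lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(cf)),
                                                     names(cf)))
  rss <- sum(stats::resid(fit)^2)
  lapply(seq_len(k), function(j) {
    structure(
      list(
        center = unname(cf[paste0("x", j)]),
        area = unname(cf[paste0("A", j)]) * f0,
        fwhm = abs(unname(cf[paste0("w", j)])) * f0,
        baseline = unname(cf["b"]),
        se_center = unname(se[paste0("x", j)]),
        se_area = unname(se[paste0("A", j)]) * f0,
        se_fwhm = unname(se[paste0("w", j)]) * f0,
        rss = rss,
        n_points = length(x),
        fit_window = c(lo, hi),
        width_at_bound = FALSE
      ),
      class = "peak_fit"
    )
  })
}

#' Integrate a fitted peak
#'
#' `analytic` mode returns the fitted full-line Lorentzian area (robust to
#' window truncation and the default for quantification). `numeric` mode
#' returns the trapezoidal integral of the baseline-subtracted real part over
#' a window, converted to the Hz scale; a window of half-width `m` times the
#' FWHM captures the fraction `(2/pi) * atan(2m)` of a Lorentzian's area.
#'
#' @param fit A `peak_fit`.
#' @param mode `"analytic"` or `"numeric"`.
#' @param spec Required for numeric mode.
#' @param window `c(lo, hi)` ppm integration window for numeric mode.
#' @param noise Optional [estimate_noise()] result; when given, numeric mode
#'   reports the integration-noise standard error.
#' @return A list with `area` and `se` (NA when not computable).
#' @export
integrate_peak <- function(fit, mode = c("analytic", "numeric"),
                           spec = NULL, window = NULL, noise = NULL) {
  mode <- match.arg(mode)
  if (mode == "analytic") {
    return(list(area = fit$area, se = fit$se_area))
  }
  if (is.null(spec) || is.null(window)) {
    stop("numeric integration requires both spec and window")
  }
  lo <- min(window); hi <- max(window)
  sel <- spec$ppm >= lo & spec$ppm <= hi
  if (sum(sel) < 2) stop("integration window contains fewer than 2 points")
  ord <- order(spec$ppm[sel])
  x <- spec$ppm[sel][ord]
  y <- Re(spec$intensity)[sel][ord] - fit$baseline
  f0 <- spec$acq$spectrometer_frequency
  area_ppm <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  se <- NA_real_
  if (!is.null(noise)) {
    se <- noise$sd * sqrt(sum(sel)) * ppm_resolution(spec) * f0
  }
  list(area = area_ppm * f0, se = se)
}

#' Full-window numeric integral of the real part
#'
#' Trapezoid-free exact discrete integral `sum(Re) * d_nu` over the whole
#' spectral window; with first-point halving this equals the simulated area
#' of a single line to machine precision (discrete Fourier identity).
#'
#' @param spec An `nmr_spectrum`.
#' @return The integral in area units (intensity x Hz).
#' @export
integrate_spectrum <- function(spec) {
  dnu <- ppm_resolution(spec) * spec$acq$spectrometer_frequency
  sum(Re(spec$intensity)) * dnu
}

#' Normalise a peak area by a reference area
#'
#' @param area Area(s) to normalise.
#' @param reference_area Positive reference (conventionally the top
#'   calibration standard, which then maps to 1).
#' @return `area / reference_area`.
#' @export
normalise_area <- function(area, reference_area) {
  if (!is.numeric(reference_area) || reference_area <= 0) {
    stop("reference_area must be > 0")
  }
  area / reference_area
}
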