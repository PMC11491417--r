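#' Exponential apodization (line broadening)
#'
#' Multiplies sample `k` by `exp(-pi * lb * t_k)`, which convolves every line
#' with a Lorentzian of width `lb` Hz: a line of width `w` emerges with width
#' `w + lb`. `lb = 0` is the identity.
#'
#' @param fid A `fid` object.
#' @param line_broadening Line broadening in Hz, `>= 0`.
#' @return An apodized `fid`.
#' @export
apodize <- function(fid, line_broadening) {
  if (!inherits(fid, "fid")) stop("fid must be a fid object")
  if (line_broadening < 0) stop("line_broadening must be >= 0")
  if (line_broadening == 0) return(fid)
  t <- time_axis(fid$acq, length(fid$samples))
  new_fid(fid$samples * exp(-pi * line_broadening * t), fid$acq)
}

fftshift <- function(x) {
  n <- length(x)
  h <- n %/% 2
  c(x[(h + 1):n], x[1:h])
}

#' Fourier transform a FID into a spectrum
#'
#' Computes the complex spectrum scaled as a discrete approximation of the
#' continuous one-sided Fourier integral (`dt * FFT`), with the conventional
#' halving of the first time-domain point so that the truncation-induced
#' baseline offset vanishes. With this scaling the absorption-mode area of a
#' line simulated by [simulate_fid()] equals the requested `area` exactly
#' (a discrete Fourier identity, independent of truncation).
#'
#' @param fid A `fid` object.
#' @param zero_fill_factor Integer `>= 1`; the FID is zero-padded to
#'   `zero_fill_factor` times its length before transformation.
#' @param halve_first Halve the first point (default TRUE). Disable only for
#'   energy-conservation checks against the raw FID.
#' @return An `nmr_spectrum` with ppm axis decreasing left-to-right, spanning
#'   `carrier_offset +/- (spectral_width/2)/spectrometer_frequency`.
#' @export
fourier_transform <- function(fid, zero_fill_factor = 1, halve_first = TRUE) {
  if (!inherits(fid, "fid")) stop("fid must be a fid object")
  n0 <- length(fid$samples)
  if (n0 < 1) stop("empty FID")
  if (zero_fill_factor < 1 || zero_fill_factor != round(zero_fill_factor)) {
    stop("zero_fill_factor must be a positive integer")
  }
  x <- fid$samples
  if (halve_first) x[1] <- x[1] / 2
  n <- n0 * zero_fill_factor
  if (n > n0) x <- c(x, complex(real = rep(0, n - n0)))
  dt <- dwell_time(fid$acq)
  s <- fftshift(stats::fft(x)) * dt
  freq <- (seq_len(n) - 1 - n %/% 2) * fid$acq$spectral_width / n
  ppm <- hz_to_ppm(freq, fid$acq)
  # ppm axis decreasing left-to-right (high field to the right)
  new_spectrum(rev(ppm), rev(s), fid$acq)
}

#' Apply zeroth- and first-order phase correction
#'
#' Multiplies the intensity by `exp(-i * (phi0 + phi1 * f_norm))` where
#' `f_norm` runs linearly from 0 to 1 across the window. `(0, 0)` is the
#' identity.
#'
#' @param spec An `nmr_spectrum`.
#' @param phi0 Zeroth-order phase in radians.
#' @param phi1 First-order phase in radians across the full window.
#' @return A phased `nmr_spectrum`.
#' @export
phase_correct <- function(spec, phi0, phi1 = 0) {
  if (!inherits(spec, "nmr_spectrum")) stop("spec must be an nmr_spectrum")
  n <- length(spec$ppm)
  f_norm <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  new_spectrum(spec$ppm, spec$intensity * exp(-1i * (phi0 + phi1 * f_norm)),
               spec$acq)
}

#' Automatic zeroth-order phase estimation
#'
#' Finds the phase that minimises the squared negative excursions of the real
#' part (a pure absorption line has no negative lobes). A coarse grid search
#' over the full circle is refined with [stats::optimize()].
#'
#' @param spec An `nmr_spectrum` containing at least one resonance.
#' @return The estimated `phi0` in radians, in `(-pi, pi]`.
#' @export
autophase0 <- function(spec) {
  obj <- function(phi) {
    re <- Re(spec$intensity * exp(-1i * phi))
    sum(pmin(re, 0)^2)
  }
  grid <- seq(-pi, pi, length.out = 181)
  vals <- vapply(grid, obj, numeric(1))
  best <- grid[which.min(vals)]
  opt <- stats::optimize(obj, lower = best - 0.05, upper = best + 0.05)
  phi <- opt$minimum
  if (phi > pi) phi <- phi - 2 * pi
  if (phi <= -pi) phi <- phi + 2 * pi
  phi
}

in_any_window <- function(x, windows) {
  hit <- rep(FALSE, length(x))
  for (w in windows) {
    lo <- min(w); hi <- max(w)
    hit <- hit | (x >= lo & x <= hi)
  }
  hit
}

#' Polynomial baseline correction
#'
#' Fits a polynomial (default order 1) to the real part over signal-free
#' regions — everything outside the supplied exclusion windows — and subtracts
#' it from the real part. The imaginary part is left untouched.
#'
#' @param spec An `nmr_spectrum`.
#' @param exclusion_windows List of `c(lo, hi)` ppm intervals marking peak
#'   regions to ignore when estimating the baseline. A single interval may be
#'   given as a length-2 numeric vector.
#' @param order Polynomial order, default 1 (linear).
#' @return A baseline-corrected `nmr_spectrum`.
#' @export
baseline_correct <- function(spec, exclusion_windows = list(), order = 1) {
  if (!inherits(spec, "nmr_spectrum")) stop("spec must be an nmr_spectrum")
  if (is.numeric(exclusion_windows) && length(exclusion_windows) == 2) {
    exclusion_windows <- list(exclusion_windows)
  }
  free <- !in_any_window(spec$ppm, exclusion_windows)
  if (sum(free) < order + 1) {
    stop("no signal-free points available for baseline estimation")
  }
  x <- spec$ppm[free]
  y <- Re(spec$intensity)[free]
  fit <- stats::lm(y ~ stats::poly(x, degree = order, raw = TRUE))
  beta <- stats::coef(fit)
  base <- rep(beta[1], length(spec$ppm))
  for (d in seq_len(order)) base <- base + beta[d + 1] * spec$ppm^d
  new_spectrum(spec$ppm,
               complex(real = Re(spec$intensity) - base,
                       imaginary = Im(spec$intensity)),
               spec$acq)
}

#' Standard processing chain for a simulated or imported FID
#'
#' Apodization, zero-filled Fourier transform, optional phasing and optional
#' baseline correction, with benign defaults for the narrow lines seen in
#' fluoride work (2 Hz broadening, twofold zero fill, linear baseline).
#'
#' @param fid A `fid` object.
#' @param lb Exponential line broadening in Hz.
#' @param zero_fill Zero-filling factor.
#' @param phi0,phi1 Manual phase correction in radians; use `phi0 = "auto"`
#'   for automatic zeroth-order phasing.
#' @param baseline Apply linear baseline correction (default TRUE).
#' @param exclusion_windows Peak regions excluded from baseline estimation;
#'   defaults to the fluoride/fluoroindole region -130 to -115 ppm.
#' @return An `nmr_spectrum`.
#' @export
process_fid <- function(fid, lb = 2, zero_fill = 2, phi0 = 0, phi1 = 0,
                        baseline = TRUE,
                        exclusion_windows = list(c(-130, -115))) {
  spec <- fourier_transform(apodize(fid, lb), zero_fill)
  if (identical(phi0, "auto")) phi0 <- autophase0(spec)
  if (phi0 != 0 || phi1 != 0) spec <- phase_correct(spec, phi0, phi1)
  if (baseline) spec <- baseline_correct(spec, exclusion_windows)
  spec
}
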