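#' Acquisition parameters for a 1D 19F experiment
#'
#' Bundles the spectrometer settings that define the time and chemical-shift
#' axes of a one-dimensional spectrum. Defaults correspond to a routine
#' fluoride survey on an 18.8 T instrument: 45,455 Hz sweep centred on the
#' fluoride region at -120 ppm, 8,192 complex points, 6,400 co-added scans.
#'
#' @param spectral_width Sweep width in Hz.
#' @param n_complex_points Number of complex time-domain points.
#' @param carrier_offset Carrier (transmitter) position in ppm; the centre of
#'   the spectral window.
#' @param spectrometer_frequency 19F basic frequency in MHz. The default
#'   752.75 MHz is the 19F frequency at 18.8 T (800 MHz 1H).
#' @param n_scans Number of co-added transients.
#' @param relaxation_delay Inter-scan delay in seconds.
#' @param temperature Sample temperature in kelvin.
#' @param n_points_interpretation Either `"complex"` (n_complex_points complex
#'   pairs, the default) or `"total-real"` (the stated count is total real
#'   points, i.e. half as many complex pairs). Vendor conventions differ;
#'   both are supported.
#'
#' @return An object of class `acq_params`.
#' @examples
#' acq <- acq_params()
#' dwell_time(acq)
#' acq_duration(acq)
#' @export
acq_params <- function(spectral_width = 45455,
                       n_complex_points = 8192,
                       carrier_offset = -120,
                       spectrometer_frequency = 752.75,
                       n_scans = 6400,
                       relaxation_delay = 0.5,
                       temperature = 298,
                       n_points_interpretation = c("complex", "total-real")) {
  n_points_interpretation <- match.arg(n_points_interpretation)
  if (spectral_width <= 0) stop("spectral_width must be > 0")
  if (n_complex_points < 2) stop("n_complex_points must be >= 2")
  if (n_scans < 1) stop("n_scans must be >= 1")
  if (spectrometer_frequency <= 0) stop("spectrometer_frequency must be > 0")
  if (relaxation_delay < 0) stop("relaxation_delay must be >= 0")
  n_eff <- if (n_points_interpretation == "total-real") {
    as.integer(n_complex_points / 2)
  } else {
    as.integer(n_complex_points)
  }
  structure(
    list(
      spectral_width = spectral_width,
      n_complex_points = n_eff,
      carrier_offset = carrier_offset,
      spectrometer_frequency = spectrometer_frequency,
      n_scans = as.integer(n_scans),
      relaxation_delay = relaxation_delay,
      temperature = temperature,
      n_points_interpretation = n_points_interpretation
    ),
    class = "acq_params"
  )
}

#' @export
print.acq_params <- function(x, ...) {
  cat("19F acquisition parameters\n")
  cat(sprintf("  spectral width     : %g Hz (%.2f ppm)\n",
              x$spectral_width, x$spectral_width / x$spectrometer_frequency))
  cat(sprintf("  complex points     : %d (aq = %.4f s)\n",
              x$n_complex_points, acq_duration(x)))
  cat(sprintf("  carrier offset     : %.2f ppm\n", x$carrier_offset))
  cat(sprintf("  19F frequency      : %.2f MHz\n", x$spectrometer_frequency))
  cat(sprintf("  scans              : %d\n", x$n_scans))
  cat(sprintf("  relaxation delay   : %g s\n", x$relaxation_delay))
  cat(sprintf("  temperature        : %g K\n", x$temperature))
  invisible(x)
}

#' Dwell time (sampling interval) in seconds
#' @param acq An `acq_params` object.
#' @return Seconds between complex samples, `1/spectral_width`.
#' @export
dwell_time <- function(acq) 1 / acq$spectral_width

#' Acquisition duration in seconds
#' @param acq An `acq_params` object.
#' @return `n_complex_points / spectral_width`.
#' @export
acq_duration <- function(acq) acq$n_complex_points / acq$spectral_width

#' Time axis of the FID
#' @param acq An `acq_params` object.
#' @param n Number of points (defaults to `acq$n_complex_points`).
#' @return Vector of sample times in seconds starting at 0.
#' @export
time_axis <- function(acq, n = acq$n_complex_points) {
  (seq_len(n) - 1) * dwell_time(acq)
}

#' Chemical-shift window covered by the acquisition
#' @param acq An `acq_params` object.
#' @return `c(low, high)` ppm bounds of the spectral window,
#'   `carrier_offset +/- (spectral_width/2)/spectrometer_frequency`.
#' @export
ppm_window <- function(acq) {
  half <- (acq$spectral_width / 2) / acq$spectrometer_frequency
  c(acq$carrier_offset - half, acq$carrier_offset + half)
}

#' Convert chemical shift to offset frequency
#'
#' Offset from the carrier in Hz: `(delta - carrier) * spectrometer_frequency`.
#' @param ppm Chemical shift(s) in ppm.
#' @param acq An `acq_params` object.
#' @return Frequency offset(s) in Hz.
#' @export
ppm_to_hz <- function(ppm, acq) {
  (ppm - acq$carrier_offset) * acq$spectrometer_frequency
}

#' Convert offset frequency to chemical shift
#' @param hz Frequency offset(s) from the carrier in Hz.
#' @param acq An `acq_params` object.
#' @return Chemical shift(s) in ppm.
#' @export
hz_to_ppm <- function(hz, acq) {
  acq$carrier_offset + hz / acq$spectrometer_frequency
}
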