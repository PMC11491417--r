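#' Free induction decay container
#'
#' A complex time-domain signal together with the acquisition parameters that
#' define its sampling.
#'
#' @param samples Complex vector of time-domain samples.
#' @param acq An [acq_params()] object.
#' @return An object of class `fid`.
#' @export
new_fid <- function(samples, acq) {
  if (!inherits(acq, "acq_params")) stop("acq must be an acq_params object")
  if (length(samples) < 1) stop("FID must contain at least one sample")
  structure(list(samples = as.complex(samples), acq = acq), class = "fid")
}

#' @export
print.fid <- function(x, ...) {
  cat(sprintf("FID: %d complex points, %.4f s, SW %g Hz\n",
              length(x$samples), length(x$samples) / x$acq$spectral_width,
              x$acq$spectral_width))
  invisible(x)
}

#' @export
length.fid <- function(x) length(x$samples)

#' Frequency-domain spectrum container
#'
#' Complex intensities on a chemical-shift axis. The axis is stored in the
#' conventional NMR orientation: ppm strictly decreasing left-to-right, so
#' fluoride (-120 ppm) plots left of 5-fluoroindole (-126 ppm).
#'
#' @param ppm Chemical-shift axis (ppm), strictly decreasing.
#' @param intensity Complex intensities, same length as `ppm`. Units are
#'   signal amplitude per Hz, so that integrating the real part over Hz gives
#'   peak area in the simulator's units.
#' @param acq An [acq_params()] object.
#' @return An object of class `nmr_spectrum`.
#' @export
new_spectrum <- function(ppm, intensity, acq) {
  if (length(ppm) != length(intensity)) {
    stop("ppm axis and intensity must have equal length")
  }
  if (length(ppm) >= 2 && any(diff(ppm) >= 0)) {
    stop("ppm axis must be strictly decreasing")
  }
  if (!inherits(acq, "acq_params")) stop("acq must be an acq_params object")
  structure(list(ppm = ppm, intensity = as.complex(intensity), acq = acq),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("Spectrum: %d points, %.2f to %.2f ppm\n",
              length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)]))
  invisible(x)
}

#' @export
length.nmr_spectrum <- function(x) length(x$ppm)

#' Digital resolution of a spectrum in ppm per point
#' @param spec An `nmr_spectrum`.
#' @return Positive spacing of the ppm axis.
#' @export
ppm_resolution <- function(spec) abs(spec$ppm[1] - spec$ppm[2])

acq_to_header <- function(acq) {
  fields <- c("spectral_width", "n_complex_points", "carrier_offset",
              "spectrometer_frequency", "n_scans", "relaxation_delay",
              "temperature")
  vapply(fields, function(f) {
    sprintf("# %s=%s", f, format(acq[[f]], digits = 15))
  }, character(1))
}

header_to_acq <- function(lines) {
  kv <- sub("^#\\s*", "", lines[grepl("^#", lines)])
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- as.numeric(sub("^[^=]*=", "", kv))
  get <- function(k, default) if (k %in% keys) vals[match(k, keys)] else default
  acq_params(
    spectral_width = get("spectral_width", 45455),
    n_complex_points = get("n_complex_points", 8192),
    carrier_offset = get("carrier_offset", -120),
    spectrometer_frequency = get("spectrometer_frequency", 752.75),
    n_scans = get("n_scans", 6400),
    relaxation_delay = get("relaxation_delay", 0.5),
    temperature = get("temperature", 298)
  )
}

#' Write a FID as tab-separated text
#'
#' Columns `time_s`, `real`, `imag`; acquisition parameters are carried in
#' `# key=value` header comments so the file round-trips.
#'
#' @param fid A `fid` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fid_tsv <- function(fid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(acq_to_header(fid$acq), con)
  writeLines("time_s\treal\timag", con)
  t <- time_axis(fid$acq, length(fid$samples))
  utils::write.table(
    data.frame(time_s = t, real = Re(fid$samples), imag = Im(fid$samples)),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a FID written by [write_fid_tsv()]
#' @param path Input path.
#' @return A `fid` object.
#' @export
read_fid_tsv <- function(path) {
  lines <- readLines(path)
  acq <- header_to_acq(lines)
  body <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  acq$n_complex_points <- nrow(body)
  new_fid(complex(real = body$real, imaginary = body$imag), acq)
}

#' Write a spectrum as tab-separated text
#'
#' Columns `ppm`, `real`, `imag` with acquisition metadata in `# key=value`
#' header comments.
#'
#' @param spec An `nmr_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(acq_to_header(spec$acq), con)
  writeLines("ppm\treal\timag", con)
  utils::write.table(
    data.frame(ppm = spec$ppm, real = Re(spec$intensity),
               imag = Im(spec$intensity)),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a spectrum written by [write_spectrum_tsv()]
#' @param path Input path.
#' @return An `nmr_spectrum`.
#' @export
read_spectrum_tsv <- function(path) {
  lines <- readLines(path)
  acq <- header_to_acq(lines)
  body <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  new_spectrum(body$ppm, complex(real = body$real, imaginary = body$imag), acq)
}
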