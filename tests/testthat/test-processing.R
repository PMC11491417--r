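test_that("apodization follows the exponential window contract", {
  acq <- acq_params(spectral_width = 10, n_complex_points = 16)
  unit <- new_fid(rep(1 + 0i, 16), acq)
  expect_identical(apodize(unit, 0)$samples, unit$samples)
  # at t = 1 s the window is exp(-pi * lb)
  ap <- apodize(unit, 1)
  i1 <- which(time_axis(acq, 16) == 1)
  expect_equal(Re(ap$samples[i1]), exp(-pi))
  expect_error(apodize(unit, -1), "line_broadening")
})

test_that("line broadening adds to the Lorentzian width", {
  # convolution closed form: fwhm w processed with lb fits as w + lb
  spec <- clean_spectrum(center = -121, area = 10, fwhm = 8, lb = 4)
  fit <- fit_lorentzian(spec, -121, 1)
  expect_equal(fit$fwhm, 12, tolerance = 0.02)
})

test_that("the Fourier transform places peaks and conserves energy", {
  acq <- default_acq()
  # all-zero in, all-zero out
  z <- fourier_transform(new_fid(rep(0 + 0i, 128),
                                 acq_params(n_complex_points = 128)), 1)
  expect_true(all(z$intensity == 0))
  # on-resonance decay peaks exactly at the -120.00 ppm carrier bin
  sp <- clean_spectrum(center = -120, area = 5, fwhm = 6, zero_fill = 1)
  expect_equal(sp$ppm[which.max(Re(sp$intensity))], -120)
  # Parseval: time-domain energy equals frequency-domain energy
  fid <- simulate_fid(peak_spec(-122, 3, 5), acq, noise_model(0))
  spec <- fourier_transform(fid, 1, halve_first = FALSE)
  e_time <- sum(Mod(fid$samples)^2) * dwell_time(acq)
  e_freq <- sum(Mod(spec$intensity)^2) *
    ppm_resolution(spec) * acq$spectrometer_frequency
  expect_equal(e_freq, e_time, tolerance = 1e-9)
})

test_that("the ppm axis runs downfield to upfield and spans the window", {
  sp <- clean_spectrum()
  expect_true(all(diff(sp$ppm) < 0))
  w <- ppm_window(default_acq())
  expect_equal(max(sp$ppm), w[2], tolerance = 1e-3)
  expect_equal(min(sp$ppm), w[1], tolerance = 1e-3)
  # fluoride region (-120) sits left of (higher index than) -126
  expect_lt(which(abs(sp$ppm + 120) < 0.01)[1],
            which(abs(sp$ppm + 126) < 0.01)[1])
})

test_that("zero filling interpolates without changing the analytic area", {
  acq <- default_acq()
  fid <- apodize(simulate_fid(peak_spec(-120.5, 20, 10), acq, noise_model(0)), 2)
  a1 <- fit_lorentzian(fourier_transform(fid, 1), -120.5, 1)$area
  a4 <- fit_lorentzian(fourier_transform(fid, 4), -120.5, 1)$area
  expect_lt(abs(a4 - a1) / a1, 0.005)
  expect_length(fourier_transform(fid, 4), 4 * 8192)
})

test_that("phase correction is invertible and (0,0) is the identity", {
  sp <- clean_spectrum()
  same <- phase_correct(sp, 0, 0)
  expect_equal(same$intensity, sp$intensity)
  acq <- default_acq()
  # simulate with phase pi/2, correct by pi/2 -> pure absorption
  fid <- simulate_fid(peak_spec(-120.5, 10, 10, phase = pi / 2), acq,
                      noise_model(0))
  spec <- phase_correct(fourier_transform(fid, 2), pi / 2)
  # pure absorption: the full-window imaginary integral vanishes exactly
  # (discrete Fourier identity) while the real integral carries the area
  dnu <- ppm_resolution(spec) * acq$spectrometer_frequency
  imag_area <- sum(Im(spec$intensity)) * dnu
  real_area <- sum(Re(spec$intensity)) * dnu
  expect_equal(real_area, 10, tolerance = 1e-9)
  expect_lt(abs(imag_area), 1e-9 * real_area)
})

test_that("automatic zeroth-order phasing recovers a random phase", {
  acq <- default_acq()
  set.seed(7)
  for (true_phase in runif(4, -2.5, 2.5)) {
    fid <- simulate_fid(peak_spec(-120.5, 10, 10, phase = true_phase), acq,
                        noise_model(0))
    spec <- fourier_transform(fid, 2)
    est <- autophase0(spec)
    # grid-search oracle: brute force over a fine grid, same objective
    neg_area <- function(phi) {
      re <- Re(spec$intensity * exp(-1i * phi))
      sum(pmin(re, 0)^2)
    }
    grid <- seq(-pi, pi, length.out = 6284)
    oracle <- grid[which.min(vapply(grid, neg_area, numeric(1)))]
    expect_equal(est, true_phase, tolerance = 0.02)
    expect_equal(est, oracle, tolerance = 0.005)
  }
})

test_that("baseline correction removes constant offsets and linear tilts", {
  sp <- clean_spectrum(center = -120, area = 20, fwhm = 10, lb = 2)
  excl <- list(c(-130, -115))
  # flat zero baseline: unchanged up to a sliver of the peak height
  flat <- baseline_correct(sp, excl)
  h <- max(Re(sp$intensity))
  expect_lt(max(abs(Re(flat$intensity) - Re(sp$intensity))), 1e-5 * h)
  # constant offset removed
  off <- new_spectrum(sp$ppm, sp$intensity + 0.5, sp$acq)
  corr <- baseline_correct(off, excl)
  sel <- sp$ppm > -100
  expect_lt(max(abs(Re(corr$intensity)[sel] - Re(sp$intensity)[sel])), 1e-6)
  # linear tilt: peak area recovered within 1% of the tilt-free area
  tilt <- new_spectrum(sp$ppm, sp$intensity + (0.02 * (sp$ppm + 120)), sp$acq)
  corr2 <- baseline_correct(tilt, excl)
  a_ref <- fit_lorentzian(sp, -120, 1)$area
  a_corr <- fit_lorentzian(corr2, -120, 1)$area
  expect_equal(a_corr, a_ref, tolerance = 0.01)
  # no free points -> error
  expect_error(baseline_correct(sp, list(range(sp$ppm))), "signal-free")
})

test_that("noiseless lineshape parameters are recovered from the spectrum", {
  # simulation inputs reappear in the fit: center to a fraction of the
  # digital resolution, width to 2%, area to 0.5%
  spec <- clean_spectrum(center = -120.5, area = 20, fwhm = 10, lb = 0)
  fit <- fit_lorentzian(spec, -120.5, 1)
  expect_lt(abs(fit$center + 120.5), 0.2 * ppm_resolution(spec))
  expect_equal(fit$fwhm, 10, tolerance = 0.02)
  expect_equal(fit$area, 20, tolerance = 0.005)
})

test_that("FID and spectrum TSV round trips preserve data and metadata", {
  acq <- acq_params(n_complex_points = 64, n_scans = 16)
  fid <- simulate_fid(peak_spec(-120.2, 3, 40), acq, noise_model(5, seed = 1))
  fp <- tempfile(fileext = ".tsv")
  write_fid_tsv(fid, fp)
  fid2 <- read_fid_tsv(fp)
  expect_equal(fid2$samples, fid$samples, tolerance = 1e-12)
  expect_equal(fid2$acq$spectral_width, acq$spectral_width)
  expect_equal(fid2$acq$n_scans, acq$n_scans)

  spec <- fourier_transform(fid, 2)
  sp <- tempfile(fileext = ".tsv")
  write_spectrum_tsv(spec, sp)
  spec2 <- read_spectrum_tsv(sp)
  expect_equal(spec2$ppm, spec$ppm, tolerance = 1e-12)
  expect_equal(spec2$intensity, spec$intensity, tolerance = 1e-12)
})
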