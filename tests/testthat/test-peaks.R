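test_that("noise estimation matches a known Gaussian noise level", {
  acq <- default_acq()
  # all-zero spectrum -> sd 0
  zero <- fourier_transform(new_fid(rep(0 + 0i, 1024),
                                    acq_params(n_complex_points = 1024)), 1)
  expect_equal(estimate_noise(zero, c(-125, -115))$sd, 0)
  # known-distribution oracle: white noise of sd sigma on a plain axis
  set.seed(11)
  n <- 4096
  ppm <- seq(-90, -150, length.out = n)
  for (sigma in c(0.5, 2)) {
    sp <- new_spectrum(ppm, complex(real = rnorm(n, 0, sigma)), acq)
    est <- estimate_noise(sp, c(-110, -100))  # ~680 points
    expect_equal(est$sd, sigma, tolerance = 0.1)
  }
  # noiseless peak, far-side region: essentially zero
  sp <- fluoride_spectrum(20, seed = 1, fwhm = 12, lb = 2)
  clean <- process_fid(simulate_fid(peak_spec(-120, 20, 12), acq,
                                    noise_model(0)), lb = 2)
  h <- max(Re(clean$intensity))
  expect_lt(estimate_noise(clean, c(-100, -95))$sd, 1e-6 * h)
  # a peak inside the region is refused
  expect_error(estimate_noise(clean, c(-121, -119)), "signal")
})

test_that("a single strong line is detected at its position", {
  sp <- fluoride_spectrum(20, seed = 3)
  pk <- detect_peaks(sp, 3)
  expect_gte(length(pk), 1)
  expect_equal(as.numeric(pk[1]), -120, tolerance = ppm_resolution(sp))
})

test_that("the two-line sample resolves fluoride and 5-fluoroindole", {
  acq <- default_acq()
  fid <- simulate_fid(list(peak_spec(-120, 20, 3), peak_spec(-126, 20, 3)),
                      acq, noise_model(1700, 5))
  sp <- process_fid(fid)
  # strongest two detections sit at -120 and -126 within 0.05 ppm
  pk3 <- as.numeric(detect_peaks(sp, 3))
  expect_gte(length(pk3), 2)
  expect_equal(sort(pk3[1:2]), c(-126, -120), tolerance = 0.05 / 126)
  # at a conservative threshold the survey region holds exactly these two
  pk5 <- as.numeric(detect_peaks(sp, 5))
  expect_length(pk5, 2)
  expect_equal(sort(pk5), c(-126, -120), tolerance = 0.05 / 126)
})

test_that("blank spectra stay quiet at a conservative threshold", {
  # order statistics: 3-sigma excursions are expected among ~16k points,
  # 5-sigma ones are not
  n_fp3 <- 0
  for (s in 1:25) {
    bl <- fluoride_spectrum(0, seed = 200 + s)
    nz <- estimate_noise(bl, c(-105, -95))
    expect_length(detect_peaks(bl, 5, noise = nz), 0)
    n_fp3 <- n_fp3 + length(detect_peaks(bl, 3, noise = nz))
  }
  # threshold 3 false positives appear at a noise-level rate, not in bulk
  expect_lt(n_fp3 / 25, 20)
})

test_that("Lorentzian fitting is self-consistent on clean lines", {
  # exact synthetic lineshape (A = 1, w = 3 Hz, d0 = -120): machine recovery
  acq <- default_acq()
  ppm <- seq(-110, -130, length.out = 4001)
  w_ppm <- 3 / acq$spectrometer_frequency
  y <- (2 * (1 / acq$spectrometer_frequency) / pi) * w_ppm /
    (4 * (ppm + 120)^2 + w_ppm^2)
  spec <- new_spectrum(ppm, complex(real = y), acq)
  fit <- fit_lorentzian(spec, -120, 1)
  expect_equal(fit$area, 1, tolerance = 1e-6)
  expect_equal(fit$fwhm, 3, tolerance = 1e-6)
  expect_equal(fit$center, -120, tolerance = 1e-9)
  expect_false(fit$width_at_bound)
  expect_lt(fit$rss, 1e-16)
  # through the transform, a fully decayed line comes back as cleanly
  sp2 <- clean_spectrum(center = -120, area = 1, fwhm = 10, lb = 2)
  fit2 <- fit_lorentzian(sp2, -120, 1)
  expect_equal(fit2$area, 1, tolerance = 1e-3)
  expect_equal(fit2$center, -120, tolerance = 1e-5)
})

test_that("windowed areas follow the closed-form arctan fraction", {
  # a +/- m*fwhm window holds (2/pi) * atan(2m) of a Lorentzian's area
  spec <- clean_spectrum(center = -120.5, area = 1, fwhm = 10, lb = 0)
  fit <- fit_lorentzian(spec, -120.5, 1)
  w_ppm <- fit$fwhm / spec$acq$spectrometer_frequency
  num10 <- integrate_peak(fit, "numeric", spec,
                          fit$center + c(-10, 10) * w_ppm)
  expect_equal(num10$area, (2 / pi) * atan(20), tolerance = 0.01)
  # numeric and analytic agree within 5% once the window reaches +/-20 fwhm
  num20 <- integrate_peak(fit, "numeric", spec,
                          fit$center + c(-20, 20) * w_ppm)
  expect_lt(abs(num20$area - fit$area) / fit$area, 0.05)
  expect_error(integrate_peak(fit, "numeric"), "requires")
})

test_that("joint fitting separates the fluoride and fluoroindole lines", {
  # fully decayed 10 Hz lines at quartered noise: residual error then
  # reflects the joint fit itself, not truncation wobble or noise scatter
  acq <- default_acq()
  fid <- simulate_fid(list(peak_spec(-120, 20, 10), peak_spec(-126, 12, 10)),
                      acq, noise_model(400, 9))
  sp <- process_fid(fid)
  fits <- fit_lorentzians(sp, c(-120, -126), window = 1)
  expect_equal(fits[[1]]$area, 20, tolerance = 0.02)
  expect_equal(fits[[2]]$area, 12, tolerance = 0.02)
  expect_equal(fits[[1]]$center, -120, tolerance = 1e-4)
  expect_equal(fits[[2]]$center, -126, tolerance = 1e-4)
})

test_that("area normalisation rescales without distorting the line", {
  expect_equal(normalise_area(5, 5), 1)
  expect_equal(normalise_area(0, 3), 0)
  expect_error(normalise_area(1, 0), "reference_area")
  # scale invariance: intercept/slope ratio of a line is unchanged
  x <- c(1, 5, 20, 60, 100)
  y <- 0.8 * x + 3
  yn <- normalise_area(y, max(y))
  f_raw <- stats::lm(y ~ x)
  f_norm <- stats::lm(yn ~ x)
  expect_equal(coef(f_norm)[[1]] / coef(f_norm)[[2]],
               coef(f_raw)[[1]] / coef(f_raw)[[2]], tolerance = 1e-10)
})

test_that("fit residual variance tracks the spectral noise variance", {
  sp <- fluoride_spectrum(20, seed = 77)
  nz <- estimate_noise(sp, c(-105, -95))
  fit <- fit_lorentzian(sp, -120, 1)
  ratio <- (fit$rss / (fit$n_points - 4)) / nz$sd^2
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})
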