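# shared fixtures, built in code at test time

default_acq <- function() acq_params()

# noiseless single-line spectrum; wide lines (>= 10 Hz) decay fully within
# the 0.18 s acquisition, so lineshapes are clean Lorentzians
clean_spectrum <- function(center = -120.5, area = 20, fwhm = 10,
                           lb = 0, zero_fill = 2, acq = default_acq()) {
  fid <- simulate_fid(peak_spec(center, area, fwhm), acq, noise_model(0))
  if (lb > 0) fid <- apodize(fid, lb)
  fourier_transform(fid, zero_fill)
}

# processed noisy spectrum of a fluoride sample at `conc` uM
fluoride_spectrum <- function(conc, seed, fwhm = 3, center = -120,
                              lb = 2, zero_fill = 2, acq = default_acq()) {
  peaks <- if (conc > 0) list(peak_spec(center, conc, fwhm)) else list()
  process_fid(simulate_fid(peaks, acq, noise_model(1700, seed)),
              lb = lb, zero_fill = zero_fill)
}

# one full quantification replicate: 7 log-spaced standards 1-100 uM plus an
# unknown at true_conc, all at default acquisition and noise
quantify_replicate <- function(true_conc, seed, acq = default_acq()) {
  cal <- simulate_calibration_series(default_standards(), acq = acq,
                                     noise = noise_model(1700, seed))
  unk <- fluoride_spectrum(true_conc, seed + 500, acq = acq)
  quantify_unknown(cal, unk)
}

fig4_truth <- function() leaching_model(A = 31, B = 0.6, C = 0.4,
                                        k1 = 0.5, k2 = 0.05)
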