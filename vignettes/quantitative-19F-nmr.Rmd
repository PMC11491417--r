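---
title: "Quantifying micromolar fluoride by 19F NMR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying micromolar fluoride by 19F NMR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorquant)
```

## The problem

Fluorine-19 NMR is prized for its clean background: almost nothing in a
biological sample contains fluorine, so any ^19^F resonance should belong to
the probe compound. That assumption fails in new borosilicate glass NMR
tubes, which leach free fluoride into aqueous samples at micromolar levels
over hours to days. The leached ion resonates near −120 ppm — squarely in
the window used for common probes such as 5-fluoroindole (−126 ppm) — and
binds proteins, so it is both a spectral and a biochemical confounder.

`fluorquant` implements the complete quantitative chain for this problem:
simulating realistic ^19^F spectra, processing them, fitting Lorentzian
lines, calibrating peak areas against sodium fluoride standards, inverting
the calibration with prediction intervals, certifying non-detections with a
limit of detection, fitting bi-exponential leaching kinetics, and measuring
chemical shift perturbations upon protein binding. Because the package's
tests run against synthetic data, the simulator is first-class, tested code
rather than a fixture.

## The forward model

A free induction decay (FID) is modelled as a sum of decaying complex
exponentials sampled at the dwell time $\Delta t = 1/\mathrm{SW}$:

$$
s(t_k) \;=\; \sum_j 2 a_j \,
  e^{\,(2\pi i \nu_j - \pi w_j)\, t_k + i\phi_j} \;+\; \varepsilon_k ,
$$

where $\nu_j = (\delta_j - \delta_\mathrm{carrier}) \cdot f_0$ is the offset
frequency in Hz ($f_0$ the ^19^F frequency in MHz), $w_j$ the full width at
half maximum in Hz (so $T_2^* = 1/\pi w_j$), and $\varepsilon_k$ circular
complex Gaussian noise. Default acquisition settings describe a routine
fluoride survey at 18.8 T: 45,455 Hz sweep, 8,192 complex points, carrier at
−120.00 ppm, 6,400 scans, 0.5 s relaxation delay. The ^19^F basic frequency
752.75 MHz follows from the 800 MHz ^1^H frequency and the gyromagnetic
ratio of ^19^F.

Two conventions deserve explanation:

* **Amplitude.** The spectrum is computed as $\Delta t \cdot
  \mathrm{FFT}(s)$ with the first point halved — the standard one-sided
  discrete transform convention that removes the truncation baseline
  offset. Under that convention the full-window integral of the real part
  equals exactly half the $t=0$ amplitude (a discrete Fourier identity that
  holds regardless of truncation), so a time-domain amplitude of $2a$ makes
  the absorption-mode area of the line exactly $a$. Numeric integration of
  a simulated spectrum therefore recovers the requested area to machine
  precision, which anchors the unit system end to end.
* **Noise.** `simulate_fid()` returns the scan-averaged FID: the coherent
  signal is unchanged while the per-point noise SD is
  $\sigma_\mathrm{scan}/\sqrt{n_\mathrm{scans}}$. Spectral SNR consequently
  grows as $\sqrt{n_\mathrm{scans}}$, the usual signal-averaging contract.
  The default $\sigma_\mathrm{scan} = 1700$ (with a response of one area
  unit per µM) was chosen once so that a 20 µM fluoride line (3 Hz wide,
  processed with 2 Hz broadening) lands at SNR ≈ 100 after 6,400 scans —
  the look of a clean survey spectrum.

An ambiguity worth noting: vendor conventions disagree on whether a stated
point count means complex pairs or total real points (the two differ by a
factor of two in acquisition time). `acq_params()` exposes both readings
through `n_points_interpretation`; the default takes the count as complex
pairs and derives the acquisition time as
$n_\mathrm{points}/\mathrm{SW} \approx 0.18$ s.

## Processing

`process_fid()` chains exponential apodization (default 2 Hz), zero-filled
Fourier transform (default factor 2), optional phasing and a linear
baseline correction estimated from signal-free regions. These defaults are
deliberately benign at the linewidths involved; all are configurable
because real studies rarely publish their processing parameters.
Zeroth-order autophasing minimises the squared negative excursions of the
real part — a pure absorption line has no negative lobes — by coarse grid
search plus local refinement, and recovers simulated phases to better than
0.02 rad.

One numerical effect matters at these settings. With a 0.18 s acquisition,
a 3 Hz line retains about 6% of its amplitude when the FID is truncated;
the resulting sinc interference can bias a single spectrum's fitted area by
up to ~2% depending on where the line falls on the frequency grid.
Quantification is insensitive to this because standards and unknowns share
the −120 ppm position, so the bias divides out of the calibration ratio.
Tests that probe fitting accuracy itself use fully decayed (≥ 10 Hz) lines
where the effect is negligible.

## Peak detection and Lorentzian fitting

Detection picks local maxima of the real part above `snr_threshold` times a
robust noise SD (1.4826 × MAD over a signal-free region). Both neighbours
of a candidate must clear half the height threshold, which suppresses
single-bin noise spikes. At the default threshold of 3, order statistics
still guarantee occasional false positives among ~16k points — roughly a
handful per blank spectrum — which is why counting applications and the
CSP module use thresholds of 5 and 4 respectively.

Fitted lineshapes are Lorentzians,

$$
L(\delta) = \frac{2A}{\pi} \cdot
  \frac{w}{4(\delta - \delta_0)^2 + w^2} + b ,
$$

parameterised so that the full-line integral of $L - b$ is exactly $A$;
widths are bounded above by 0.2 ppm (~150 Hz, far beyond any liquid-state
^19^F line here) to stop low-SNR fits from degenerating into a broad
pseudo-baseline. The analytic fitted area is the default quantification
integral because it is robust to window truncation: a window of half-width
$m$ linewidths captures only $(2/\pi)\arctan(2m)$ of a Lorentzian's area
(96.8% at $m = 10$), so numeric windowed integrals systematically undershoot.
Numeric integration is retained as an option and as a cross-check.

## Calibration and inverse prediction

Standards (default: seven concentrations log-spaced over 1–100 µM,
emulating sodium fluoride in buffer measured in quartz) are fit by ordinary
least squares of normalised area on concentration. Normalising by the top
standard maps it to 1 and makes the scale irrelevant; the choice of
reference is configuration, not substance, since the intercept/slope ratio
is scale-invariant.

An unknown with mean area $\bar y$ over $m$ replicates is estimated as
$\hat x = (\bar y - b_0)/b_1$ with the classical inverse-prediction interval

$$
\hat x \;\pm\; t_{1-\alpha/2,\,n-2}\,\frac{s}{|b_1|}
 \sqrt{\frac{1}{m} + \frac{1}{n} +
       \frac{(\hat x - \bar x)^2}{S_{xx}}} .
$$

A Fieller construction is available behind `method = "fieller"` for slopes
near zero; at the steep slopes of a working calibration the two coincide.
The slope must differ from zero at the stated confidence or the inversion
refuses to report an interval. The intercept is estimated rather than
forced through the origin, since leached blanks may carry a real offset; a
through-origin analysis can be emulated by supplying a zero standard.
Monte-Carlo checks in the test suite confirm 95% intervals cover the truth
in 93–97% of 1,000 draws at the area noise the pipeline produces.

## Limit of detection

Non-detections are certified with a 3σ rule referenced to the calibration
slope: the LOD is the concentration whose expected area equals three times
the standard error of a noise-only numeric integration over a
±2-linewidth window,

$$
\mathrm{LOD} = \frac{3\,\sigma_\mathrm{noise}\sqrt{n_\mathrm{pts}}\,
  \Delta\nu}{b_1 \cdot A_\mathrm{ref}} .
$$

Under the default acquisition and noise model this evaluates to ≈ 0.6 µM,
below the 1 µM threshold used to certify rinsed tubes as clean, and it
scales linearly in the noise SD.

## Leaching kinetics

Fluoride release from glass follows a bi-exponential rise to plateau,

$$
[\mathrm{F}^-](t) = A\left(1 - B e^{-k_1 t} - C e^{-k_2 t}\right),
$$

with plateau $A$, amplitudes $B, C$ and rates $k_1 \ge k_2$ (the canonical
ordering; swapping $(B,k_1)$ with $(C,k_2)$ leaves the curve unchanged, so
ordering makes reported parameters unique). $B + C = 1$ — zero
concentration at filling — is *not* imposed by default: sampling typically
starts up to an hour after filling, so the extrapolated $t=0$ value is
reported rather than assumed. A `constrain_origin` flag provides the
anchored fit.

Bi-exponential least squares is multimodal, so `fit_leaching()` uses a
seeded multi-start protocol (default 20 starts): rate pairs drawn from a
log grid over $[1/t_\max,\, 10/t_\min]$, amplitudes initialised by a linear
solve at fixed rates (the model is linear in $A$, $AB$, $AC$), and the
best-RSS converged solution returned. Nearly degenerate rate pairs
($k_1/k_2 < 1.2$) are flagged and a nested mono-exponential comparison
(BIC) is always attached. On noiseless data the fit is a fixed point of its
own predictions to 10⁻⁶; at 5% proportional noise on 92 hourly points, the
plateau is recovered within 10% in well over 90% of seeds.

## Chemical shift perturbation

`compute_csp()` fits the single line inside a search window in a free and a
bound spectrum and reports the signed difference (positive = downfield
shift of the bound form) with the propagated standard error; a shift
exceeding three combined SEs is flagged as significant. Center standard
errors are tiny at survey SNR (~10⁻⁴–10⁻⁵ ppm at SNR ≈ 100), so the
significance machinery only becomes discriminating at low SNR; at 2.5 µM a
0.01 ppm shift is flagged essentially always while a 0.001 ppm shift
usually is not, and the test suite checks exactly that contrast. The
empirical scatter of fitted centers matches the reported SEs at these
settings, which is what makes the 3σ rule meaningful.

## What the generator does and does not emulate

The simulator reproduces the statistical structure the analysis relies on:
Lorentzian lines at the correct offsets, concentration-proportional areas,
scan-averaged white complex noise, truncation effects of the finite
acquisition, and bi-exponential time courses with absolute or proportional
noise floored at zero. It deliberately omits J-coupling multiplets,
chemical exchange broadening, field inhomogeneity, solvent artifacts and
acoustic ringing (single Lorentzian lines only), and it trusts the carrier
for referencing rather than modelling lock-based indirect referencing.
Passing tests therefore demonstrate correctness of the analysis chain under
the stated noise model — not robustness to every pathology of real spectra.
Time courses are generated on exact hourly grids by default; an optional
±5 min uniform jitter emulates "approximately hourly" sampling.

## Problem sizes and reproducibility

The tests and the acceptance script size their Monte-Carlo loops to what
the statistics require rather than more: 50 replicates per tube type for
end-to-end quantification (each replicate simulating seven standards and
one unknown), 50 replicates for plateau recovery, 1,000 area-level draws
for interval coverage, and 20–25 seeds for detection and power checks.
Every stochastic operation takes an explicit seed, and `run_pipeline()`
derives fixed per-stage seeds from a single configuration seed, so
identical configurations produce byte-identical artifacts.

## Known limitations

* Calibration is unweighted; strong heteroscedasticity across the standard
  range would call for weighted least squares, which is out of scope.
* Overlap resolution is limited to joint fitting of a small number of
  Lorentzians; heavily overlapped multiplets are not deconvolved.
* Temperature enters only through separately fitted conditions; no
  Arrhenius model links rates across temperatures.
* The LOD rule is the conventional 3σ slope-referenced form; it certifies
  "below X µM" statements but is not a full detection-decision theory.
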