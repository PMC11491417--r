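#' Chemical shift perturbation of the fluoride resonance
#'
#' Fits a Lorentzian to the single peak inside `search_window` in each of a
#' free (ligand alone) and bound (protein-containing) spectrum and returns
#' the signed shift difference with propagated uncertainty. Sign convention:
#' positive CSP means the bound resonance lies at higher ppm (downfield) than
#' the free one. A perturbation larger than three combined standard errors is
#' flagged as significant evidence of binding.
#'
#' @param free_spec,bound_spec `nmr_spectrum` objects, phased.
#' @param search_window `c(lo, hi)` ppm interval expected to contain exactly
#'   one peak in each spectrum (default the fluoride region -121 to -119).
#' @param snr_threshold Detection threshold passed to [detect_peaks()];
#'   default 5 rather than the general-survey 3, since a shift difference is
#'   only meaningful for a clearly established line and stray 3-sigma noise
#'   excursions inside the search window would otherwise raise spurious
#'   ambiguity errors.
#' @param noise_region Signal-free region for noise estimation.
#' @param fit_window Half-width in ppm of the Lorentzian fit window.
#' @param min_separation Coalescing distance for [detect_peaks()] in ppm;
#'   the 0.2 ppm default absorbs truncation sidelobes of a strong line into
#'   its central maximum.
#' @return An object of class `shift_perturbation`: `delta_free`,
#'   `delta_bound`, `csp` (= bound - free, ppm), `se` (combined standard
#'   error), `significance` (csp / se) and `perturbed` (|csp| > 3 se).
#' @export
compute_csp <- function(free_spec, bound_spec, search_window = c(-121, -119),
                        snr_threshold = 5, noise_region = c(-105, -95),
                        fit_window = 0.5, min_separation = 0.2) {
  fit_one <- function(spec, label) {
    noise <- estimate_noise(spec, noise_region)
    cand <- detect_peaks(spec, snr_threshold, noise = noise,
                         min_separation = min_separation)
    lo <- min(search_window); hi <- max(search_window)
    cand <- cand[cand >= lo & cand <= hi]
    if (length(cand) == 0) {
      stop(sprintf("no peak detected in the %s spectrum within [%.2f, %.2f] ppm",
                   label, lo, hi))
    }
    if (length(cand) > 1) {
      stop(sprintf(
        "ambiguous %s spectrum: %d peaks in [%.2f, %.2f] ppm (at %s ppm)",
        label, length(cand), lo, hi,
        paste(sprintf("%.3f", cand), collapse = ", ")))
    }
    fit_lorentzian(spec, cand[1], window = fit_window)
  }
  ff <- fit_one(free_spec, "free")
  fb <- fit_one(bound_spec, "bound")
  csp <- fb$center - ff$center
  se <- sqrt(ff$se_center^2 + fb$se_center^2)
  structure(
    list(delta_free = ff$center, delta_bound = fb$center, csp = csp,
         se = se, significance = csp / se, perturbed = abs(csp) > 3 * se,
         free_fit = ff, bound_fit = fb),
    class = "shift_perturbation"
  )
}

#' @export
print.shift_perturbation <- function(x, ...) {
  cat(sprintf("CSP: %+.4f ppm (free %.4f, bound %.4f), se %.2g ppm — %s\n",
              x$csp, x$delta_free, x$delta_bound, x$se,
              if (x$perturbed) "significant perturbation" else "not significant"))
  invisible(x)
}
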