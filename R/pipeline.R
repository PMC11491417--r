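#' Default calibration standard concentrations
#'
#' Seven sodium fluoride standards log-spaced over 1-100 uM, the working
#' range used for quantifying tube leachate.
#'
#' @return Numeric vector of concentrations in uM.
#' @export
default_standards <- function() {
  exp(seq(log(1), log(100), length.out = 7))
}

#' Measure the fluoride peak area in a processed spectrum
#'
#' Fits a Lorentzian at the expected fluoride position and returns the
#' analytic (full-line) area, the default quantification integral because it
#' is robust to window truncation.
#'
#' @param spec An `nmr_spectrum`.
#' @param center Expected peak position in ppm (default -120).
#' @param window Fit half-width in ppm.
#' @return A `peak_fit` object.
#' @export
measure_fluoride_peak <- function(spec, center = -120, window = 1.0) {
  fit_lorentzian(spec, center, window)
}

#' End-to-end quantification of an unknown against a standards series
#'
#' Fits the fluoride line in every standard spectrum and in the unknown,
#' normalises all areas by the top-standard area (which then maps to 1),
#' fits the calibration line and inverts it with a prediction interval.
#'
#' @param cal_series A [simulate_calibration_series()] result, or any list
#'   with elements `concentration` and `spectra`.
#' @param unknown_spec Processed `nmr_spectrum` of the unknown sample (or a
#'   list of replicate spectra).
#' @param center Fluoride position in ppm.
#' @param window Fit half-width in ppm.
#' @param confidence Interval coverage (default 0.95).
#' @return A list: `estimate` (a `concentration_estimate`), `calibration`
#'   (a `calibration_fit` on normalised areas), `reference_area` (raw area
#'   of the top standard), `areas` (normalised standard areas) and
#'   `unknown_area` (normalised).
#' @export
quantify_unknown <- function(cal_series, unknown_spec, center = -120,
                             window = 1.0, confidence = 0.95) {
  areas <- vapply(cal_series$spectra, function(s) {
    measure_fluoride_peak(s, center, window)$area
  }, numeric(1))
  ref <- areas[which.max(cal_series$concentration)]
  if (ref <= 0) stop("top-standard area is nonpositive; cannot normalise")
  norm_areas <- normalise_area(areas, ref)
  cal <- fit_calibration(cal_series$concentration, norm_areas)
  if (inherits(unknown_spec, "nmr_spectrum")) unknown_spec <- list(unknown_spec)
  u_areas <- vapply(unknown_spec, function(s) {
    normalise_area(measure_fluoride_peak(s, center, window)$area, ref)
  }, numeric(1))
  est <- invert_calibration(cal, u_areas, confidence = confidence)
  list(estimate = est, calibration = cal, reference_area = ref,
       areas = norm_areas, unknown_area = mean(u_areas))
}

config_defaults <- function() {
  list(
    seed = 1,
    outdir = "fluorquant_run",
    stages = c("simulate", "process", "fit_peaks"),
    acquisition = list(),
    noise = list(sigma_per_scan = 1700),
    simulate = list(peaks = list(list(center = -120, area = 20, fwhm = 3))),
    process = list(lb = 2, zero_fill = 2, phi0 = 0, baseline = TRUE),
    fit_peaks = list(snr_threshold = 3, window = 1.0,
                     noise_region = c(-105, -95)),
    quantify = list(standards = default_standards(), response = 1,
                    confidence = 0.95, center = -120),
    kinetics = list(truth = list(A = 31, B = 0.6, C = 0.4, k1 = 0.5, k2 = 0.05),
                    times = 1:92, sd = 0.05, noise_type = "proportional",
                    n_starts = 20),
    csp = list(free_center = -120, shift = 0.05, area = 20, fwhm = 3,
               window = c(-121, -119))
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Validate and complete a run configuration
#'
#' Fills unspecified fields from the package defaults and checks types and
#' ranges before any computation runs.
#'
#' @param config A named list (e.g. from [read_config()]); may be partial.
#' @return The completed configuration list.
#' @export
validate_config <- function(config = list()) {
  if (!is.list(config)) stop("config must be a list")
  known_stages <- c("simulate", "process", "fit_peaks", "quantify",
                    "kinetics", "csp")
  cfg <- merge_config(config_defaults(), config)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 ||
      cfg$seed != round(cfg$seed)) {
    stop("config error: seed must be a single integer")
  }
  bad <- setdiff(cfg$stages, known_stages)
  if (length(bad) > 0) {
    stop("config error: unknown stage(s): ", paste(bad, collapse = ", "))
  }
  if (!is.character(cfg$outdir) || length(cfg$outdir) != 1) {
    stop("config error: outdir must be a single path")
  }
  if (cfg$noise$sigma_per_scan < 0) {
    stop("config error: sigma_per_scan must be >= 0")
  }
  pk <- cfg$simulate$peaks
  if (is.data.frame(pk)) {
    # a JSON array of peak objects reads back as a data frame
    pk <- lapply(seq_len(nrow(pk)), function(i) as.list(pk[i, ]))
  } else if (is.list(pk) && !is.null(names(pk))) {
    pk <- list(pk)  # single peak given directly
  }
  cfg$simulate$peaks <- pk
  for (p in cfg$simulate$peaks) {
    if (is.null(p$center) || is.null(p$area) || is.null(p$fwhm)) {
      stop("config error: each peak needs center, area and fwhm")
    }
  }
  cfg
}

#' Read a run configuration from JSON
#' @param path Path to a JSON configuration file.
#' @return A completed, validated configuration list.
#' @export
read_config <- function(path) {
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write a run configuration to JSON
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

stage_seeds <- function(seed) {
  # fixed per-stage offsets: every stochastic stage gets its own stream,
  # all derived from the single config seed
  list(simulate = seed + 101L, quantify = seed + 202L,
       kinetics = seed + 303L, csp = seed + 404L)
}

#' Run the configured analysis stages end-to-end
#'
#' Executes the requested stages in order, writing each stage's artifact
#' (TSV/CSV/JSON) plus a manifest recording inputs, parameters and derived
#' seeds. Identical configurations produce identical outputs; all randomness
#' flows from `config$seed`. A stage failure is recorded in the report and
#' later stages that depend on it are skipped, while earlier artifacts are
#' preserved.
#'
#' @param config A configuration list (see [validate_config()]) or a path to
#'   a JSON configuration.
#' @return A run report list: per-stage status, artifact paths and headline
#'   numbers. The manifest is also written to `outdir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- validate_config(config)
  seeds <- stage_seeds(as.integer(cfg$seed))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  acq <- do.call(acq_params, cfg$acquisition)
  report <- list(stages = list(), outdir = cfg$outdir)
  state <- list(fid = NULL, spectrum = NULL)

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[name]] <<- list(status = "failed",
                                     message = conditionMessage(res))
    } else {
      report$stages[[name]] <<- c(list(status = "ok"), res)
    }
  }

  for (stage in cfg$stages) {
    switch(stage,
      simulate = run_stage("simulate", function() {
        peaks <- lapply(cfg$simulate$peaks, function(p) {
          peak_spec(p$center, p$area, p$fwhm,
                    if (is.null(p$phase)) 0 else p$phase)
        })
        nm <- noise_model(cfg$noise$sigma_per_scan, seeds$simulate)
        state$fid <<- simulate_fid(peaks, acq, nm)
        path <- file.path(cfg$outdir, "fid.tsv")
        write_fid_tsv(state$fid, path)
        list(artifact = path, seed = seeds$simulate)
      }),
      process = run_stage("process", function() {
        if (is.null(state$fid)) stop("process stage requires a simulated FID")
        pr <- cfg$process
        state$spectrum <<- process_fid(state$fid, lb = pr$lb,
                                       zero_fill = pr$zero_fill,
                                       phi0 = pr$phi0,
                                       baseline = isTRUE(pr$baseline))
        path <- file.path(cfg$outdir, "spectrum.tsv")
        write_spectrum_tsv(state$spectrum, path)
        list(artifact = path)
      }),
      fit_peaks = run_stage("fit_peaks", function() {
        if (is.null(state$spectrum)) stop("fit_peaks requires a processed spectrum")
        fp <- cfg$fit_peaks
        noise <- estimate_noise(state$spectrum, fp$noise_region)
        centers <- detect_peaks(state$spectrum, fp$snr_threshold, noise = noise)
        fits <- if (length(centers) >= 2 &&
                    min(diff(sort(centers))) < 2 * fp$window) {
          fit_lorentzians(state$spectrum, as.numeric(centers), fp$window)
        } else {
          lapply(as.numeric(centers), function(cc) {
            fit_lorentzian(state$spectrum, cc, fp$window)
          })
        }
        tab <- do.call(rbind, lapply(fits, function(f) {
          data.frame(center_ppm = f$center, area = f$area, fwhm_hz = f$fwhm,
                     se_center = f$se_center, se_area = f$se_area,
                     se_fwhm = f$se_fwhm,
                     snr = if (noise$sd > 0) {
                       2 * f$area / (pi * f$fwhm) / noise$sd
                     } else Inf,
                     width_at_bound = f$width_at_bound)
        }))
        path <- file.path(cfg$outdir, "peaks.csv")
        if (is.null(tab)) {
          tab <- data.frame(center_ppm = numeric(0), area = numeric(0),
                            fwhm_hz = numeric(0), se_center = numeric(0),
                            se_area = numeric(0), se_fwhm = numeric(0),
                            snr = numeric(0), width_at_bound = logical(0))
        }
        utils::write.csv(tab, path, row.names = FALSE)
        list(artifact = path, n_peaks = nrow(tab), noise_sd = noise$sd)
      }),
      quantify = run_stage("quantify", function() {
        if (is.null(state$spectrum)) stop("quantify requires a processed spectrum")
        qf <- cfg$quantify
        cal_series <- simulate_calibration_series(
          as.numeric(qf$standards), response = qf$response, acq = acq,
          noise = noise_model(cfg$noise$sigma_per_scan, seeds$quantify),
          lb = cfg$process$lb, zero_fill = cfg$process$zero_fill
        )
        q <- quantify_unknown(cal_series, state$spectrum, center = qf$center,
                              confidence = qf$confidence)
        out <- list(
          estimate_uM = q$estimate$estimate,
          interval_uM = q$estimate$interval,
          confidence = qf$confidence,
          calibration = list(slope = q$calibration$slope,
                             intercept = q$calibration$intercept,
                             r_squared = q$calibration$r_squared,
                             residual_sd = q$calibration$residual_sd,
                             n = q$calibration$n),
          seed = seeds$quantify
        )
        path <- file.path(cfg$outdir, "quantify.json")
        jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
        c(list(artifact = path), out["estimate_uM"])
      }),
      kinetics = run_stage("kinetics", function() {
        kn <- cfg$kinetics
        tr <- kn$truth
        truth <- leaching_model(tr$A, tr$B, tr$C, tr$k1, tr$k2)
        series <- simulate_leaching_series(truth, as.numeric(kn$times),
                                           sd = kn$sd, seed = seeds$kinetics,
                                           noise_type = kn$noise_type)
        fit <- fit_leaching(series, n_starts = kn$n_starts,
                            seed = seeds$kinetics + 1L)
        m <- fit$model
        out <- list(parameters = list(A = m$A, B = m$B, C = m$C,
                                      k1 = m$k1, k2 = m$k2),
                    se = as.list(fit$se), rss = fit$rss,
                    plateau = m$A, time_to_90pct = time_to_fraction(m, 0.9),
                    seed = seeds$kinetics)
        path <- file.path(cfg$outdir, "kinetics.json")
        jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
        list(artifact = path, plateau = m$A)
      }),
      csp = run_stage("csp", function() {
        cs <- cfg$csp
        nm1 <- noise_model(cfg$noise$sigma_per_scan, seeds$csp)
        nm2 <- noise_model(cfg$noise$sigma_per_scan, seeds$csp + 1L)
        free <- process_fid(simulate_fid(
          peak_spec(cs$free_center, cs$area, cs$fwhm), acq, nm1),
          lb = cfg$process$lb, zero_fill = cfg$process$zero_fill)
        bound <- process_fid(simulate_fid(
          peak_spec(cs$free_center + cs$shift, cs$area, cs$fwhm), acq, nm2),
          lb = cfg$process$lb, zero_fill = cfg$process$zero_fill)
        res <- compute_csp(free, bound, search_window = as.numeric(cs$window))
        out <- list(delta_free = res$delta_free, delta_bound = res$delta_bound,
                    csp_ppm = res$csp, se_ppm = res$se,
                    significant = res$perturbed, seed = seeds$csp)
        path <- file.path(cfg$outdir, "csp.json")
        jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
        list(artifact = path, csp_ppm = res$csp)
      }),
      stop("unknown stage: ", stage)
    )
  }

  manifest <- list(config = cfg, derived_seeds = seeds,
                   package_version = as.character(utils::packageVersion("fluorquant")),
                   stages = lapply(report$stages, function(s) s$status))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$manifest <- file.path(cfg$outdir, "manifest.json")
  report
}
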