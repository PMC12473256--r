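# Scenario configuration, reproducible runs, and run comparison.

#' Build and validate a scenario configuration
#'
#' A scenario bundles everything one simulation run needs: the excitation
#' case, the true-pulse description, the drift, the stack parameters, the
#' TVSP mapping, solver and analysis options, and a seed. Presets
#' reproducing the two canonical analyses are available through
#' [scenario_preset()].
#'
#' @param case `"wall"` (wall displacement excites the 1DOF stack) or
#'   `"pressure"` (pulsatile pressure excites the 2DOF artery-stack system).
#' @param duration simulated length (s), default 12 (12 cycles at 1 Hz).
#' @param fs sampling rate (Hz), default 200.
#' @param pulse list describing the true pulse: `type` (`"harmonic"`,
#'   `"apw"`, or `"file"`), `f_c`, and type-specific fields
#'   (`n_harmonics`, `decay` for harmonic; `centers/widths/heights` for
#'   apw; `path` for file).
#' @param drift list describing the baseline drift (fields of
#'   [drift_spec()]), or `NULL` for an MA-free run.
#' @param params list with `r0, zeta0, k0_over_kA, kA, a` (ratio form).
#' @param gains TVSP gains `(gk, gc, gm)`.
#' @param normalizer TVSP normalizer mode.
#' @param solver list overriding `rtol`, `atol`, `method`.
#' @param analysis list: `discard_cycles` (lead-in cycles dropped before
#'   analysis, default 2), `n_harmonics`, `band`, `zero_pad_factor`,
#'   `window`.
#' @param seed integer seed recorded in every output and used for any
#'   random drift.
#' @return a validated object of class `scenario_config`.
#' @export
scenario_config <- function(case = c("wall", "pressure"),
                            duration = 12, fs = 200,
                            pulse = list(type = "harmonic", f_c = 1,
                                         n_harmonics = 10L, decay = 0.6),
                            drift = list(kind = "harmonic-sum", amplitude = 1),
                            params = list(r0 = 2, zeta0 = 1.5,
                                          k0_over_kA = 1 / 6, kA = 1,
                                          a = 1 / pi),
                            gains = c(-1 / 3, -1 / 3, -1 / 2),
                            normalizer = "max",
                            solver = list(),
                            analysis = list(),
                            seed = 1L) {
  case <- match.arg(case)
  bad <- character(0)
  if (!is.numeric(duration) || duration <= 0) bad <- c(bad, "duration")
  if (!is.numeric(fs) || fs <= 0) bad <- c(bad, "fs")
  if (!is.list(pulse) || is.null(pulse$type) ||
      !pulse$type %in% c("harmonic", "apw", "file")) bad <- c(bad, "pulse$type")
  if (!is.null(drift) && (!is.list(drift) || is.null(drift$kind) ||
      !drift$kind %in% c("harmonic-sum", "random-smooth", "from-samples")))
    bad <- c(bad, "drift$kind")
  for (f in c("r0", "zeta0", "k0_over_kA", "kA"))
    if (is.null(params[[f]]) || !is.numeric(params[[f]]) || params[[f]] <= 0)
      bad <- c(bad, paste0("params$", f))
  if (length(gains) != 3L) bad <- c(bad, "gains")
  if (length(bad))
    stop("invalid scenario config; offending fields: ",
         paste(bad, collapse = ", "), call. = FALSE)
  analysis <- utils::modifyList(
    list(discard_cycles = 2, n_harmonics = 10L, band = 0.35,
         zero_pad_factor = 4L, window = "rectangular"), analysis)
  if (is.null(params$a)) params$a <- 1 / pi
  if (is.null(pulse$f_c)) pulse$f_c <- 1
  structure(list(case = case, duration = duration, fs = fs, pulse = pulse,
                 drift = drift, params = params, gains = as.numeric(gains),
                 normalizer = normalizer, solver = solver,
                 analysis = analysis, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Canonical scenario presets
#'
#' `"wall-default"`: the 10-harmonic pulse at 1 Hz driving the 1DOF stack
#' (r0 = 2, zeta0 = 1.5, k0 = kA/6) with the two-tone 0.2 + 0.35 Hz drift.
#' `"pressure-default"`: the same drift and stack with pulsatile pressure
#' driving the 2DOF artery-stack system.
#'
#' @param name preset name.
#' @param ... overrides forwarded to [scenario_config()].
#' @return a `scenario_config`.
#' @export
scenario_preset <- function(name = c("wall-default", "pressure-default"), ...) {
  name <- match.arg(name)
  base <- list(
    duration = 12, fs = 200,
    pulse = list(type = "harmonic", f_c = 1, n_harmonics = 10L, decay = 0.6),
    drift = list(kind = "harmonic-sum", amplitude = 1),
    params = list(r0 = 2, zeta0 = 1.5, k0_over_kA = 1 / 6, kA = 1, a = 1 / pi))
  base$case <- if (name == "wall-default") "wall" else "pressure"
  do.call(scenario_config, utils::modifyList(base, list(...)))
}

# materialize the pulse / drift / params described by a config
build_scenario_inputs <- function(cfg) {
  p <- cfg$pulse
  pulse <- switch(p$type,
    harmonic = {
      spec <- carotid_harmonic_spec(
        f_c = p$f_c,
        n_harmonics = if (is.null(p$n_harmonics)) 10L else p$n_harmonics,
        decay = if (is.null(p$decay)) 0.6 else p$decay)
      make_harmonic_pulse(spec, cfg$duration, cfg$fs)
    },
    apw = make_synthetic_apw(p$f_c, cfg$duration, cfg$fs,
      centers = if (is.null(p$centers)) c(0.15, 0.45) else p$centers,
      widths = if (is.null(p$widths)) c(0.05, 0.09) else p$widths,
      heights = if (is.null(p$heights)) c(1, 0.4) else p$heights),
    file = read_pulse_csv(p$path))
  drift <- if (is.null(cfg$drift)) NULL else {
    d <- cfg$drift
    spec <- drift_spec(
      kind = d$kind,
      amplitude = if (is.null(d$amplitude)) 1 else d$amplitude,
      band_limit = if (is.null(d$band_limit)) 0.7 else d$band_limit,
      seed = if (is.null(d$seed)) cfg$seed else d$seed,
      components = if (is.null(d$components))
        data.frame(freq = c(0.2, 0.35), amp = c(0.7, 0.3)) else
        as.data.frame(d$components),
      n_knots = if (is.null(d$n_knots)) 8L else d$n_knots,
      path = d$path)
    make_baseline_drift(spec, cfg$duration, cfg$fs)
  }
  pr <- cfg$params
  params <- nominal_params(r0 = pr$r0, zeta0 = pr$zeta0,
                           k0_over_kA = pr$k0_over_kA, f_c = p$f_c,
                           kA = pr$kA)
  artery <- artery_params(kA = pr$kA, a = pr$a)
  list(pulse = pulse, drift = drift, params = params, artery = artery)
}

# write a named set of aligned series as one CSV (time first)
write_series_csv <- function(time, series, path) {
  cols <- c(list(time_s = time), lapply(series, function(s)
    if (inherits(s, "pulse_signal")) s$samples else as.numeric(s)))
  header <- paste(names(cols), collapse = ",")
  rows <- do.call(paste, c(lapply(cols, function(v) sprintf("%.12g", v)),
                           sep = ","))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Run a scenario end to end
#'
#' Materializes the configured inputs, runs the simulation, the
#' equivalent-force decomposition, and the full analysis set (spectra,
#' per-cycle metrics, CSE baseline, parameter trajectories, sideband
#' report), and writes everything to `out_dir` as CSV/JSON with a manifest.
#' Output is deterministic for a fixed config: rerunning produces
#' byte-identical files.
#'
#' @param config a `scenario_config`.
#' @param out_dir output directory (created if missing).
#' @return the path to `out_dir`, invisibly; the in-memory results as the
#'   attribute `"results"`.
#' @export
run_scenario <- function(config, out_dir = tempfile("pulsema-run-")) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- build_scenario_inputs(config)
  an <- config$analysis
  f_c <- config$pulse$f_c
  if (config$case == "wall") {
    res <- run_case_wall(inp$params, inp$pulse, inp$drift,
                         gains = config$gains, normalizer = config$normalizer,
                         solver_opts = config$solver)
    forces <- equivalent_forces_1dof(res)
    sim_series <- res[c("y", "x_b", "x_C", "x_M", "x_TVSP", "x_ACC",
                        "x_PPG", "x_ACC_MA", "x_PPG_MA")]
    force_series <- forces[c("F_b", "F_C", "F_T", "F_TVSP", "F_MA")]
    dist <- res$x_TVSP
    measured <- res$x_ACC
  } else {
    res <- run_case_pressure(inp$params, inp$artery, inp$pulse, inp$drift,
                             gains = config$gains,
                             normalizer = config$normalizer,
                             solver_opts = config$solver)
    forces <- equivalent_forces_2dof(res)
    sim_series <- res[c("F", "x_1b", "x_2b", "Fb", "x_1C", "x_2C", "x_1M",
                        "x_2M", "x_1TVSP", "x_2TVSP", "x_ACC", "x_PPG",
                        "x_ACC_MA", "x_PPG_MA")]
    force_series <- forces[c("F_b", "F_1T", "F_2T", "F_1TVSP", "F_2TVSP",
                             "F_1MA", "F_2MA")]
    dist <- res$x_2TVSP
    measured <- res$x_ACC
  }
  write_series_csv(res$time, sim_series, file.path(out_dir, "sim.csv"))
  write_series_csv(res$time, force_series, file.path(out_dir, "forces.csv"))

  # analysis window: drop the configured lead-in cycles
  t0 <- res$time[1L] + an$discard_cycles / f_c
  keep <- res$time >= t0 - 1e-12
  crop <- function(s) pulse_signal(s$samples[keep], fs = s$fs,
                                   t_start = res$time[keep][1L],
                                   label = s$label)
  dist_c <- crop(dist); meas_c <- crop(measured)
  spec_dist <- pulse_spectrum(dist_c, window = an$window,
                              zero_pad_factor = an$zero_pad_factor)
  spec_meas <- pulse_spectrum(meas_c, window = an$window,
                              zero_pad_factor = an$zero_pad_factor)
  write_series_csv(spec_dist$frequency,
                   list(amp_distortion = spec_dist$amplitude,
                        amp_measured = spec_meas$amplitude),
                   file.path(out_dir, "spectra.csv"))
  feet <- detect_feet(meas_c, f_c)
  cm <- per_cycle_metrics(meas_c, feet)
  write_series_csv(cm$onsets[-length(cm$onsets)],
                   list(hr_bpm = cm$hr_bpm, amplitude = cm$amplitude),
                   file.path(out_dir, "cycle_metrics.csv"))
  cse <- if (length(feet) >= 4L) cse_baseline(meas_c, feet) else NULL
  if (!is.null(cse))
    write_series_csv(signal_time(cse), list(x_CSE = cse),
                     file.path(out_dir, "cse_baseline.csv"))
  traj <- if (!is.null(res$tvsp))
    param_trajectories(res$tvsp, res$params,
                       artery = if (config$case == "pressure") res$artery)
  if (!is.null(traj))
    write_series_csv(traj$time, traj[-1L],
                     file.path(out_dir, "param_trajectories.csv"))
  sb <- sideband_report(spec_dist, f_c, n_harmonics = an$n_harmonics,
                        band = an$band)
  jsonlite::write_json(
    list(bands = sb$bands, total_energy = sb$total_energy,
         in_band_fraction = sb$in_band_fraction),
    file.path(out_dir, "sidebands.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "pulsema",
    version = as.character(utils::packageVersion("pulsema")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config),
    files = c("sim.csv", "forces.csv", "spectra.csv", "cycle_metrics.csv",
              if (!is.null(cse)) "cse_baseline.csv",
              if (!is.null(traj)) "param_trajectories.csv",
              "sidebands.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  out <- invisible(out_dir)
  attr(out, "results") <- list(sim = res, forces = forces,
                               spectrum = spec_dist, feet = feet,
                               cycle_metrics = cm, cse = cse,
                               trajectories = traj, sidebands = sb)
  out
}

#' Compare two scenario runs series by series
#'
#' Reads `sim.csv` from both run directories and reports the maximum and
#' RMS absolute difference per requested series.
#'
#' @param run_a,run_b run directories written by [run_scenario()].
#' @param series character vector of series names (default: all shared
#'   columns except time).
#' @return data.frame with columns `series, max_abs_diff, rms_diff`.
#' @export
compare_runs <- function(run_a, run_b, series = NULL) {
  a <- utils::read.csv(file.path(run_a, "sim.csv"))
  b <- utils::read.csv(file.path(run_b, "sim.csv"))
  if (nrow(a) != nrow(b) || max(abs(a$time_s - b$time_s)) > 1e-9)
    stop("runs are on different time grids", call. = FALSE)
  if (is.null(series))
    series <- setdiff(intersect(names(a), names(b)), "time_s")
  missing <- setdiff(series, intersect(names(a), names(b)))
  if (length(missing))
    stop("series not present in both runs: ",
         paste(missing, collapse = ", "), call. = FALSE)
  diffs <- vapply(series, function(s) {
    d <- a[[s]] - b[[s]]
    c(max(abs(d)), sqrt(mean(d^2)))
  }, numeric(2))
  data.frame(series = series, max_abs_diff = diffs[1L, ],
             rms_diff = diffs[2L, ], row.names = NULL)
}

#' Write / read a scenario config as YAML
#'
#' @param config a `scenario_config`.
#' @param path YAML file path.
#' @return `write_scenario_yaml()` returns `path`; `read_scenario_yaml()`
#'   returns a validated `scenario_config`.
#' @export
write_scenario_yaml <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(scenario_config, cfg)
}
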