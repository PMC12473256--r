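# Shared fixtures: the canonical simulation conditions (10-harmonic carotid-
# like pulse at 1 Hz, two-tone 0.2 + 0.35 Hz drift, r0 = 2, zeta0 = 1.5,
# k0 = kA/6) built in code and memoized so the expensive ODE runs happen once
# per test session.

.pulsema_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .pulsema_test_cache))
    assign(name, expr, envir = .pulsema_test_cache)
  get(name, envir = .pulsema_test_cache)
}

default_params <- function() nominal_params()

default_artery <- function() artery_params()

default_pulse <- function(duration = 12, fs = 200)
  make_harmonic_pulse(carotid_harmonic_spec(), duration, fs)

default_drift <- function(duration = 12, fs = 200)
  make_baseline_drift(drift_spec(), duration, fs)

# full 12-cycle wall-displacement scenario (1DOF)
wall_default_run <- function()
  cached("wall12",
         run_case_wall(default_params(), default_pulse(), default_drift()))

# full 12-cycle pulsatile-pressure scenario (2DOF)
pressure_default_run <- function()
  cached("press12",
         run_case_pressure(default_params(), default_artery(),
                           default_pulse(), default_drift()))

# drop everything before t0 (lead-in removal)
trim_signal <- function(s, t0) {
  t <- signal_time(s)
  keep <- t >= t0 - 1e-12
  pulse_signal(s$samples[keep], fs = s$fs, t_start = t[keep][1L],
               label = s$label)
}

# spectral energy fraction below f_lim, Hann-windowed periodogram
energy_below <- function(s, f_lim) {
  x <- s$samples - mean(s$samples)
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  X <- Mod(stats::fft(x * w))^2
  f <- (0:(n - 1)) * s$fs / n
  f <- pmin(f, s$fs - f)
  sum(X[f <= f_lim]) / sum(X)
}

# steady-state amplitude of a (nearly) harmonic signal over t >= t0
steady_amplitude <- function(s, t0) {
  x <- trim_signal(s, t0)$samples
  (max(x) - min(x)) / 2
}
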