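#' Harmonic description of a true pulse signal
#'
#' An arterial pulse at rest is a sum of harmonics of the heart rate. A
#' `harmonic_spec` lists the fundamental frequency `f_c` (Hz; 1 Hz = 60 bpm)
#' and one `(order, amplitude, phase)` row per harmonic. It describes either
#' the arterial wall displacement y(t) or the pulsatile pressure waveform
#' that drives the tissue-contact-sensor (TCS) stack.
#'
#' @param f_c fundamental frequency in Hz (> 0).
#' @param orders integer harmonic orders (>= 1, unique).
#' @param amplitudes non-negative amplitudes, one per order.
#' @param phases phases in radians, one per order (recycled if length 1).
#' @return an object of class `harmonic_spec`.
#' @seealso [carotid_harmonic_spec()] for the package default,
#'   [make_harmonic_pulse()] to render a signal.
#' @export
harmonic_spec <- function(f_c, orders, amplitudes, phases = 0) {
  if (!is.numeric(f_c) || length(f_c) != 1L || f_c <= 0)
    stop("f_c must be a single positive frequency in Hz", call. = FALSE)
  orders <- as.integer(orders)
  if (length(orders) && (any(orders < 1L) || anyDuplicated(orders)))
    stop("harmonic orders must be unique integers >= 1", call. = FALSE)
  if (length(amplitudes) != length(orders))
    stop("amplitudes must match orders in length", call. = FALSE)
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  phases <- rep_len(as.numeric(phases), length(orders))
  structure(list(f_c = as.numeric(f_c), orders = orders,
                 amplitudes = as.numeric(amplitudes), phases = phases),
            class = "harmonic_spec")
}

#' Default carotid-like harmonic spectrum
#'
#' Ten harmonics with geometrically decaying amplitudes
#' (amp_n = `decay`^(n-1)) and phases chosen to produce a sharp systolic
#' upstroke. This is a synthetic stand-in for a measured carotid pulse: any
#' multi-harmonic waveform exercises the same transmission-path mathematics.
#'
#' @param f_c fundamental frequency (Hz), default 1 (60 bpm).
#' @param n_harmonics number of harmonics, default 10.
#' @param decay geometric amplitude decay ratio, default 0.6.
#' @return a `harmonic_spec`.
#' @export
carotid_harmonic_spec <- function(f_c = 1, n_harmonics = 10L, decay = 0.6) {
  n <- seq_len(n_harmonics)
  # phase ramp -n*pi/2 steepens the upstroke (sawtooth-like alignment)
  harmonic_spec(f_c, n, decay^(n - 1), phases = -n * pi / 2)
}

# evaluate a harmonic spec (and derivatives) at arbitrary times
harmonic_eval <- function(spec, t, deriv = 0L) {
  stopifnot(inherits(spec, "harmonic_spec"))
  out <- numeric(length(t))
  for (i in seq_along(spec$orders)) {
    w <- 2 * pi * spec$orders[i] * spec$f_c
    th <- w * t + spec$phases[i]
    out <- out + spec$amplitudes[i] * switch(as.character(deriv),
      "0" = cos(th), "1" = -w * sin(th), "2" = -w^2 * cos(th),
      stop("deriv must be 0, 1 or 2"))
  }
  out
}

#' Render a harmonic spec as a sampled pulse signal
#'
#' Evaluates `sum_n amp_n * cos(2*pi*n*f_c*t + phase_n)` on a uniform grid.
#' The returned signal carries the spec as an attribute so downstream ODE
#' integration can use exact analytic derivatives of the excitation instead
#' of numerical ones.
#'
#' @param spec a `harmonic_spec`.
#' @param duration signal length in seconds (>= 2 cycles recommended).
#' @param fs sampling rate (Hz); must resolve the highest harmonic (an error
#'   names the Nyquist bound when violated).
#' @param t_start start time (s).
#' @return a `pulse_signal` with attribute `"harmonic_spec"`.
#' @examples
#' y <- make_harmonic_pulse(carotid_harmonic_spec(), duration = 4, fs = 200)
#' @export
make_harmonic_pulse <- function(spec, duration, fs, t_start = 0) {
  stopifnot(inherits(spec, "harmonic_spec"))
  if (length(spec$orders)) {
    f_max <- max(spec$orders) * spec$f_c
    if (fs <= 2 * f_max)
      stop(sprintf(
        "fs = %g Hz aliases the highest harmonic at %g Hz; need fs > Nyquist bound 2*%g = %g Hz",
        fs, f_max, f_max, 2 * f_max), call. = FALSE)
  }
  n <- max(2L, round(duration * fs))
  t <- t_start + (seq_len(n) - 1) / fs
  out <- pulse_signal(harmonic_eval(spec, t), fs = fs, t_start = t_start,
                      label = sprintf("harmonic pulse f_c=%g Hz", spec$f_c))
  attr(out, "harmonic_spec") <- spec
  out
}

#' Synthesize a physiologic-looking arterial pulse waveform
#'
#' Builds a strictly periodic waveform from two positive bumps per cycle
#' (systolic peak plus dicrotic wave), each a circularly wrapped Gaussian in
#' cycle phase. The foot (cycle minimum) precedes the systolic upstroke.
#'
#' @param f_c fundamental frequency (Hz).
#' @param duration signal length (s).
#' @param fs sampling rate (Hz).
#' @param centers bump centers as fractions of the cycle, default
#'   `c(0.15, 0.45)` (systolic, dicrotic).
#' @param widths bump standard deviations in cycle fraction, default
#'   `c(0.05, 0.09)`.
#' @param heights bump heights, default `c(1, 0.4)`.
#' @param t_start start time (s).
#' @return a `pulse_signal`, one dominant maximum per cycle.
#' @export
make_synthetic_apw <- function(f_c, duration, fs,
                               centers = c(0.15, 0.45),
                               widths = c(0.05, 0.09),
                               heights = c(1, 0.4),
                               t_start = 0) {
  stopifnot(length(centers) == length(widths),
            length(widths) == length(heights))
  if (any(widths <= 0)) stop("bump widths must be > 0", call. = FALSE)
  if (length(heights) >= 2 && any(duplicated(heights[heights > 0])))
    warning("equal bump heights may produce multiple equal maxima per cycle")
  n <- max(2L, round(duration * fs))
  t <- t_start + (seq_len(n) - 1) / fs
  u <- (t * f_c) %% 1
  s <- numeric(n)
  for (i in seq_along(centers)) {
    d <- (u - centers[i] + 0.5) %% 1 - 0.5  # wrapped phase distance
    s <- s + heights[i] * exp(-0.5 * (d / widths[i])^2)
  }
  pulse_signal(s, fs = fs, t_start = t_start,
               label = sprintf("synthetic APW f_c=%g Hz", f_c))
}

#' Baseline-drift specification
#'
#' Motion artifacts at rest displace the sensor relative to the artery at
#' frequencies below 0.7 Hz. A `drift_spec` describes such a band-limited
#' drift waveform: a deterministic harmonic sum, a seeded random smooth
#' curve, or a tabulated file.
#'
#' @param kind one of `"harmonic-sum"`, `"random-smooth"`, `"from-samples"`.
#' @param amplitude peak absolute value of the generated drift after
#'   rescaling (>= 0; 0 yields a zero signal).
#' @param band_limit band limit in Hz; must be <= 0.7 unless
#'   `allow_above_rest_band = TRUE` (at-rest motion artifacts live below
#'   0.7 Hz).
#' @param seed integer RNG seed (random-smooth kind).
#' @param components for `"harmonic-sum"`: a data.frame with columns
#'   `freq` (Hz), `amp`, and optionally `phase` (radians, sine convention:
#'   each term is `amp * sin(2*pi*freq*t + phase)`). Default 0.7 at 0.2 Hz
#'   plus 0.3 at 0.35 Hz.
#' @param n_knots for `"random-smooth"`: number of random spline knots.
#' @param path for `"from-samples"`: CSV file readable by [read_pulse_csv()].
#' @param allow_above_rest_band set `TRUE` to permit `band_limit > 0.7` Hz.
#' @return an object of class `drift_spec`.
#' @export
drift_spec <- function(kind = c("harmonic-sum", "random-smooth", "from-samples"),
                       amplitude = 1, band_limit = 0.7, seed = 1L,
                       components = data.frame(freq = c(0.2, 0.35),
                                               amp = c(0.7, 0.3)),
                       n_knots = 8L, path = NULL,
                       allow_above_rest_band = FALSE) {
  kind <- match.arg(kind)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (band_limit > 0.7 && !allow_above_rest_band)
    stop("band_limit above 0.7 Hz models motion beyond at-rest artifacts; ",
         "set allow_above_rest_band = TRUE to override", call. = FALSE)
  if (kind == "harmonic-sum") {
    if (!is.data.frame(components) || !all(c("freq", "amp") %in% names(components)))
      stop("components must be a data.frame with columns freq, amp", call. = FALSE)
    if (is.null(components$phase)) components$phase <- 0
    if (any(components$freq > band_limit))
      stop("harmonic-sum component frequencies must lie within band_limit",
           call. = FALSE)
  }
  if (kind == "from-samples" && is.null(path))
    stop("from-samples drift needs a file path", call. = FALSE)
  structure(list(kind = kind, amplitude = amplitude, band_limit = band_limit,
                 seed = as.integer(seed), components = components,
                 n_knots = as.integer(n_knots), path = path),
            class = "drift_spec")
}

# run expr with a local, restored RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a band-limited baseline drift
#'
#' Realizes a [drift_spec()] on a uniform grid and rescales it so that its
#' peak absolute value equals `spec$amplitude`. Random-smooth drifts
#' interpolate seeded random knots with a periodic-safe spline and are then
#' hard-truncated above the band limit in the frequency domain, so at least
#' 99% of spectral energy always lies below `band_limit`. Identical specs
#' (including seed) reproduce bit-identical samples.
#'
#' @param spec a `drift_spec`.
#' @param duration signal length (s).
#' @param fs sampling rate (Hz).
#' @param t_start start time (s).
#' @return a `pulse_signal`.
#' @export
make_baseline_drift <- function(spec, duration, fs, t_start = 0) {
  stopifnot(inherits(spec, "drift_spec"))
  n <- max(2L, round(duration * fs))
  t_rel <- (seq_len(n) - 1) / fs
  raw <- switch(spec$kind,
    "harmonic-sum" = {
      s <- numeric(n)
      for (i in seq_len(nrow(spec$components)))
        s <- s + spec$components$amp[i] *
          sin(2 * pi * spec$components$freq[i] * t_rel + spec$components$phase[i])
      s
    },
    "random-smooth" = {
      knots <- with_local_seed(spec$seed, stats::rnorm(spec$n_knots))
      kt <- seq(0, duration, length.out = spec$n_knots)
      s <- stats::spline(kt, knots, xout = t_rel, method = "fmm")$y
      # hard frequency-domain truncation above the band limit
      X <- stats::fft(s)
      f <- (0:(n - 1)) * fs / n
      f <- pmin(f, fs - f)  # two-sided frequency magnitude
      X[f > spec$band_limit] <- 0
      Re(stats::fft(X, inverse = TRUE) / n)
    },
    "from-samples" = {
      sig <- read_pulse_csv(spec$path)
      if (abs(sig$fs - fs) > 1e-9 * fs || length(sig$samples) < n)
        stop("from-samples drift must match the requested fs and cover duration",
             call. = FALSE)
      sig$samples[seq_len(n)]
    })
  peak <- max(abs(raw))
  s <- if (spec$amplitude == 0 || peak == 0) raw * 0
       else raw * (spec$amplitude / peak)
  pulse_signal(s, fs = fs, t_start = t_start,
               label = sprintf("baseline drift (%s)", spec$kind))
}

#' Arterial-wall parameters
#'
#' In the pulsatile-pressure (2DOF) model the arterial wall is a spring of
#' stiffness `kA`; the pulsatile pressure acts on it through an effective
#' radius `a`, giving a force `F(t) = pi * a * dp(t)`.
#'
#' @param kA wall stiffness (> 0, normalized force/length; package default 1).
#' @param a effective artery radius (> 0, length units).
#' @return an object of class `artery_params`.
#' @export
artery_params <- function(kA = 1, a = 1 / pi) {
  if (!is.numeric(kA) || kA <= 0) stop("kA must be > 0", call. = FALSE)
  if (!is.numeric(a) || a <= 0) stop("a must be > 0", call. = FALSE)
  structure(list(kA = as.numeric(kA), a = as.numeric(a)),
            class = "artery_params")
}

#' Convert pulsatile pressure to arterial-wall force
#'
#' Pointwise scaling `F(t) = pi * a * dp(t)`.
#'
#' @param dp pulsatile pressure as a `pulse_signal`.
#' @param artery an `artery_params`.
#' @return a `pulse_signal` on the same grid.
#' @export
pressure_to_force <- function(dp, artery) {
  stopifnot(inherits(dp, "pulse_signal"), inherits(artery, "artery_params"))
  out <- ps_map(dp, function(s) pi * artery$a * s, label = "wall force F(t)")
  sp <- attr(dp, "harmonic_spec")
  if (!is.null(sp)) {
    sp$amplitudes <- sp$amplitudes * pi * artery$a
    attr(out, "harmonic_spec") <- sp
  }
  out
}
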