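# Result-space analyses: amplitude spectra, pulse-foot detection, per-cycle
# heart rate and waveform metrics, cubic-spline baseline estimation,
# instantaneous system-parameter trajectories, and harmonic-sideband energy.

#' Single-sided amplitude spectrum
#'
#' FFT-based amplitude spectrum with an optional window and zero padding.
#' With the rectangular window and an integer number of periods, a unit
#' cosine yields a single bin of amplitude 1. Zero padding (default 4x)
#' refines the frequency grid so that narrow sidebands around the pulse
#' harmonics are resolved.
#'
#' @param x a `pulse_signal` covering at least 2 cycles of interest.
#' @param window `"rectangular"` (default), `"hann"`, or `"hamming"`.
#' @param zero_pad_factor integer >= 1, default 4.
#' @return an object of class `spectrum_result`: `frequency` (Hz, from 0),
#'   `amplitude` (signal units), `resolution` (Hz), `window`, plus the
#'   windowed-signal energy for Parseval checks.
#' @export
pulse_spectrum <- function(x, window = c("rectangular", "hann", "hamming"),
                           zero_pad_factor = 4L) {
  stopifnot(inherits(x, "pulse_signal"))
  window <- match.arg(window)
  n <- length(x$samples)
  w <- switch(window,
    rectangular = rep(1, n),
    hann = 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
    hamming = 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1)))
  wx <- x$samples * w
  npad <- as.integer(zero_pad_factor) * n
  X <- stats::fft(c(wx, rep(0, npad - n)))
  half <- floor(npad / 2) + 1L
  amp <- Mod(X[seq_len(half)]) / sum(w)
  # double the non-unique bins (not DC; not Nyquist when npad is even)
  dbl <- seq_len(half) > 1L
  if (npad %% 2L == 0L) dbl[half] <- FALSE
  amp[dbl] <- 2 * amp[dbl]
  structure(list(frequency = (seq_len(half) - 1L) * x$fs / npad,
                 amplitude = amp,
                 resolution = x$fs / npad,
                 window = window,
                 window_sum = sum(w),
                 n_signal = n, n_pad = npad,
                 energy_time = sum(wx^2)),
            class = "spectrum_result")
}

#' Detect pulse feet (cycle onsets)
#'
#' Marks each cycle's foot: the local minimum preceding the maximal systolic
#' upstroke within the expected cycle window. Upstroke candidates are local
#' maxima of the centered first derivative separated by at least 60% of the
#' expected period; the foot is the signal minimum in the 0.8-period window
#' before each upstroke (ties broken to the earliest sample). Candidates
#' whose search window does not fit inside the signal are skipped, and a
#' minimum pinned to a window edge (no interior minimum, e.g. under a trend
#' steeper than the waveform's foot curvature) is rejected rather than
#' reported at an arbitrary position. Foot times are refined to sub-sample
#' accuracy by parabolic interpolation, so per-cycle heart rate is not
#' quantized to the sample period. Because the foot of an arterial pulse is
#' a curved minimum, slow baseline trends move it by far less than a sample;
#' the same detector should be applied to every signal being compared so
#' that heart-rate differences reflect distortion, not detector changes.
#'
#' @param x a `pulse_signal` with at least 3 cycles.
#' @param f_c_hint expected fundamental frequency (Hz), within about 30% of
#'   the truth.
#' @param refine logical; parabolic sub-sample refinement (default TRUE).
#' @return numeric vector of onset times (s). A count far from
#'   `duration * f_c_hint` triggers a warning with diagnostics.
#' @export
detect_feet <- function(x, f_c_hint, refine = TRUE) {
  stopifnot(inherits(x, "pulse_signal"), f_c_hint > 0)
  s <- x$samples
  n <- length(s)
  t <- signal_time(x)
  d <- c(0, (s[3:n] - s[1:(n - 2)]) * x$fs / 2, 0)  # centered derivative
  min_sep <- max(1L, round(0.6 * x$fs / f_c_hint))
  # local maxima of the derivative above a fraction of its global max
  cand <- which(d > 0.3 * max(d))
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[d[cand] >= d[cand - 1L] & d[cand] >= d[cand + 1L]]
  # enforce separation, keeping the strongest upstroke in each cluster
  if (length(cand)) {
    ord <- cand[order(-d[cand])]
    keep <- integer(0)
    for (i in ord)
      if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
    cand <- sort(keep)
  }
  if (length(cand) < 2L)
    stop("could not find at least 2 upstrokes; check f_c_hint", call. = FALSE)
  win <- as.integer(round(0.8 * x$fs / f_c_hint))
  cand <- cand[cand - win >= 1L]  # the search window must fit the signal
  onsets_idx <- integer(0)
  for (i in cand) {
    lo <- i - win
    j <- which.min(s[lo:i])  # earliest tie
    if (j > 1L && j < win + 1L)  # interior minimum only
      onsets_idx <- c(onsets_idx, as.integer(lo + j - 1L))
  }
  onsets_idx <- unique(onsets_idx)
  onset_t <- t[onsets_idx]
  if (refine) {
    for (j in seq_along(onsets_idx)) {
      i <- onsets_idx[j]
      den <- s[i - 1L] - 2 * s[i] + s[i + 1L]
      if (is.finite(den) && den > 0) {
        delta <- 0.5 * (s[i - 1L] - s[i + 1L]) / den
        onset_t[j] <- t[i] + max(-0.5, min(0.5, delta)) / x$fs
      }
    }
  }
  expected <- (t[n] - t[1L]) * f_c_hint
  if (abs(length(onset_t) - expected) > max(1.5, 0.3 * expected))
    warning(sprintf("found %d feet but expected about %.1f cycles at %g Hz",
                    length(onset_t), expected, f_c_hint))
  onset_t
}

#' Per-cycle heart rate, amplitude, and normalized waveform
#'
#' For each foot-to-foot cycle: heart rate `60 / interval` (bpm),
#' peak-to-foot amplitude (cycle maximum minus cycle minimum), and the
#' normalized arterial pulse waveform (APW): the cycle resampled to
#' `n_points` samples and min-max normalized to attain both 0 and 1.
#'
#' @param x a `pulse_signal`.
#' @param onsets onset times from [detect_feet()] (>= 2).
#' @param n_points resampling length for normalized APWs, default 200.
#' @return an object of class `cycle_metrics`: `onsets`, `hr_bpm`,
#'   `amplitude`, `apw` (matrix, one row per cycle), `degenerate` (logical,
#'   flat cycles flagged).
#' @export
per_cycle_metrics <- function(x, onsets, n_points = 200L) {
  stopifnot(inherits(x, "pulse_signal"), length(onsets) >= 2L,
            all(diff(onsets) > 0))
  t <- signal_time(x)
  sf <- stats::splinefun(t, x$samples, method = "fmm")
  nc <- length(onsets) - 1L
  hr <- 60 / diff(onsets)
  amplitude <- numeric(nc)
  degenerate <- logical(nc)
  apw <- matrix(NA_real_, nrow = nc, ncol = n_points)
  for (i in seq_len(nc)) {
    tt <- seq(onsets[i], onsets[i + 1L], length.out = n_points)
    cyc <- sf(tt)
    rng <- range(cyc)
    amplitude[i] <- rng[2L] - rng[1L]
    if (amplitude[i] <= 0) {
      degenerate[i] <- TRUE
      apw[i, ] <- 0
    } else {
      apw[i, ] <- (cyc - rng[1L]) / amplitude[i]
    }
  }
  if (any(degenerate)) warning("degenerate (flat) cycles flagged")
  structure(list(onsets = onsets, hr_bpm = hr, amplitude = amplitude,
                 apw = apw, degenerate = degenerate),
            class = "cycle_metrics")
}

#' Cubic-spline baseline estimation (CSE)
#'
#' The standard baseline estimator in pulse processing: a natural cubic
#' spline through the signal values at the pulse feet, evaluated on the full
#' grid. No pre-filtering is applied (filtering before CSE would add its own
#' distortion). On an MA-free periodic signal all knots coincide and the
#' estimate is a constant; under motion artifacts the estimate generally
#' fails to match the true drift because TVSP distortion shifts the feet.
#'
#' @param x a `pulse_signal`.
#' @param onsets foot times (>= 4, a cubic spline needs 4 knots).
#' @return the estimated baseline as a `pulse_signal` on `x`'s grid.
#' @export
cse_baseline <- function(x, onsets) {
  stopifnot(inherits(x, "pulse_signal"))
  if (length(onsets) < 4L)
    stop("cubic-spline baseline estimation needs at least 4 feet", call. = FALSE)
  t <- signal_time(x)
  sf <- stats::splinefun(t, x$samples, method = "fmm")
  knots_y <- sf(onsets)
  est <- stats::spline(onsets, knots_y, xout = t, method = "natural")$y
  pulse_signal(est, fs = x$fs, t_start = x$t_start, label = "x_CSE")
}

#' Instantaneous frequency-ratio and damping-factor trajectories
#'
#' The TVSPs move the stack's operating point: the instantaneous frequency
#' ratio is `r(t) = sqrt((k0+dk)/(m0+dm)) / omegaC` and the damping factor
#' `zeta(t) = (c0+dc) / (2*sqrt((m0+dm)*(k0+dk)))`. When the arterial wall
#' is in the loop, `r_total(t)` uses the series stiffness seen by the mass,
#' `k_series = kA*(k0+dk) / (kA+k0+dk)` (the wall spring and the perturbed
#' stack spring act in series).
#'
#' @param tvsp a `tvsp_trajectory`.
#' @param params a `tcs_params`.
#' @param artery optional `artery_params`; enables `r_total`.
#' @return data.frame with columns `time, r, zeta` and, with `artery`,
#'   `r_total`.
#' @export
param_trajectories <- function(tvsp, params, artery = NULL) {
  stopifnot(inherits(tvsp, "tvsp_trajectory"), inherits(params, "tcs_params"))
  k <- params$k0 + tvsp$dk
  m <- params$m0 + tvsp$dm
  c_ <- params$c0 + tvsp$dc
  out <- data.frame(time = tvsp$time,
                    r = sqrt(k / m) / params$omegaC,
                    zeta = c_ / (2 * sqrt(m * k)))
  if (!is.null(artery)) {
    ks <- artery$kA * k / (artery$kA + k)
    out$r_total <- sqrt(ks / m) / params$omegaC
  }
  out
}

#' Harmonic-sideband energy report
#'
#' TVSP distortion is multiplicative: it rides on each harmonic of the true
#' pulse as low-amplitude sidebands. This report integrates the distortion
#' spectrum's squared amplitude within `harmonic_n*f_c +/- band` for each
#' harmonic, records the harmonic's peak amplitude, and the in-band fraction
#' of the spectrum's total energy.
#'
#' @param spec a `spectrum_result` of the distortion signal.
#' @param f_c fundamental frequency (Hz).
#' @param n_harmonics number of harmonics to report, default 10.
#' @param band half-width of each band (Hz), default 0.7 (the drift band);
#'   must not exceed `f_c/2` (bands would overlap) and must be at least 4
#'   spectral resolution steps.
#' @return an object of class `sideband_report`: data.frame `bands` with
#'   columns `harmonic, center_hz, energy, peak_amplitude, ratio`, plus
#'   `total_energy` and `in_band_fraction`.
#' @export
sideband_report <- function(spec, f_c, n_harmonics = 10L, band = 0.7) {
  stopifnot(inherits(spec, "spectrum_result"))
  if (band > f_c / 2)
    stop("band > f_c/2 makes adjacent harmonic bands overlap", call. = FALSE)
  if (spec$resolution > band / 4)
    stop("spectral resolution too coarse for the requested band; ",
         "use a longer signal or more zero padding", call. = FALSE)
  total <- sum(spec$amplitude^2)
  bands <- data.frame(harmonic = seq_len(n_harmonics))
  bands$center_hz <- bands$harmonic * f_c
  bands$energy <- NA_real_
  bands$peak_amplitude <- NA_real_
  for (i in seq_len(n_harmonics)) {
    sel <- spec$frequency >= bands$center_hz[i] - band &
           spec$frequency <= bands$center_hz[i] + band
    bands$energy[i] <- sum(spec$amplitude[sel]^2)
    bands$peak_amplitude[i] <- if (any(sel)) max(spec$amplitude[sel]) else 0
  }
  bands$ratio <- bands$energy / pmax(bands$peak_amplitude^2, .Machine$double.eps)
  structure(list(bands = bands, total_energy = total,
                 in_band_fraction = if (total > 0) sum(bands$energy) / total
                                    else 0,
                 band = band, f_c = f_c),
            class = "sideband_report")
}

#' Fraction of spectral energy near the pulse harmonics
#'
#' Energy fraction of a spectrum lying in the union of bands
#' `harmonic_n*f_c +/- band`, n = 1..`n_harmonics`. Unlike
#' [sideband_report()], the bands may be wider than `f_c/2`: overlapping
#' bands are merged (each frequency bin counted once), so the fraction is
#' well defined for any band width.
#'
#' @param spec a `spectrum_result`.
#' @param f_c fundamental frequency (Hz).
#' @param n_harmonics number of harmonics, default 10.
#' @param band half-width of each band (Hz).
#' @return scalar in `[0, 1]` (0 for an all-zero spectrum).
#' @export
band_energy_fraction <- function(spec, f_c, n_harmonics = 10L, band = 0.7) {
  stopifnot(inherits(spec, "spectrum_result"))
  total <- sum(spec$amplitude^2)
  if (total == 0) return(0)
  sel <- rep(FALSE, length(spec$frequency))
  for (n in seq_len(n_harmonics))
    sel <- sel | (spec$frequency >= n * f_c - band &
                  spec$frequency <= n * f_c + band)
  sum(spec$amplitude[sel]^2) / total
}
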