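# Time-domain integration of the 1DOF / 2DOF tissue-contact-sensor models.
#
# All integrators run deSolve's Dormand-Prince 4(5) pair ("ode45") from rest
# with tight tolerances (rtol 1e-8, atol 1e-10) and report the solution on
# the excitation's sample grid. Velocities are taken from the solver state
# and accelerations from the ODE right-hand side, never by differencing the
# output, so force residuals stay near solver tolerance.

default_solver_opts <- function(opts = list()) {
  utils::modifyList(list(rtol = 1e-8, atol = 1e-10, method = "ode45"), opts)
}

# evaluator for an excitation signal: analytic when a harmonic_spec rides
# along, cubic-spline otherwise
excitation_fn <- function(sig) {
  spec <- attr(sig, "harmonic_spec")
  if (!is.null(spec)) {
    function(t, deriv = 0L) harmonic_eval(spec, t, deriv)
  } else {
    t0 <- signal_time(sig)
    sf <- stats::splinefun(t0, sig$samples, method = "fmm")
    function(t, deriv = 0L) sf(t, deriv = as.integer(deriv))
  }
}

# evaluators for a TVSP trajectory (zero functions when tvsp is NULL)
tvsp_fns <- function(tvsp) {
  if (is.null(tvsp)) {
    z <- function(t) rep(0, length(t))
    return(list(dm = z, dk = z, dc = z))
  }
  stopifnot(inherits(tvsp, "tvsp_trajectory"))
  list(dm = stats::splinefun(tvsp$time, tvsp$dm, method = "fmm"),
       dk = stats::splinefun(tvsp$time, tvsp$dk, method = "fmm"),
       dc = stats::splinefun(tvsp$time, tvsp$dc, method = "fmm"))
}

#' Simulate the (time-varying) 1DOF stack under base excitation
#'
#' Integrates
#' `(m0+dm) x'' + (c0+dc) x' + (k0+dk) x = (k0+dk) y + (c0+dc) y'`
#' from rest on the excitation's grid. With `tvsp = NULL` the equation is
#' linear time-invariant and its steady state matches [transfer_1dof()].
#'
#' @param params a `tcs_params`.
#' @param tvsp a `tvsp_trajectory` covering `y`'s grid, or `NULL` for the
#'   MA-free (LTI) system.
#' @param y base excitation (wall displacement) as a `pulse_signal`; if it
#'   carries a `harmonic_spec` attribute its derivative is analytic.
#' @param solver_opts list overriding `rtol`, `atol`, `method`.
#' @return a `pulse_signal` of the mass displacement, with the solver's
#'   velocity and acceleration attached as attributes `"velocity"` and
#'   `"accel"` and diagnostics as `"diagnostics"`.
#' @export
simulate_1dof_tv <- function(params, tvsp, y, solver_opts = list()) {
  stopifnot(inherits(params, "tcs_params"), inherits(y, "pulse_signal"))
  so <- default_solver_opts(solver_opts)
  ex <- excitation_fn(y)
  tv <- tvsp_fns(tvsp)
  times <- signal_time(y)
  rhs <- function(t, state, parms) {
    m <- params$m0 + tv$dm(t); k <- params$k0 + tv$dk(t)
    c_ <- params$c0 + tv$dc(t)
    a <- (k * (ex(t) - state[1L]) + c_ * (ex(t, 1L) - state[2L])) / m
    list(c(state[2L], a))
  }
  sol <- deSolve::ode(y = c(x = 0, v = 0), times = times, func = rhs,
                      parms = NULL, method = so$method,
                      rtol = so$rtol, atol = so$atol)
  if (nrow(sol) != length(times) || any(!is.finite(sol[, 2L])))
    stop("1DOF solver failed (non-finite state or truncated output); ",
         "rtol=", so$rtol, " atol=", so$atol, call. = FALSE)
  x <- sol[, 2L]; v <- sol[, 3L]
  a <- (  (params$k0 + tv$dk(times)) * (ex(times) - x)
        + (params$c0 + tv$dc(times)) * (ex(times, 1L) - v)) /
       (params$m0 + tv$dm(times))
  out <- pulse_signal(x, fs = y$fs, t_start = y$t_start,
                      label = if (is.null(tvsp)) "x_C (MA-free)" else "x_M (TVSP)")
  attr(out, "velocity") <- v
  attr(out, "accel") <- a
  attr(out, "diagnostics") <- list(rtol = so$rtol, atol = so$atol,
                                   method = so$method, n_out = length(x))
  out
}

#' Simulate the (time-varying) 2DOF artery-stack system under wall force
#'
#' Integrates the coupled equations
#' `(kA+k0+dk) x1 - (k0+dk) x2 + (c0+dc)(x1' - x2') = F` and
#' `(k0+dk)(x2-x1) + (c0+dc)(x2'-x1') + (m0+dm) x2'' = 0`
#' from rest on the force's grid. `x1` is the arterial wall, `x2` the
#' sensor mass. With `tvsp = NULL` the steady state matches
#' [transfer_2dof()].
#'
#' @param params a `tcs_params`.
#' @param artery an `artery_params`.
#' @param tvsp a `tvsp_trajectory` or `NULL`.
#' @param F wall force as a `pulse_signal` (see [pressure_to_force()]).
#' @param solver_opts list overriding `rtol`, `atol`, `method`.
#' @return list of `pulse_signal`s `x1`, `x2`; each carries `"velocity"`
#'   (and `x2` also `"accel"`) attributes from the solver state.
#' @export
simulate_2dof_tv <- function(params, artery, tvsp, F, solver_opts = list()) {
  stopifnot(inherits(params, "tcs_params"), inherits(artery, "artery_params"),
            inherits(F, "pulse_signal"))
  so <- default_solver_opts(solver_opts)
  ex <- excitation_fn(F)
  tv <- tvsp_fns(tvsp)
  kA <- artery$kA
  times <- signal_time(F)
  rhs <- function(t, state, parms) {
    k <- params$k0 + tv$dk(t); c_ <- params$c0 + tv$dc(t)
    m <- params$m0 + tv$dm(t)
    x1 <- state[1L]; x2 <- state[2L]; v2 <- state[3L]
    v1 <- v2 + (ex(t) - (kA + k) * x1 + k * x2) / c_
    a2 <- (-k * (x2 - x1) - c_ * (v2 - v1)) / m
    list(c(v1, v2, a2))
  }
  sol <- deSolve::ode(y = c(x1 = 0, x2 = 0, v2 = 0), times = times,
                      func = rhs, parms = NULL, method = so$method,
                      rtol = so$rtol, atol = so$atol)
  if (nrow(sol) != length(times) || any(!is.finite(sol[, 2L])))
    stop("2DOF solver failed (non-finite state or truncated output)",
         call. = FALSE)
  x1 <- sol[, 2L]; x2 <- sol[, 3L]; v2 <- sol[, 4L]
  k <- params$k0 + tv$dk(times); c_ <- params$c0 + tv$dc(times)
  m <- params$m0 + tv$dm(times)
  v1 <- v2 + (ex(times) - (kA + k) * x1 + k * x2) / c_
  a2 <- (-k * (x2 - x1) - c_ * (v2 - v1)) / m
  tag <- if (is.null(tvsp)) "C" else "M"
  s1 <- pulse_signal(x1, fs = F$fs, t_start = F$t_start,
                     label = paste0("x1", tag, " (wall)"))
  s2 <- pulse_signal(x2, fs = F$fs, t_start = F$t_start,
                     label = paste0("x2", tag, " (mass)"))
  attr(s1, "velocity") <- v1
  attr(s2, "velocity") <- v2
  attr(s2, "accel") <- a2
  attr(s2, "diagnostics") <- list(rtol = so$rtol, atol = so$atol,
                                  method = so$method, n_out = length(x2))
  list(x1 = s1, x2 = s2)
}

#' Propagate a mass drift to the arterial wall (2DOF force balance)
#'
#' Given the baseline drift `x2b` at the sensor mass, solves the force
#' balance for the induced wall drift `x1b`:
#' `(kA+k0) x1b - k0 x2b + c0 (x1b' - x2b') = 0`, starting from the
#' quasi-static value `x1b(0) = k0 x2b(0) / (kA+k0)`, and derives the
#' motion-artifact force `Fb = k0 (x2b - x1b) + c0 (x2b' - x1b') + m0 x2b''`.
#'
#' @param params a `tcs_params`.
#' @param artery an `artery_params`.
#' @param x2b drift at the mass as a `pulse_signal` (smooth, band-limited;
#'   energy above fs/4 triggers a warning).
#' @param solver_opts list overriding `rtol`, `atol`, `method`.
#' @return list of `pulse_signal`s `x1b` (with `"velocity"` attribute) and
#'   `Fb`.
#' @export
drift_pair_2dof <- function(params, artery, x2b, solver_opts = list()) {
  stopifnot(inherits(params, "tcs_params"), inherits(artery, "artery_params"),
            inherits(x2b, "pulse_signal"))
  so <- default_solver_opts(solver_opts)
  n <- length(x2b$samples)
  # Hann-windowed check so finite-window leakage does not flag smooth drifts
  wh <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  X <- stats::fft((x2b$samples - mean(x2b$samples)) * wh)
  f2 <- (0:(n - 1)) * x2b$fs / n
  f2 <- pmin(f2, x2b$fs - f2)
  hi <- sum(Mod(X[f2 > x2b$fs / 4])^2)
  if (hi > 1e-6 * sum(Mod(X)^2))
    warning("x2b has spectral energy above fs/4; drift propagation assumes a smooth drift")
  times <- signal_time(x2b)
  ex <- excitation_fn(x2b)
  kA <- artery$kA; k0 <- params$k0; c0 <- params$c0; m0 <- params$m0
  rhs <- function(t, state, parms) {
    list(ex(t, 1L) + (k0 * ex(t) - (kA + k0) * state[1L]) / c0)
  }
  x1b0 <- k0 * x2b$samples[1L] / (kA + k0)
  sol <- deSolve::ode(y = c(x1b = x1b0), times = times, func = rhs,
                      parms = NULL, method = so$method,
                      rtol = so$rtol, atol = so$atol)
  x1b <- sol[, 2L]
  d1 <- ex(times, 1L) + (k0 * ex(times) - (kA + k0) * x1b) / c0
  d2b <- ex(times, 1L)
  dd2b <- ex(times, 2L)
  Fb <- k0 * (x2b$samples - x1b) + c0 * (d2b - d1) + m0 * dd2b
  s1 <- pulse_signal(x1b, fs = x2b$fs, t_start = x2b$t_start,
                     label = "x1b (wall drift)")
  attr(s1, "velocity") <- d1
  list(x1b = s1,
       Fb = pulse_signal(Fb, fs = x2b$fs, t_start = x2b$t_start,
                         label = "Fb (drift force)"))
}

zero_like <- function(sig, label = "") {
  pulse_signal(rep(0, length(sig$samples)), fs = sig$fs,
               t_start = sig$t_start, label = label)
}

#' Full wall-displacement (1DOF) measurement scenario
#'
#' Runs the MA-free and TVSP-perturbed 1DOF simulations and assembles the
#' sensor outputs and distortion decomposition:
#' `x_TVSP = x_M - x_C`, accelerometer `x_ACC = x_M + x_b`, PPG
#' `x_PPG = y + g(x_TVSP + x_b)`, and the total MA distortions
#' `x_ACC_MA = x_TVSP + x_b`, `x_PPG_MA = g(x_TVSP + x_b)`. The additive
#' identities hold to machine precision by construction.
#'
#' @param params a `tcs_params`.
#' @param y true pulse (wall displacement) as a `pulse_signal`.
#' @param drift baseline drift `x_b` on `y`'s grid, or `NULL` for none.
#' @param gains,normalizer TVSP mapping, see [tvsp_from_drift()].
#' @param g optical-transduction function applied to `x_TVSP + x_b`
#'   (default identity).
#' @param tvsp explicit `tvsp_trajectory` overriding the drift-derived one.
#' @param solver_opts passed to [simulate_1dof_tv()].
#' @return an object of class `sim_result_1dof`: named `pulse_signal`s
#'   `y, x_b, x_C, x_M, x_TVSP, x_ACC, x_PPG, x_ACC_MA, x_PPG_MA`, the
#'   `tvsp` trajectory, parameters, and solver diagnostics.
#' @export
run_case_wall <- function(params, y, drift = NULL,
                          gains = c(-1 / 3, -1 / 3, -1 / 2),
                          normalizer = "max", g = identity, tvsp = NULL,
                          solver_opts = list()) {
  stopifnot(inherits(params, "tcs_params"), inherits(y, "pulse_signal"))
  if (is.null(drift)) drift <- zero_like(y, "x_b = 0")
  stop_if_grid_mismatch(y, drift, "y and drift")
  if (is.null(tvsp) && any(drift$samples != 0))
    tvsp <- tvsp_from_drift(drift, params, gains = gains,
                            normalizer = normalizer)
  x_C <- simulate_1dof_tv(params, NULL, y, solver_opts)
  x_M <- if (is.null(tvsp)) x_C else simulate_1dof_tv(params, tvsp, y, solver_opts)
  x_TVSP <- ps_combine(x_M, x_C, `-`, label = "x_TVSP")
  x_ACC <- ps_combine(x_M, drift, `+`, label = "x_ACC")
  ma_in <- ps_combine(x_TVSP, drift, `+`)
  x_PPG_MA <- ps_map(ma_in, g, label = "x_PPG_MA")
  x_ACC_MA <- ps_map(ma_in, identity, label = "x_ACC_MA")
  x_PPG <- ps_combine(y, x_PPG_MA, `+`, label = "x_PPG")
  structure(list(time = signal_time(y), y = y, x_b = drift,
                 x_C = x_C, x_M = x_M, x_TVSP = x_TVSP,
                 x_ACC = x_ACC, x_PPG = x_PPG,
                 x_ACC_MA = x_ACC_MA, x_PPG_MA = x_PPG_MA,
                 tvsp = tvsp, params = params, gains = gains,
                 normalizer = normalizer,
                 diagnostics = attr(x_M, "diagnostics")),
            class = "sim_result_1dof")
}

#' Full pulsatile-pressure (2DOF) measurement scenario
#'
#' Converts pressure to wall force, propagates the mass drift `x2b` to the
#' wall drift `x1b`, slaves the TVSPs to the stack compression
#' `x2b - x1b`, and runs the MA-free and perturbed 2DOF simulations.
#' Sensor outputs: accelerometer `x_ACC = x2M + x2b`; PPG
#' `x_PPG = x1M + x1b + g(x2TVSP + x2b)`. Distortions:
#' `x_ACC_MA = x2TVSP + x2b`,
#' `x_PPG_MA = x1TVSP + x1b + g(x2TVSP + x2b)`.
#'
#' @param params a `tcs_params`.
#' @param artery an `artery_params`.
#' @param dp pulsatile pressure as a `pulse_signal`.
#' @param drift baseline drift `x2b` at the mass, or `NULL` for none.
#' @param gains,normalizer TVSP mapping applied to `x2b - x1b`.
#' @param g optical-transduction function (default identity).
#' @param solver_opts passed to the integrators.
#' @return an object of class `sim_result_2dof` with named `pulse_signal`s
#'   `F, x_1b, x_2b, Fb, x_1C, x_2C, x_1M, x_2M, x_1TVSP, x_2TVSP,
#'   x_ACC, x_PPG, x_ACC_MA, x_PPG_MA`, the `tvsp` trajectory, parameters
#'   and diagnostics.
#' @export
run_case_pressure <- function(params, artery, dp, drift = NULL,
                              gains = c(-1 / 3, -1 / 3, -1 / 2),
                              normalizer = "max", g = identity,
                              solver_opts = list()) {
  stopifnot(inherits(params, "tcs_params"), inherits(artery, "artery_params"),
            inherits(dp, "pulse_signal"))
  F <- pressure_to_force(dp, artery)
  if (is.null(drift)) drift <- zero_like(dp, "x_2b = 0")
  stop_if_grid_mismatch(dp, drift, "dp and drift")
  has_drift <- any(drift$samples != 0)
  if (has_drift) {
    pair <- drift_pair_2dof(params, artery, drift, solver_opts)
    x1b <- pair$x1b; Fb <- pair$Fb
    driver <- ps_combine(drift, x1b, `-`, label = "x2b - x1b")
    tvsp <- tvsp_from_drift(driver, params, gains = gains,
                            normalizer = normalizer)
  } else {
    x1b <- zero_like(dp, "x_1b = 0"); Fb <- zero_like(dp, "Fb = 0")
    attr(x1b, "velocity") <- rep(0, length(dp$samples))
    tvsp <- NULL
  }
  lti <- simulate_2dof_tv(params, artery, NULL, F, solver_opts)
  tv <- if (is.null(tvsp)) lti else simulate_2dof_tv(params, artery, tvsp, F, solver_opts)
  x_1TVSP <- ps_combine(tv$x1, lti$x1, `-`, label = "x_1TVSP")
  x_2TVSP <- ps_combine(tv$x2, lti$x2, `-`, label = "x_2TVSP")
  x_ACC <- ps_combine(tv$x2, drift, `+`, label = "x_ACC")
  g2 <- ps_map(ps_combine(x_2TVSP, drift, `+`), g)
  x_ACC_MA <- ps_combine(x_2TVSP, drift, `+`, label = "x_ACC_MA")
  x_PPG <- ps_combine(ps_combine(tv$x1, x1b, `+`), g2, `+`, label = "x_PPG")
  x_PPG_MA <- ps_combine(ps_combine(x_1TVSP, x1b, `+`), g2, `+`,
                         label = "x_PPG_MA")
  structure(list(time = signal_time(dp), F = F, dp = dp,
                 x_1b = x1b, x_2b = drift, Fb = Fb,
                 x_1C = lti$x1, x_2C = lti$x2,
                 x_1M = tv$x1, x_2M = tv$x2,
                 x_1TVSP = x_1TVSP, x_2TVSP = x_2TVSP,
                 x_ACC = x_ACC, x_PPG = x_PPG,
                 x_ACC_MA = x_ACC_MA, x_PPG_MA = x_PPG_MA,
                 tvsp = tvsp, params = params, artery = artery,
                 gains = gains, normalizer = normalizer,
                 diagnostics = attr(tv$x2, "diagnostics")),
            class = "sim_result_2dof")
}

# analytic signal z = x + i H(x) by the FFT construction: zero the negative
# frequencies, double the positive ones
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# unwrap a phase sequence (remove 2*pi jumps)
unwrap_phase <- function(p) {
  d <- diff(p)
  jumps <- round(d / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

#' Instantaneous amplitude, phase, and frequency of a response
#'
#' Because TVSPs make the response non-stationary, its harmonic description
#' needs time-varying attributes. These are computed from the analytic
#' signal (Hilbert transform): amplitude is the envelope, phase the
#' unwrapped argument, and frequency the phase derivative over `2*pi`.
#' Samples where the envelope falls below `mask_rel` times its maximum have
#' phase and frequency masked to `NA` (frequency is undefined at amplitude
#' zeros).
#'
#' @param x a `pulse_signal`, zero-mean over the window (the mean is removed
#'   before the transform).
#' @param mask_rel relative envelope threshold for masking, default 0.01.
#' @return an object of class `instant_attributes`: list with `time`,
#'   `amplitude`, `phase` (rad), `frequency` (Hz).
#' @export
instantaneous_attributes <- function(x, mask_rel = 0.01) {
  stopifnot(inherits(x, "pulse_signal"))
  s <- x$samples - mean(x$samples)
  if (all(s == 0)) {
    n <- length(s)
    return(structure(list(time = signal_time(x), amplitude = rep(0, n),
                          phase = rep(NA_real_, n),
                          frequency = rep(NA_real_, n)),
                     class = "instant_attributes"))
  }
  z <- analytic_signal(s)
  amp <- Mod(z)
  ph <- unwrap_phase(Arg(z))
  freq <- pracma::gradient(ph, 1 / x$fs) / (2 * pi)
  mask <- amp < mask_rel * max(amp)
  ph[mask] <- NA_real_
  freq[mask] <- NA_real_
  structure(list(time = signal_time(x), amplitude = amp, phase = ph,
                 frequency = freq),
            class = "instant_attributes")
}
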