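# Equivalent-force representation of motion artifacts: the nominal
# (time-invariant) stack is kept, and the artifact's influence is moved into
# forces acting on the mass (and, in the 2DOF case, on the arterial wall).

#' Drift force on the 1DOF stack
#'
#' The baseline drift `xb` of the mass is associated with the force
#' `F_b = m0 xb'' + c0 xb' + k0 xb` that the artifact exerts through the
#' stack. Derivatives use the drift's analytic form when available and a
#' cubic-spline interpolant otherwise (the drift is band-limited, so spline
#' derivatives are accurate away from the window edges).
#'
#' @param xb baseline drift as a `pulse_signal`.
#' @param params a `tcs_params`.
#' @return a `pulse_signal` `F_b` on the same grid.
#' @export
drift_force_1dof <- function(xb, params) {
  stopifnot(inherits(xb, "pulse_signal"), inherits(params, "tcs_params"))
  ex <- excitation_fn(xb)
  t <- signal_time(xb)
  Fb <- params$m0 * ex(t, 2L) + params$c0 * ex(t, 1L) + params$k0 * ex(t)
  pulse_signal(Fb, fs = xb$fs, t_start = xb$t_start, label = "F_b")
}

#' Base-excitation force on the 1DOF stack
#'
#' The wall displacement forces the mass through the spring and damper:
#' `F_C = k0 y + c0 y'`. This is the force input the MA-free system sees.
#'
#' @param y wall displacement as a `pulse_signal`.
#' @param params a `tcs_params`.
#' @return a `pulse_signal` `F_C` on the same grid.
#' @export
base_excitation_force <- function(y, params) {
  stopifnot(inherits(y, "pulse_signal"), inherits(params, "tcs_params"))
  ex <- excitation_fn(y)
  t <- signal_time(y)
  pulse_signal(params$k0 * ex(t) + params$c0 * ex(t, 1L),
               fs = y$fs, t_start = y$t_start, label = "F_C")
}

#' Equivalent MA forces for the 1DOF scenario
#'
#' Substitutes the perturbed response into the nominal left-hand side,
#' `F_T = m0 xM'' + c0 xM' + k0 xM`, and decomposes
#' `F_MA = F_TVSP + F_b` with `F_TVSP = F_T - F_C`. Driving the nominal
#' stack with `y` plus `F_MA` reproduces the distorted measurement
#' (see [reconstruct_from_forces()]). Derivatives of `x_M` come from the
#' solver state, not from differencing.
#'
#' @param result a `sim_result_1dof` from [run_case_wall()].
#' @param params a `tcs_params` (defaults to the one stored in `result`).
#' @return an object of class `force_set_1dof`: `pulse_signal`s
#'   `F_b, F_C, F_T, F_TVSP, F_MA` on the shared grid.
#' @export
equivalent_forces_1dof <- function(result, params = result$params) {
  stopifnot(inherits(result, "sim_result_1dof"))
  xM <- result$x_M
  v <- attr(xM, "velocity"); a <- attr(xM, "accel")
  if (is.null(v) || is.null(a))
    stop("result$x_M lacks solver state; rerun run_case_wall()", call. = FALSE)
  F_T <- pulse_signal(params$m0 * a + params$c0 * v + params$k0 * xM$samples,
                      fs = xM$fs, t_start = xM$t_start, label = "F_T")
  F_C <- base_excitation_force(result$y, params)
  F_b <- drift_force_1dof(result$x_b, params)
  F_TVSP <- ps_combine(F_T, F_C, `-`, label = "F_TVSP")
  F_MA <- ps_combine(F_TVSP, F_b, `+`, label = "F_MA")
  structure(list(time = result$time, F_b = F_b, F_C = F_C, F_T = F_T,
                 F_TVSP = F_TVSP, F_MA = F_MA),
            class = "force_set_1dof")
}

#' Equivalent MA forces for the 2DOF scenario
#'
#' Substitutes the perturbed responses into the nominal-parameter left-hand
#' sides of the coupled equations, giving `F_1T` (on the wall) and `F_2T`
#' (on the mass); the MA forces are `F_1MA = F_1TVSP = F_1T - F` and
#' `F_2MA = F_2TVSP + F_b` with `F_2TVSP = F_2T`.
#'
#' @param result a `sim_result_2dof` from [run_case_pressure()].
#' @param params a `tcs_params` (defaults to the stored one).
#' @param artery an `artery_params` (defaults to the stored one).
#' @return an object of class `force_set_2dof`: `pulse_signal`s
#'   `F, F_b, F_1T, F_2T, F_1TVSP, F_2TVSP, F_1MA, F_2MA`.
#' @export
equivalent_forces_2dof <- function(result, params = result$params,
                                   artery = result$artery) {
  stopifnot(inherits(result, "sim_result_2dof"))
  x1 <- result$x_1M; x2 <- result$x_2M
  v1 <- attr(x1, "velocity"); v2 <- attr(x2, "velocity")
  a2 <- attr(x2, "accel")
  if (is.null(v1) || is.null(v2) || is.null(a2))
    stop("result lacks solver state; rerun run_case_pressure()", call. = FALSE)
  kA <- artery$kA
  F_1T <- (kA + params$k0) * x1$samples - params$k0 * x2$samples +
    params$c0 * (v1 - v2)
  F_2T <- params$k0 * (x2$samples - x1$samples) +
    params$c0 * (v2 - v1) + params$m0 * a2
  mk <- function(s, lab) pulse_signal(s, fs = x2$fs, t_start = x2$t_start,
                                      label = lab)
  F_1T <- mk(F_1T, "F_1T"); F_2T <- mk(F_2T, "F_2T")
  F_1TVSP <- ps_combine(F_1T, result$F, `-`, label = "F_1TVSP")
  F_2TVSP <- ps_map(F_2T, identity, label = "F_2TVSP")
  F_2MA <- ps_combine(F_2TVSP, result$Fb, `+`, label = "F_2MA")
  F_1MA <- ps_map(F_1TVSP, identity, label = "F_1MA")
  structure(list(time = result$time, F = result$F, F_b = result$Fb,
                 F_1T = F_1T, F_2T = F_2T,
                 F_1TVSP = F_1TVSP, F_2TVSP = F_2TVSP,
                 F_1MA = F_1MA, F_2MA = F_2MA),
            class = "force_set_2dof")
}

# integrate the nominal LTI 1DOF system under an arbitrary extra force
nominal_1dof_forced <- function(params, y, extra_force, state0 = c(0, 0),
                                solver_opts = list()) {
  so <- default_solver_opts(solver_opts)
  ex <- excitation_fn(y)
  ff <- excitation_fn(extra_force)
  times <- signal_time(y)
  rhs <- function(t, state, parms) {
    a <- (params$k0 * (ex(t) - state[1L]) + params$c0 * (ex(t, 1L) - state[2L]) +
            ff(t)) / params$m0
    list(c(state[2L], a))
  }
  sol <- deSolve::ode(y = c(x = state0[1L], v = state0[2L]), times = times,
                      func = rhs, parms = NULL, method = so$method,
                      rtol = so$rtol, atol = so$atol)
  pulse_signal(sol[, 2L], fs = y$fs, t_start = y$t_start,
               label = "reconstruction")
}

# integrate the nominal LTI 2DOF system under wall force Fw and mass force Fm
nominal_2dof_forced <- function(params, artery, Fw, Fm,
                                state0 = c(0, 0, 0), solver_opts = list()) {
  so <- default_solver_opts(solver_opts)
  fw <- excitation_fn(Fw); fm <- excitation_fn(Fm)
  kA <- artery$kA; k0 <- params$k0; c0 <- params$c0; m0 <- params$m0
  times <- signal_time(Fw)
  rhs <- function(t, state, parms) {
    x1 <- state[1L]; x2 <- state[2L]; v2 <- state[3L]
    v1 <- v2 + (fw(t) - (kA + k0) * x1 + k0 * x2) / c0
    a2 <- (-k0 * (x2 - x1) - c0 * (v2 - v1) + fm(t)) / m0
    list(c(v1, v2, a2))
  }
  sol <- deSolve::ode(y = c(x1 = state0[1L], x2 = state0[2L], v2 = state0[3L]),
                      times = times, func = rhs, parms = NULL,
                      method = so$method, rtol = so$rtol, atol = so$atol)
  list(x1 = pulse_signal(sol[, 2L], fs = Fw$fs, t_start = Fw$t_start,
                         label = "x1 reconstruction"),
       x2 = pulse_signal(sol[, 3L], fs = Fw$fs, t_start = Fw$t_start,
                         label = "x2 reconstruction"))
}

#' Reconstruct the distorted measurement from equivalent forces
#'
#' The closure property of the equivalent-force decomposition: integrating
#' the NOMINAL, time-invariant system driven by the original excitation plus
#' the MA forces reproduces the distorted measurement.
#'
#' * 1DOF: the nominal stack under base excitation `y` plus `F_MA` on the
#'   mass reproduces `x_M + x_b`.
#' * 2DOF: the nominal system under `F_1MA` on the wall and `F_2MA` on the
#'   mass (without the pulse force) reproduces the MA part
#'   `x_i = x_iM + x_ib - x_iC`.
#'
#' Initial conditions are assembled from the simulated components so the
#' reconstruction carries no spurious transient.
#'
#' @param result a `sim_result_1dof` or `sim_result_2dof`.
#' @param forces the matching `force_set_1dof` / `force_set_2dof`.
#' @param tol relative tolerance (against the response scale) above which a
#'   mismatch is an error, default `1e-3`.
#' @param solver_opts solver options for the reconstruction integration.
#' @return list with the reconstructed `pulse_signal`(s), the target(s), and
#'   `max_rel_residual`.
#' @export
reconstruct_from_forces <- function(result, forces, tol = 1e-3,
                                    solver_opts = list()) {
  if (inherits(result, "sim_result_1dof")) {
    stopifnot(inherits(forces, "force_set_1dof"))
    params <- result$params
    # IC: x_M starts from rest; add the drift's initial state
    exb <- excitation_fn(result$x_b)
    t0 <- result$time[1L]
    state0 <- c(result$x_M$samples[1L] + exb(t0),
                attr(result$x_M, "velocity")[1L] + exb(t0, 1L))
    rec <- nominal_1dof_forced(params, result$y, forces$F_MA, state0,
                               solver_opts)
    target <- ps_combine(result$x_M, result$x_b, `+`, label = "x_M + x_b")
    scale <- max(abs(result$x_M$samples))
    res <- max(abs(rec$samples - target$samples)) / scale
    if (res > tol)
      stop(sprintf("1DOF force-closure residual %.3g exceeds tol %.3g",
                   res, tol), call. = FALSE)
    list(reconstruction = rec, target = target, max_rel_residual = res)
  } else if (inherits(result, "sim_result_2dof")) {
    stopifnot(inherits(forces, "force_set_2dof"))
    params <- result$params; artery <- result$artery
    v1b <- attr(result$x_1b, "velocity")
    if (is.null(v1b)) v1b <- rep(0, length(result$time))
    ex2b <- excitation_fn(result$x_2b)
    t0 <- result$time[1L]
    # x_iM and x_iC both start from rest; the drift state remains
    state0 <- c(result$x_1b$samples[1L], result$x_2b$samples[1L], ex2b(t0, 1L))
    rec <- nominal_2dof_forced(params, artery, forces$F_1MA, forces$F_2MA,
                               state0, solver_opts)
    targ1 <- pulse_signal(result$x_1M$samples + result$x_1b$samples -
                            result$x_1C$samples,
                          fs = result$x_1M$fs, t_start = t0,
                          label = "x1M + x1b - x1C")
    targ2 <- pulse_signal(result$x_2M$samples + result$x_2b$samples -
                            result$x_2C$samples,
                          fs = result$x_2M$fs, t_start = t0,
                          label = "x2M + x2b - x2C")
    scale <- max(abs(result$x_2M$samples), abs(result$x_1M$samples))
    res <- max(abs(rec$x1$samples - targ1$samples),
               abs(rec$x2$samples - targ2$samples)) / scale
    if (res > tol)
      stop(sprintf("2DOF force-closure residual %.3g exceeds tol %.3g",
                   res, tol), call. = FALSE)
    list(reconstruction = rec, target = list(x1 = targ1, x2 = targ2),
         max_rel_residual = res)
  } else stop("result must be a sim_result_1dof or sim_result_2dof",
              call. = FALSE)
}
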