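#' Tissue-contact-sensor (TCS) stack parameters
#'
#' The transmission path from artery to sensor is modelled as a 1DOF
#' mass-spring-damper with nominal mass `m0`, stiffness `k0` and damping
#' `c0`, set by the hold-down contact pressure. Derived quantities follow
#' the standard definitions: natural frequency `omega0 = sqrt(k0/m0)`,
#' damping factor `zeta0 = c0 / (2*sqrt(m0*k0))`, and frequency ratio
#' `r0 = omega0 / omegaC` with `omegaC = 2*pi*f_c` the heart-rate frequency.
#'
#' @param m0,k0,c0 nominal mass, stiffness, damping (all > 0, normalized).
#' @param f_c heart-rate fundamental frequency (Hz).
#' @return an object of class `tcs_params` with fields `m0,k0,c0,f_c` and
#'   derived `omega0`, `zeta0`, `r0`, `omegaC`.
#' @seealso [nominal_params()] to construct from the ratio parameterization.
#' @export
tcs_params <- function(m0, k0, c0, f_c) {
  vals <- c(m0 = m0, k0 = k0, c0 = c0, f_c = f_c)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("m0, k0, c0 and f_c must all be positive and finite", call. = FALSE)
  omega0 <- sqrt(k0 / m0)
  omegaC <- 2 * pi * f_c
  structure(list(m0 = m0, k0 = k0, c0 = c0, f_c = f_c,
                 omega0 = omega0, omegaC = omegaC,
                 zeta0 = c0 / (2 * sqrt(m0 * k0)), r0 = omega0 / omegaC),
            class = "tcs_params")
}

#' @export
print.tcs_params <- function(x, ...) {
  cat(sprintf(
    "<tcs_params> m0=%.4g k0=%.4g c0=%.4g | f_c=%g Hz, r0=%.4g, zeta0=%.4g\n",
    x$m0, x$k0, x$c0, x$f_c, x$r0, x$zeta0))
  invisible(x)
}

#' Nominal TCS parameters from the ratio parameterization
#'
#' Sets the nominal stack the way the model is usually specified: the stack
#' stiffness as a fraction of the arterial-wall stiffness
#' (`k0 = k0_over_kA * kA`), the frequency ratio `r0 = omega0/omegaC`, and
#' the damping factor `zeta0`. Defaults `r0 = 2`, `zeta0 = 1.5`,
#' `k0 = kA/6` describe a taped sensor over the carotid artery.
#'
#' @param r0 frequency ratio (> 0), default 2.
#' @param zeta0 damping factor (> 0), default 1.5.
#' @param k0_over_kA stack-to-wall stiffness ratio (> 0), default 1/6.
#' @param f_c heart-rate frequency (Hz), default 1.
#' @param kA arterial-wall stiffness (> 0), default 1 (normalized).
#' @return a `tcs_params`.
#' @examples
#' p <- nominal_params()
#' c(p$k0, p$m0, p$c0)  # 1/6, 1/(96*pi^2), 3*sqrt(m0/6)
#' @export
nominal_params <- function(r0 = 2, zeta0 = 1.5, k0_over_kA = 1 / 6,
                           f_c = 1, kA = 1) {
  vals <- c(r0 = r0, zeta0 = zeta0, k0_over_kA = k0_over_kA,
            f_c = f_c, kA = kA)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all of r0, zeta0, k0_over_kA, f_c, kA must be positive; got: ",
         paste(sprintf("%s=%g", names(vals), vals), collapse = ", "),
         call. = FALSE)
  k0 <- k0_over_kA * kA
  m0 <- k0 / (r0 * 2 * pi * f_c)^2
  c0 <- 2 * zeta0 * sqrt(m0 * k0)
  tcs_params(m0 = m0, k0 = k0, c0 = c0, f_c = f_c)
}

#' Time-varying system-parameter (TVSP) trajectory
#'
#' Baseline drift alters the prestress in the tissue and thereby perturbs
#' the stack parameters: `m(t) = m0 + dm(t)` etc. [tvsp_from_drift()] builds
#' the trajectory from a drift waveform; this constructor validates an
#' explicit one.
#'
#' @param time time grid (s), shared with the simulation.
#' @param dm,dk,dc perturbations of mass, stiffness, damping (same units as
#'   the nominal values).
#' @param params the `tcs_params` whose invariants
#'   (`m0+dm > 0`, `k0+dk > 0`, `c0+dc >= 0`) are enforced.
#' @return an object of class `tvsp_trajectory`.
#' @export
tvsp_trajectory <- function(time, dm, dk, dc, params) {
  stopifnot(inherits(params, "tcs_params"))
  n <- length(time)
  if (length(dm) != n || length(dk) != n || length(dc) != n)
    stop("dm, dk, dc must match the time grid length", call. = FALSE)
  if (any(params$m0 + dm <= 0))
    stop("TVSP invariant violated: m0 + dm(t) <= 0 (mass gain too large)",
         call. = FALSE)
  if (any(params$k0 + dk <= 0))
    stop("TVSP invariant violated: k0 + dk(t) <= 0 (stiffness gain too large)",
         call. = FALSE)
  if (any(params$c0 + dc < 0))
    stop("TVSP invariant violated: c0 + dc(t) < 0 (damping gain too large)",
         call. = FALSE)
  structure(list(time = as.numeric(time), dm = as.numeric(dm),
                 dk = as.numeric(dk), dc = as.numeric(dc)),
            class = "tvsp_trajectory")
}

#' Map baseline drift to TVSPs
#'
#' The TVSPs are assumed to vary linearly with the (normalized) drift:
#' `dk(t) = gk * k0 * xb(t)/M`, `dc(t) = gc * c0 * xb(t)/M`,
#' `dm(t) = gm * m0 * xb(t)/M`, where `M` is the drift normalizer. The
#' default gains `(-1/3, -1/3, -1/2)` make the mass vary faster with drift
#' than the stiffness, lowering the natural frequency as the stack
#' lengthens. Because the drift enters only through `xb/M`, the trajectory
#' is invariant to the drift's amplitude scale.
#'
#' @param drift baseline drift as a `pulse_signal`.
#' @param params a `tcs_params`.
#' @param gains numeric length-3 `(gk, gc, gm)`, default `c(-1/3, -1/3, -1/2)`.
#' @param normalizer `"max"` (default; the drift's positive maximum, which
#'   must be > 0), `"absmax"` (peak absolute value, for predominantly
#'   negative drifts), or a positive number used directly.
#' @return a `tvsp_trajectory` on the drift's grid.
#' @export
tvsp_from_drift <- function(drift, params, gains = c(-1 / 3, -1 / 3, -1 / 2),
                            normalizer = "max") {
  stopifnot(inherits(drift, "pulse_signal"), inherits(params, "tcs_params"))
  if (length(gains) != 3L) stop("gains must be (gk, gc, gm)", call. = FALSE)
  M <- if (is.numeric(normalizer)) {
    if (normalizer <= 0) stop("numeric normalizer must be > 0", call. = FALSE)
    normalizer
  } else switch(match.arg(normalizer, c("max", "absmax")),
    max = {
      m <- max(drift$samples)
      if (m <= 0)
        stop("normalizer 'max' needs a drift with a positive maximum; ",
             "use 'absmax' or a numeric normalizer", call. = FALSE)
      m
    },
    absmax = {
      m <- max(abs(drift$samples))
      if (m == 0) stop("cannot normalize an identically zero drift", call. = FALSE)
      m
    })
  u <- drift$samples / M
  dk <- gains[1] * params$k0 * u
  dc <- gains[2] * params$c0 * u
  dm <- gains[3] * params$m0 * u
  if (any(params$k0 + dk <= 0))
    stop("stiffness gain gk drives k0 + dk(t) non-positive", call. = FALSE)
  if (any(params$m0 + dm <= 0))
    stop("mass gain gm drives m0 + dm(t) non-positive", call. = FALSE)
  if (any(params$c0 + dc < 0))
    stop("damping gain gc drives c0 + dc(t) negative", call. = FALSE)
  tvsp_trajectory(signal_time(drift), dm = dm, dk = dk, dc = dc,
                  params = params)
}

#' MA-free transfer function of the 1DOF stack (base excitation)
#'
#' Complex ratio of the mass displacement to the wall displacement at
#' angular frequency `omega = 2*pi*f`:
#' `G0 * exp(1i*phi0) = (k0 + 1i*c0*omega) / (k0 - m0*omega^2 + 1i*c0*omega)`.
#' At f = 0 the gain is exactly 1 (the mass rides the wall statically).
#'
#' @param params a `tcs_params`.
#' @param f frequency in Hz (vectorized, >= 0).
#' @return complex gain(s).
#' @export
transfer_1dof <- function(params, f) {
  stopifnot(inherits(params, "tcs_params"))
  if (any(f < 0)) stop("f must be >= 0", call. = FALSE)
  w <- 2 * pi * f
  (params$k0 + 1i * params$c0 * w) /
    (params$k0 - params$m0 * w^2 + 1i * params$c0 * w)
}

#' MA-free transfer functions of the 2DOF stack (pressure excitation)
#'
#' With the arterial wall as a spring `kA` in series with the stack, the
#' MA-free displacements at the wall (`x1C`) and at the mass (`x2C`) per
#' unit wall force are, with `Z = k0 + 1i*c0*omega` and
#' `D = Z - m0*omega^2`:
#' `G10 = 1 / (kA - Z*m0*omega^2 / D)` and `G20 = Z / (kA*D - Z*m0*omega^2)`.
#' Both reduce to `1/kA` at f = 0. These closed forms are equivalent to the
#' 2x2 frequency-domain solve of the equations of motion (asserted in the
#' test suite).
#'
#' @param params a `tcs_params`.
#' @param artery an `artery_params`.
#' @param f frequency in Hz (vectorized, >= 0).
#' @return a list with complex vectors `G10` (wall) and `G20` (mass), in
#'   1/stiffness units.
#' @export
transfer_2dof <- function(params, artery, f) {
  stopifnot(inherits(params, "tcs_params"), inherits(artery, "artery_params"))
  if (any(f < 0)) stop("f must be >= 0", call. = FALSE)
  w <- 2 * pi * f
  Z <- params$k0 + 1i * params$c0 * w
  D <- Z - params$m0 * w^2
  G10 <- 1 / (artery$kA - Z * params$m0 * w^2 / D)
  G20 <- Z / (artery$kA * D - Z * params$m0 * w^2)
  list(G10 = G10, G20 = G20)
}

#' Serialize TCS/scenario parameters to a flat list
#'
#' @param params a `tcs_params`.
#' @param artery optional `artery_params`.
#' @param gains TVSP gains `(gk, gc, gm)`.
#' @param normalizer TVSP normalizer mode.
#' @return a plain named list suitable for YAML/JSON.
#' @export
params_to_config <- function(params, artery = NULL,
                             gains = c(-1 / 3, -1 / 3, -1 / 2),
                             normalizer = "max") {
  out <- list(r0 = params$r0, zeta0 = params$zeta0,
              f_c = params$f_c, k0 = params$k0, m0 = params$m0,
              c0 = params$c0, gains = as.numeric(gains),
              normalizer = normalizer)
  if (!is.null(artery)) {
    out$kA <- artery$kA
    out$a <- artery$a
    out$k0_over_kA <- params$k0 / artery$kA
  }
  out
}

#' Rebuild parameters from a flat config list
#'
#' Accepts the mapping written by [params_to_config()] or a hand-written one
#' with fields `r0, zeta0, k0_over_kA, kA, f_c` (ratio form) or
#' `m0, k0, c0, f_c` (direct form).
#'
#' @param cfg a named list.
#' @return a list with elements `params` (`tcs_params`), `artery`
#'   (`artery_params` or NULL), `gains`, `normalizer`.
#' @export
config_to_params <- function(cfg) {
  params <- if (all(c("m0", "k0", "c0", "f_c") %in% names(cfg))) {
    tcs_params(cfg$m0, cfg$k0, cfg$c0, cfg$f_c)
  } else if (all(c("r0", "zeta0", "k0_over_kA", "f_c") %in% names(cfg))) {
    nominal_params(cfg$r0, cfg$zeta0, cfg$k0_over_kA, cfg$f_c,
                   kA = if (is.null(cfg$kA)) 1 else cfg$kA)
  } else stop("config must provide m0/k0/c0/f_c or r0/zeta0/k0_over_kA/f_c",
              call. = FALSE)
  artery <- if (!is.null(cfg$kA))
    artery_params(kA = cfg$kA, a = if (is.null(cfg$a)) 1 / pi else cfg$a)
  list(params = params, artery = artery,
       gains = if (is.null(cfg$gains)) c(-1 / 3, -1 / 3, -1 / 2)
               else as.numeric(cfg$gains),
       normalizer = if (is.null(cfg$normalizer)) "max" else cfg$normalizer)
}
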