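test_that("zero excitation from rest stays at rest", {
  p <- nominal_params()
  y0 <- pulse_signal(rep(0, 400), fs = 100)
  x <- simulate_1dof_tv(p, NULL, y0)
  expect_lt(max(abs(x$samples)), 1e-12)
  tv <- tvsp_from_drift(make_baseline_drift(drift_spec(), 4, 100), p)
  xtv <- simulate_1dof_tv(p, tv, y0)
  expect_lt(max(abs(xtv$samples)), 1e-12)

  art <- default_artery()
  F0 <- pulse_signal(rep(0, 400), fs = 100)
  r <- simulate_2dof_tv(p, art, NULL, F0)
  expect_lt(max(abs(r$x1$samples)), 1e-12)
  expect_lt(max(abs(r$x2$samples)), 1e-12)
})

test_that("LTI 1DOF steady state reproduces the closed-form gain and phase", {
  p <- nominal_params()
  y <- make_harmonic_pulse(harmonic_spec(1, 1, 1), duration = 8, fs = 200)
  x <- simulate_1dof_tv(p, NULL, y)
  G <- transfer_1dof(p, 1)
  amp <- steady_amplitude(x, 4)
  expect_equal(amp, Mod(G), tolerance = 1e-3)
  # phase via projection on the steady window (integer periods)
  keep <- signal_time(x) >= 4 & signal_time(x) < 8
  t <- signal_time(x)[keep]
  z <- 2 * mean(x$samples[keep] * exp(-2i * pi * t))
  expect_equal(Arg(z), Arg(G), tolerance = 1e-3)
})

test_that("a constant stiffness offset equals the re-parameterized LTI system", {
  p <- nominal_params()
  y <- make_harmonic_pulse(harmonic_spec(1, 1, 1), duration = 6, fs = 200)
  t <- signal_time(y)
  n <- length(t)
  tv <- tvsp_trajectory(t, dm = rep(0, n), dk = rep(-p$k0 / 3, n),
                        dc = rep(0, n), params = p)
  x_tv <- simulate_1dof_tv(p, tv, y)
  p_eq <- tcs_params(m0 = p$m0, k0 = 2 * p$k0 / 3, c0 = p$c0, f_c = p$f_c)
  x_eq <- simulate_1dof_tv(p_eq, NULL, y)
  expect_lt(max(abs(x_tv$samples - x_eq$samples)) / max(abs(x_eq$samples)),
            1e-6)
})

test_that("the LTI response obeys superposition", {
  p <- nominal_params()
  y1 <- make_harmonic_pulse(harmonic_spec(1, 1, 1), 5, 200)
  y2 <- make_harmonic_pulse(harmonic_spec(1, 3, 0.5, pi / 3), 5, 200)
  ysum <- pulse_signal(y1$samples + y2$samples, fs = 200)
  xs <- simulate_1dof_tv(p, NULL, ysum)
  x1 <- simulate_1dof_tv(p, NULL, y1)
  x2 <- simulate_1dof_tv(p, NULL, y2)
  expect_lt(max(abs(xs$samples - x1$samples - x2$samples)) /
              max(abs(xs$samples)), 1e-6)
})

test_that("LTI 2DOF steady state matches the closed-form transfer functions", {
  p <- nominal_params()
  art <- default_artery()
  Fh <- make_harmonic_pulse(harmonic_spec(1, 1, 1), 8, 200)
  r <- simulate_2dof_tv(p, art, NULL, Fh)
  G <- transfer_2dof(p, art, 1)
  expect_equal(steady_amplitude(r$x1, 4), Mod(G$G10), tolerance = 1e-3)
  expect_equal(steady_amplitude(r$x2, 4), Mod(G$G20), tolerance = 1e-3)
})

test_that("a stiff arterial wall reduces the 2DOF system to the 1DOF one", {
  p <- nominal_params()
  art <- artery_params(kA = 1e4 * p$k0)
  Fh <- make_harmonic_pulse(harmonic_spec(1, 1, 1), 8, 200)
  # the near-rigid wall makes the system stiff; use an implicit solver
  r <- simulate_2dof_tv(p, art, NULL, Fh,
                        solver_opts = list(method = "lsoda"))
  a1 <- steady_amplitude(r$x1, 4)
  a2 <- steady_amplitude(r$x2, 4)
  expect_equal(a1, 1 / art$kA, tolerance = 0.01)       # x1 ~ F / kA
  expect_equal(a2 / a1, Mod(transfer_1dof(p, 1)), tolerance = 0.01)
})

test_that("drift propagation to the wall satisfies the force balance", {
  p <- nominal_params()
  art <- default_artery()
  # static drift: x1b = C k0/(kA+k0), Fb = C k0 kA/(kA+k0)
  C <- 0.5
  x2b <- pulse_signal(rep(C, 800), fs = 200)
  pair <- drift_pair_2dof(p, art, x2b)
  expect_equal(pair$x1b$samples[400], C * p$k0 / (art$kA + p$k0),
               tolerance = 1e-9)
  expect_equal(pair$Fb$samples[400], C * p$k0 * art$kA / (art$kA + p$k0),
               tolerance = 1e-9)
  # zero drift
  z <- pulse_signal(rep(0, 200), fs = 100)
  pz <- drift_pair_2dof(p, art, z)
  expect_true(all(abs(pz$x1b$samples) < 1e-14) &&
                all(abs(pz$Fb$samples) < 1e-14))
  # harmonic drift: steady complex ratio (k0 + i c0 w)/(kA + k0 + i c0 w)
  wb <- 2 * pi * 0.2
  x2h <- make_harmonic_pulse(harmonic_spec(0.2, 1, 1), duration = 20, fs = 200)
  ph <- drift_pair_2dof(p, art, x2h)
  H <- (p$k0 + 1i * p$c0 * wb) / (art$kA + p$k0 + 1i * p$c0 * wb)
  expect_equal(steady_amplitude(ph$x1b, 10), Mod(H), tolerance = 1e-3)
})

test_that("drift-pair residuals vanish against independent derivatives", {
  p <- nominal_params()
  art <- default_artery()
  x2b <- default_drift()
  pair <- drift_pair_2dof(p, art, x2b)
  t <- signal_time(x2b)
  d1b <- stats::splinefun(t, pair$x1b$samples)(t, deriv = 1L)
  d2b <- stats::splinefun(t, x2b$samples)(t, deriv = 1L)
  dd2b <- stats::splinefun(t, x2b$samples)(t, deriv = 2L)
  keep <- t > 1 & t < max(t) - 1  # interior (spline edges excluded)
  res_a <- (art$kA + p$k0) * pair$x1b$samples - p$k0 * x2b$samples +
    p$c0 * (d1b - d2b)
  res_b <- p$k0 * (x2b$samples - pair$x1b$samples) + p$c0 * (d2b - d1b) +
    p$m0 * dd2b - pair$Fb$samples
  scale <- max(abs(pair$Fb$samples))
  expect_lt(max(abs(res_a[keep])) / scale, 1e-6)
  expect_lt(max(abs(res_b[keep])) / scale, 1e-6)
})

test_that("the 1DOF decomposition identities hold exactly", {
  p <- nominal_params()
  y <- default_pulse(6)
  # MA-free: sensor outputs reduce to the clean responses
  free <- run_case_wall(p, y, drift = NULL)
  expect_identical(free$x_ACC$samples, free$x_C$samples)
  expect_identical(free$x_PPG$samples, free$y$samples)
  # identity transduction: x_PPG - y = x_ACC - x_C pointwise
  res <- run_case_wall(p, y, default_drift(6))
  expect_equal(res$x_PPG$samples - res$y$samples,
               res$x_ACC$samples - res$x_C$samples, tolerance = 1e-14)
  # reconstruction identity to machine precision
  expect_lt(max(abs(res$x_ACC$samples - res$x_C$samples -
                      res$x_b$samples - res$x_TVSP$samples)), 1e-14)
})

test_that("the 2DOF scenario honours its static limit and identities", {
  p <- nominal_params()
  art <- default_artery()
  dp <- default_pulse(6)
  free <- run_case_pressure(p, art, dp, drift = NULL)
  expect_identical(free$x_ACC$samples, free$x_2C$samples)
  expect_identical(free$x_PPG$samples, free$x_1C$samples)
  # static pressure, zero drift: x1C = x2C = pi a dp / kA after the transient
  dpc <- pulse_signal(rep(0.8, 1200), fs = 200)
  st <- run_case_pressure(p, art, dpc, drift = NULL)
  expected <- pi * art$a * 0.8 / art$kA
  expect_equal(st$x_1C$samples[1000], expected, tolerance = 1e-6)
  expect_equal(st$x_2C$samples[1000], expected, tolerance = 1e-6)
  # decomposition identities
  res <- pressure_default_run()
  expect_lt(max(abs(res$x_ACC$samples - res$x_2M$samples -
                      res$x_2b$samples)), 1e-14)
  expect_lt(max(abs(res$x_2M$samples - res$x_2C$samples -
                      res$x_2TVSP$samples)), 1e-14)
})

test_that("time-varying 2DOF responses satisfy the equations of motion", {
  # commensurate drift (0.25 Hz) and pulse (1 Hz): the steady state is
  # periodic over 4 s, so spectral differentiation of an integer window
  # gives solver-independent derivatives
  p <- nominal_params()
  art <- default_artery()
  fs <- 200
  dp <- make_harmonic_pulse(carotid_harmonic_spec(), duration = 10, fs = fs)
  dr <- make_baseline_drift(
    drift_spec(components = data.frame(freq = 0.25, amp = 1)),
    duration = 10, fs = fs)
  res <- run_case_pressure(p, art, dp, dr)
  # discard enough lead-in for the slowest mode (~4.8 1/s) to die out, so
  # the window is periodic to solver precision
  i0 <- which.min(abs(res$time - 6))
  idx <- i0:(i0 + 4 * fs - 1)              # exactly one drift period
  specd <- function(v, order) {
    n <- length(v)
    k <- c(0:(n / 2), -(n / 2 - 1):-1)
    if (order %% 2 == 1) k[n / 2 + 1] <- 0
    w <- (2i * pi * k * fs / n)^order
    Re(stats::fft(stats::fft(v) * w, inverse = TRUE) / n)
  }
  x1 <- res$x_1M$samples[idx]; x2 <- res$x_2M$samples[idx]
  v1 <- specd(x1, 1); v2 <- specd(x2, 1); a2 <- specd(x2, 2)
  tt <- res$time[idx]
  tvk <- stats::splinefun(res$tvsp$time, res$tvsp$dk)(tt)
  tvc <- stats::splinefun(res$tvsp$time, res$tvsp$dc)(tt)
  tvm <- stats::splinefun(res$tvsp$time, res$tvsp$dm)(tt)
  Fv <- res$F$samples[idx]
  res_a <- (art$kA + p$k0 + tvk) * x1 - (p$k0 + tvk) * x2 +
    (p$c0 + tvc) * (v1 - v2) - Fv
  res_b <- (p$k0 + tvk) * (x2 - x1) + (p$c0 + tvc) * (v2 - v1) +
    (p$m0 + tvm) * a2
  scale <- max(abs(Fv))
  expect_lt(max(abs(res_a)) / scale, 1e-6)
  expect_lt(max(abs(res_b)) / scale, 1e-6)
})

test_that("TVSP distortion is invariant to the drift amplitude", {
  p <- nominal_params()
  y <- default_pulse(6)
  r1 <- run_case_wall(p, y, default_drift(6))
  d5 <- make_baseline_drift(drift_spec(amplitude = 5), 6, 200)
  r5 <- run_case_wall(p, y, d5)
  expect_lt(max(abs(r1$x_TVSP$samples - r5$x_TVSP$samples)) /
              max(abs(r1$x_TVSP$samples)), 1e-6)
  # while the additive part scales
  expect_equal(max(abs(r5$x_b$samples)), 5 * max(abs(r1$x_b$samples)),
               tolerance = 1e-9)
})

test_that("solutions converge under tolerance refinement", {
  p <- nominal_params()
  y <- default_pulse(4)
  tv <- tvsp_from_drift(default_drift(4), p)
  x1 <- simulate_1dof_tv(p, tv, y)
  x2 <- simulate_1dof_tv(p, tv, y, solver_opts = list(rtol = 5e-9, atol = 5e-11))
  expect_lt(max(abs(x1$samples - x2$samples)) / max(abs(x1$samples)), 1e-4)
})

test_that("instantaneous attributes recover amplitude and frequency", {
  t <- seq(0, 10, by = 1 / 100)
  x <- pulse_signal(cos(2 * pi * t), fs = 100)
  ia <- instantaneous_attributes(x)
  interior <- ia$time > 1 & ia$time < 9
  expect_equal(mean(ia$amplitude[interior]), 1, tolerance = 0.005)
  expect_equal(mean(ia$frequency[interior], na.rm = TRUE), 1,
               tolerance = 0.005)
  expect_true(all(abs(ia$frequency[interior] - 1) < 0.01))
  # amplitude-modulated cosine: envelope recovered within 2% interior
  env <- 1 + 0.1 * sin(0.2 * pi * t)
  xm <- pulse_signal(env * cos(2 * pi * t), fs = 100)
  iam <- instantaneous_attributes(xm)
  expect_lt(max(abs(iam$amplitude[interior] - env[interior]) / env[interior]),
            0.02)
  # zero signal: masked
  z <- pulse_signal(rep(0, 100), fs = 100)
  iz <- instantaneous_attributes(z)
  expect_true(all(is.na(iz$frequency)))
  expect_true(all(iz$amplitude == 0))
})
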