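---
title: "Modelling motion artifacts in measured arterial pulse signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling motion artifacts in measured arterial pulse signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

A wearable sensor — an accelerometer or a PPG sensor taped over the carotid
artery — never records the arterial pulse directly. The signal travels
through the tissue, the tissue–sensor contact, and the sensor body: the
tissue–contact–sensor (TCS) stack. `pulsema` models this transmission path
as a mass–spring–damper system and asks what motion artifacts (MAs) do to
the measured signal.

The central point of the model is that an MA acts **twice**:

1. It displaces the sensor relative to the artery — the familiar
   *baseline drift* `x_b(t)`, additive low-frequency (< 0.7 Hz at rest)
   noise.
2. By changing the stack's length it changes the prestress in the tissue
   and therefore the stack's mass, damping, and stiffness — *time-varying
   system parameters* (TVSPs) `m(t), c(t), k(t)`. Because the system
   parameters multiply the true pulse, this second pathway is
   **multiplicative** noise: it puts low-amplitude sidebands around every
   harmonic of the pulse, which no low-pass-style baseline removal can
   touch.

## The model

### Wall displacement as the true pulse (1DOF)

The arterial wall displacement `y(t)` — a sum of harmonics of the heart
rate `f_c` — is the base excitation of a single-degree-of-freedom system
with nominal parameters `m0, c0, k0`:

```
(m0 + dm(t)) x'' + (c0 + dc(t)) x' + (k0 + dk(t)) x
    = (k0 + dk(t)) y + (c0 + dc(t)) y'
```

With all perturbations zero the response is the MA-free signal `x_C(t)`,
related to `y` harmonic by harmonic through

```
G0 e^{i phi0} = (k0 + i c0 w) / (k0 - m0 w^2 + i c0 w),   w = 2 pi f .
```

The perturbed response `x_M` defines the TVSP distortion
`x_TVSP = x_M - x_C`. The sensor outputs are assembled as

```
x_ACC = x_M + x_b                 (accelerometer, displacement units)
x_PPG = y + g(x_TVSP + x_b)       (PPG; g = optical transduction, default identity)
```

### Pulsatile pressure as the true pulse (2DOF)

When the pulsatile pressure `dp(t)` is taken as the true signal, the
arterial wall itself (a spring `kA`, inertia and damping neglected) joins
the system. The pressure loads the wall with `F = pi * a * dp`, and the
wall (`x1`) and mass (`x2`) displacements obey the coupled equations
implemented in `simulate_2dof_tv()`. A drift `x2b` imposed at the mass
drags the wall along (`drift_pair_2dof()` solves the first-order force
balance for `x1b` and the associated artifact force `Fb`), and the TVSPs
are slaved to the stack compression `x2b - x1b`.

### TVSPs slaved to drift

Lacking a tissue-mechanics law, the TVSPs are taken linear in the
normalized drift:

```
dk = -(k0/3) xb/M,   dc = -(c0/3) xb/M,   dm = -(m0/2) xb/M,
```

with `M = max(xb)`. The mass gain is larger than the stiffness gain so the
natural frequency falls as the stack lengthens. The gains are exposed
(`gains` argument) so the linearity assumption can be stress-tested; the
trajectory is invariant to the drift's amplitude scale by construction,
which the test suite asserts.

Two interpretation choices here were genuinely open:

* **The normalizer.** `max(xb)` (the positive maximum) is the default; a
  predominantly negative drift would make it meaningless, so an `"absmax"`
  mode and a numeric override exist.
* **`r_total(t)`** (the frequency ratio including the wall spring) uses the
  series stiffness `kA*(k0+dk)/(kA+k0+dk)` — the stiffness the mass
  actually sees through the two springs. This is an interpretation, not a
  unique definition, and is documented as such.

### Equivalent forces

The artifact can equivalently be moved out of the parameters and into
forces on the *nominal, time-invariant* system:
`F_T = m0 x_M'' + c0 x_M' + k0 x_M`, `F_C = k0 y + c0 y'`,
`F_TVSP = F_T - F_C`, `F_b = m0 x_b'' + c0 x_b' + k0 x_b`, and
`F_MA = F_TVSP + F_b`. The master property — asserted by
`reconstruct_from_forces()` and the test suite — is closure: integrating
the nominal system under `y` plus `F_MA` reproduces `x_M + x_b` to better
than 1e-3 relative. The 2DOF analogue drives the nominal coupled system
with `F_1MA` on the wall and `F_2MA` on the mass and reproduces
`x_iM + x_ib - x_iC`. While `F_b` is linear in the drift, `F_TVSP` depends
only on the drift's shape — a signature separating the additive from the
multiplicative pathway.

## Synthetic inputs

No measured data ship with the package; the generators produce the study
conditions:

* `carotid_harmonic_spec()` — 10 harmonics, amplitudes `0.6^(n-1)`, phases
  `-n*pi/2`. A measured carotid pulse is not reproducible here; any
  multi-harmonic waveform with a decaying envelope exercises the same
  transmission-path mathematics. The geometric decay and phase ramp give a
  realistic sharp systolic upstroke.
* `make_synthetic_apw()` — two wrapped-Gaussian bumps per cycle (systolic
  at 15% of the cycle, width 5%; dicrotic at 45%, width 9%, height 0.4):
  a physiologic-looking waveform with a well-defined foot for testing the
  cycle-segmentation code.
* `make_baseline_drift()` — the default drift is the two-tone
  `0.7 sin(2 pi 0.2 t) + 0.3 sin(2 pi 0.35 t)`, rescaled to unit peak;
  a seeded `random-smooth` kind (spline through random knots, then a hard
  frequency-domain truncation at the 0.7 Hz band limit) provides
  irregular but reproducible drifts.

What these generators do **not** emulate: respiration-driven amplitude and
frequency modulation of the pulse, beat-to-beat physiological variability,
nonlinearity of the tissue, and motion in the sensor's transverse axes.
Passing tests therefore demonstrate the internal consistency of the
mechanical model under idealized excitation, not fidelity to any
individual's recorded pulse.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `f_c` | heart rate (Hz) | 1 (60 bpm) | resting adult rate |
| `r0` | natural freq. / heart-rate freq. | 2 | taped sensor over the carotid artery |
| `zeta0` | damping factor | 1.5 | overdamped tissue contact |
| `k0_over_kA` | stack / wall stiffness | 1/6 | soft tissue against a stiff wall |
| `kA` | wall stiffness | 1 | normalization anchor |
| `a` | effective artery radius | `1/pi` | makes `pi*a = 1`, so pressure and force share scale |
| gains | TVSP per-unit-drift | `(-1/3, -1/3, -1/2)` | mass varies faster than stiffness |
| `fs` | sampling rate (Hz) | 200 | 20 samples per period of the 10th harmonic |
| band limit | drift bandwidth (Hz) | 0.7 | at-rest MA band |

All units are normalized (`kA = 1`, pulse amplitude O(1)); every output is
a dimensionless ratio. The model's behaviour depends only on the ratios
`r0`, `zeta0`, `k0/kA`, so nothing is lost.

## Numerical choices

* **Integration**: deSolve's Dormand–Prince 4(5) pair (`"ode45"`),
  `rtol = 1e-8`, `atol = 1e-10`, dense output on the excitation grid. The
  near-rigid-wall limit makes the 2DOF system stiff; `solver_opts =
  list(method = "lsoda")` handles it.
* **Initial conditions and transients**: integration starts from rest and
  analyses discard a two-cycle lead-in — more than `5/(zeta0*omega0)`
  (~0.27 s at the defaults), so the transient is far below solver
  tolerance in the analysis window.
* **Derivatives**: excitation derivatives are analytic whenever the signal
  carries its harmonic description; simulated-response derivatives come
  from the solver state (velocity) and the ODE right-hand side
  (acceleration); tabulated band-limited signals are differentiated by a
  cubic-spline interpolant. Output series are never finite-differenced.
* **Foot detection**: the minimum preceding each maximal upstroke
  (centered-derivative peak, 30% prominence threshold, 0.6-period
  separation), searched 0.8 period back, ties to the earliest sample; a
  minimum pinned to the window edge is rejected. Foot times are refined by
  three-point parabolic interpolation so per-cycle heart rate is not
  quantized to the sample period. A slow additive trend moves a detected
  foot by roughly (trend slope)/(foot curvature) — negligible for a curved
  foot, but a truncated harmonic series has low-level ripple at its foot,
  so foot placement there is sensitive at the ripple scale. The same
  detector is applied to every signal compared, so heart-rate differences
  reflect signal distortion, not detector changes.
* **Spectra**: rectangular window over the post-lead-in window, zero-pad
  factor 4; Parseval consistency is asserted in the tests.
* **Sidebands**: per-harmonic band energies require disjoint bands
  (half-width <= `f_c/2`; `sideband_report()` errors otherwise); the
  union-of-bands energy fraction for any width (e.g. the +/-0.7 Hz drift
  band) is `band_energy_fraction()`.
* **CSE baseline**: natural cubic spline through the analyzed signal's own
  foot points, no pre-filtering — the standard estimator, applied exactly
  so its failure to recover the true drift under TVSP distortion is a
  model result, not an artifact of extra processing.

## Canonical scenario and problem sizes

The packaged presets (`scenario_preset("wall-default")`,
`"pressure-default"`) simulate 12 cycles at `fs = 200` Hz and analyze the
last 10. That length keeps every run in the seconds range while giving 10
clean cycles, a 0.1 Hz raw spectral resolution (0.025 Hz zero-padded), and
stable per-cycle statistics; the test suite uses shorter windows where a
property does not need the full length.

Under the canonical wall scenario the TVSP-only distortion changes
per-cycle pulse amplitude by well under 5% and per-cycle heart rate by
under 1% — small in the time domain, but concentrated as sidebands around
every harmonic (over 85% of the distortion energy within +/-0.7 Hz of
harmonics 1–10, with the second harmonic amplified because `r0 = 2` parks
it on the stack's natural frequency). `scripts/acceptance.R` recomputes
the two headline percentages from scratch.

## Known limitations

* The TCS stack is linear and its TVSPs exactly linear in drift; both are
  modelling assumptions, adjustable only in gain, not in functional form.
* The true pulse is assumed unaffected by the measurement; the 2DOF case
  relaxes this only as far as a spring-loaded wall.
* Optical transduction enters as a pluggable `g(.)` with identity default;
  real PPG transduction is considerably more complex.
* Foot-based cycle boundaries are one convention among several; absolute
  per-cycle heart-rate deviations depend on it, and only like-for-like
  comparisons (same detector on all signals) are meaningful.
* The inverse problem — estimating TVSPs or equivalent forces from a
  measured signal — is out of scope.
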