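# pulsema

Motion-artifact modelling for arterial pulse measurement by accelerometers
and PPG sensors.

## The problem

Wearable pulse sensors read the artery through a mechanical transmission
path — the tissue, the tissue–sensor contact, and the sensor body (the
**TCS stack**). Motion artifacts (MAs) are usually treated as *baseline
drift*: additive low-frequency (< 0.7 Hz at rest) wander that filtering or
cubic-spline estimation can remove. But the same motion that displaces the
sensor also changes the stack's prestress, and with it the stack's mass,
damping and stiffness — **time-varying system parameters (TVSPs)**. TVSP
distortion is *multiplicative*: it rides on every harmonic of the pulse as
low-amplitude sidebands that no baseline-removal scheme can touch, and it
perturbs exactly the waveform features (per-cycle amplitude, foot timing,
harmonic content) that clinical indices are built from.

`pulsema` is a simulation laboratory for this effect, for researchers in
physiological signal processing who need ground-truth distorted signals.

## The model

The TCS stack is a mass–spring–damper. With the arterial wall displacement
`y(t)` (a harmonic series of the heart rate) as base excitation, the mass
displacement `x_M(t)` obeys the 1DOF equation with drift-perturbed
parameters

```
(m0+dm(t)) x'' + (c0+dc(t)) x' + (k0+dk(t)) x = (k0+dk(t)) y + (c0+dc(t)) y'
dk = -(k0/3) xb/max(xb),  dc = -(c0/3) xb/max(xb),  dm = -(m0/2) xb/max(xb)
```

and the sensor outputs are `x_ACC = x_M + x_b` (accelerometer) and
`x_PPG = y + g(x_TVSP + x_b)` (PPG), with `x_TVSP = x_M - x_C` the
deviation from the MA-free response `x_C`, which relates to `y` through
`G0 e^{i phi0} = (k0 + i c0 w)/(k0 - m0 w^2 + i c0 w)`. When pulsatile
pressure is the true signal, the wall becomes a spring `kA` and the same
machinery runs on the coupled 2DOF system. The artifact can equivalently be
expressed as forces (`F_b`, `F_TVSP`) on the *nominal* time-invariant
system; `reconstruct_from_forces()` verifies that closure. Nominal
defaults: frequency ratio `r0 = omega0/omegaC = 2`, damping `zeta0 = 1.5`,
`k0 = kA/6`, all in normalized units (`kA = 1`).

## Worked example

```r
library(pulsema)

params <- nominal_params()          # r0 = 2, zeta0 = 1.5, k0 = kA/6, f_c = 1 Hz
y     <- make_harmonic_pulse(carotid_harmonic_spec(), duration = 12, fs = 200)
drift <- make_baseline_drift(drift_spec(), duration = 12, fs = 200)
res   <- run_case_wall(params, y, drift)

# analyse the last 10 cycles
keep <- function(s) pulse_signal(s$samples[res$time >= 2], fs = 200, t_start = 2)
x_M <- keep(res$x_M); x_C <- keep(res$x_C)
cm_M <- per_cycle_metrics(x_M, detect_feet(x_M, 1))
cm_C <- per_cycle_metrics(x_C, detect_feet(x_C, 1))

100 * max(abs(cm_M$amplitude - cm_C$amplitude) / cm_C$amplitude)
100 * max(abs(cm_M$hr_bpm - 60)) / 60
band_energy_fraction(pulse_spectrum(keep(res$x_TVSP)), f_c = 1, band = 0.7)
```

Output:

```
TVSP-only amplitude distortion: 0.74% (max over cycles)
TVSP-only heart-rate deviation: 0.25% (max over cycles)
x_TVSP energy within +/-0.7 Hz of harmonics 1-10: 100.0%
```

Meaning: with the canonical two-tone drift (0.2 + 0.35 Hz) slaved to the
TVSPs, the multiplicative distortion alone changes per-cycle pulse
amplitude by under 1% and per-cycle heart rate by a quarter of a percent —
small in the time domain, yet essentially all of its energy sits in
sidebands around the pulse harmonics, where baseline-removal algorithms
cannot reach it.

A full run (simulation, forces, spectra, cycle metrics, CSE baseline,
parameter trajectories, sideband report, manifest) is one call:

```r
run_scenario(scenario_preset("wall-default"), "my-run")
```

or from a shell: `Rscript inst/cli/pulsema simulate --preset wall-default
--out my-run`.

## Layout

- `R/` — waveform/drift generators, TCS parameterization and transfer
  functions, time-varying ODE integration, equivalent forces, analyses,
  scenario runner.
- `vignettes/motion-artifact-model.Rmd` — the model, its assumptions,
  parameter meanings, numerical choices, and limitations.
- `tests/testthat/` — closed-form oracles, property tests, and end-to-end
  distortion-bound checks.
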