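---
title: "Modelling electrochemical safety limits for stimulation electrodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling electrochemical safety limits for stimulation electrodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimsafe)
```

## The problem

Pulsed electrical stimulation of neural tissue is limited by
electrochemistry: once the potential built up across the
electrode-electrolyte interface exceeds the water electrolysis window,
irreversible reactions begin, gas evolves and both tissue and electrode
are damaged. The widely used Shannon charge-density rule
(`log10 Dq = k - log10 Q`) draws a single empirical line through
historical damage data, but it ignores pulse width, contact material,
electrode separation and the interface impedance — exactly the knobs a
stimulation designer actually turns.

`stimsafe` implements a measurement-driven alternative. The chain is:

1. **Equivalent circuit.** The current path is modelled as a
   constant-phase-element (CPE) double layer in parallel with a Faradaic
   branch (charge-transfer resistance in series with a pseudo-capacitive
   CPE) at each contact, in series with a spreading resistance from
   current crowding next to the contact and a bulk tissue network
   (extracellular resistance in parallel with an intracellular RC path).
2. **Configuration spectroscopy.** Impedance spectra measured in 4-, 3-
   and 2-contact wirings see, respectively, the medium alone, one
   interface plus medium, and both interfaces plus medium. Subtracting
   the 4-contact from the 3-contact spectrum delineates the interface.
3. **Water window.** Cyclic voltammetry locates the cathodal and anodal
   onset potentials `E_mc` and `E_ma` of unrestricted electrolysis
   current.
4. **Voltage transients.** Square-pulse transients are split into an
   instantaneous ohmic access step and the slow interface polarization
   ("cathodal excitation", `V_elec`), read at the end of the cathodal
   phase.
5. **Predictive model.** The excitation is fit as

   `V_elec = a * ln(b * |I_inj|^k2 * t_pw^k4 * |Z_imag|^k6 + 1)`

   with `|Z_imag|` the reactance magnitude at the principal frequency
   (10 kHz by default). Setting `V_elec = |E_mc|` and inverting in
   closed form gives the maximum safe current; substituting the
   impedance-diameter power law `Z_imag = alpha * D^d1` expresses the
   limit directly as a function of contact diameter, which is the form
   compared against the Shannon limit.

## Model conventions

**Magnitudes.** Cathodal potentials are negative at the instrument; the
excitation model is fit on magnitudes with `a > 0` and the sign is
restored only at reporting. This removes the sign ambiguity between the
single-factor forms (which carry a leading minus) and the full model.

**Units of `b`.** The rate constant `b` is dimensionful: its numeric
value depends on the scales used for current, time and reactance. All
fitting is done in a recorded unit convention — microamps, microseconds,
kiloohms by default — stored in every `safety_params` object, and all
public functions take SI inputs and convert internally. A model fit
under one convention is therefore portable.

**Faradaic branch topology.** The pseudo-capacitance is placed in series
with the charge-transfer resistance (CPE parallel to `R_CT + C_F`), the
usual Randles-type arrangement; with `q_f = 0` the branch reduces to
`R_CT` alone.

**Diameter form of the limit.** The diameter-parameterized limit is
computed by literally substituting `alpha * D^d1` into the closed-form
inverse, never from a separately transcribed expression, so the power
law, the forward model and the inverse can never drift apart (the
impedance scale enters raised to `k6`, as the substitution dictates).

**Shannon comparison.** The Shannon boundary is solved exactly from its
defining pair of equations: for a circular contact of area `A` (cm^2),
`Q = sqrt(A * 10^k)` uC/phase and `I = Q / t_pw`. The closed form is
re-derived from the definition rather than copied, for the same
consistency reason as above.

## Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| principal frequency | 10 kHz | reactance feeding the excitation model; 1 kHz is also common for diameter parametrization and both are exposed |
| scan rate | 0.2 V/s | CV sweep rate |
| `baseline_band` | 0.4 | central fraction of the CV potential range used for the baseline envelope |
| `onset_ratio` | 3 | multiple of the baseline envelope that marks electrolysis onset |
| `find_imax` tolerance | 1 mV | excitation tolerance of the bisection |
| Shannon `k` | 1.8 | empirical damage constant |

The window detector is deliberately ratio-based (invariant to uniform
current scaling) with a sustained-growth confirmation; a purely
derivative-based onset criterion was rejected as too fragile under
noise. Both knobs are surfaced and recorded in the detector output.
The window used for limits is taken from the same wiring configuration
as the transient data, and that choice travels with the result.

## The synthetic-data generator

No raw measurement set ships with the package, so a seeded generator
(`make_electrode`, `generate_eis_dataset`, `generate_cv`,
`generate_transient_dataset`, `generate_rho_r_series`,
`generate_excitation_grid`) stands in for the bench. It emulates the
structure the analysis assumes:

* interface CPEs sized so the 10 kHz reactance follows
  `alpha * D^d1` per material — exponents near -1.67 (PtNR) and -1.61
  (planar Pt), a 2% electrode-to-electrode log-normal jitter;
* an in-vivo medium that multiplies the interface impedance (x2) and
  raises the medium resistivity (0.7 to 3.0 Ohm m), so in-vivo spectra
  sit strictly above benchtop ones;
* spreading resistance from `R = rho * G(D, S) / (4 pi)` with an
  empirical `G(D, S)` table that rises as contacts shrink and falls as
  separation grows (the exact table values are free generator
  parameters; only the trends are meaningful);
* CV sweeps with a capacitive baseline plus sharp exponential
  electrolysis branches (onset steepness 100 per volt) outside a window
  that widens in two-contact wiring (x1.6) and in vivo (x1.25); the
  sweep scans to 1.55x each expected edge, as an experimentalist would;
* transients carrying a known access step plus an embedded
  generator-truth excitation with a mildly sub-linear charging profile,
  near-linear early so back-extrapolation isolates the access step;
* measurement noise of 1% (multiplicative, on magnitudes), 1 degree of
  impedance phase, defaults chosen to keep parameter recovery
  well-posed at desk scale.

Generator-truth excitation parameters per material are calibrated so
that absolute current limits land at realistic magnitudes — for the
low-impedance PtNR preset the modelled limit exceeds the Shannon
prediction at small diameters (430 vs 211 uA at 30 um, 100 us), while
the high-impedance planar-Pt preset falls below it. The in-vivo
impedance exponent defaults to 1.08 (insertion-type) and 1.04 (surface)
with the benchtop truth at 1.0.

What the generator does **not** emulate: instrument drift, mains
pickup, quantization, chronic impedance changes, electrode-to-electrode
defect variability beyond the log-normal jitter, and any non-electrochemical
damage mechanism. Passing the recovery suite therefore shows the
analysis chain is correct and well-conditioned under the stated noise
model — not that real tissue behaves this way.

## Numerical choices

* **CPE time-domain realization.** Exact fractional-order integration
  is unnecessary at desk scale; each CPE becomes a fixed log-spaced
  chain of parallel-RC rungs (8 per decade) spanning
  `[1/(10 t_pw), 10/dt]` Hz padded by 1.5 decades each side. Rung
  resistances are solved by non-negative least squares against the
  analytic CPE impedance; fidelity is asserted in the test-suite at 5%
  magnitude over the band. `n` within 0.001 of 1 (or 0) degenerates to
  an ideal capacitor (resistor).
* **Transient integration.** `deSolve::lsoda` phase-by-phase with the
  drive constant within each solve (`rtol 1e-8`, `atol 1e-12`). The
  optional bias-dependent Faradaic conductance
  `g(V) = exp(gamma |V|) / R_CT` (a one-branch Butler-Volmer-like law,
  off by default) is evaluated from the double-layer state, which is
  exact whenever the double-layer element has no resistive
  feed-through.
* **Interpolation.** Spectra are interpolated linearly in log-frequency
  (impedance spectra are near power-law in `f`); linear-frequency
  interpolation was rejected. No extrapolation outside the measured
  range, ever.
* **Circuit fitting.** Complex nonlinear least squares on stacked
  real/imaginary residuals weighted by `1/|Z|`, with data-driven
  initialization (mid-band reactance slope for the CPE exponent, low-f
  plateau for `R_CT`) and a small multi-start over the exponent. The
  bulk-tissue arc is a one-pole response and therefore identifiable
  only up to its canonical form; the fit pins the intracellular
  resistance at zero and returns the equivalent `r_ex`/`c_in` pair.
  The lead resistance is likewise absorbed into the reported series
  (spreading) resistance.
* **Excitation-surface fitting.** Exponents bounded to (0, 3];
  initialization from single-factor log-linearizations; `b`
  multi-started over a decade grid (1e-6 to 1e2) to escape the flat
  region of `ln(1 + x)`, best fit wins with ties broken by the smaller
  parameter norm. Residuals are weighted by the inverse excitation by
  default, matching the multiplicative error structure of the
  measurements; this is what makes the small-excitation records —
  which carry the curvature information separating `a` from `b` —
  statistically effective.
* **Bisection.** `find_imax` bisects in log-current (limits span
  decades), verifies monotonicity on the bracket and stops at 1 mV on
  the excitation within at most 60 iterations.
* **Degenerate inputs.** All-zero excitations flag a degenerate
  single-factor fit; negative access or excitation estimates are
  clamped to zero with a flag; an arm of the water window with no onset
  in range is an explicit open-window value (`NA`), not a number.

## Problem sizes

The recovery studies run at desk scale: excitation grids of 5 currents
(20-2000 uA) x 5 pulse widths (100-1000 us) x 3 reactances (the
100/200/400 um diameter rungs) over 50 seeds; impedance-scaling and
geometric-factor Monte Carlos over 100 seeds; window detection over 20
seeds; the held-out transfer surrogate uses a 25-point benchtop grid
and a 36-point in-vivo grid. The whole suite completes in about a
minute on one core. The measurement-current ladder intentionally spans
up to the safe-current region (access drops of several volts), because
the curvature of `ln(1 + x)` around `x ~ 1` is what identifies `a` and
`b` separately — grids confined to the small-signal regime leave the
pair degenerate.

## Known limitations

* Electrolysis is treated as the damage criterion; chronic,
  neurobiological and mechanical damage pathways are out of scope, so
  any limit computed here is an upper bound on electrochemical grounds
  only.
* The model is calibrated and inverted for cathodal-first biphasic
  square pulses; the anodal window is extracted but no anodal-first
  limit model is fit.
* Geometry enters only through lumped parameters (`G`, `alpha`, `d1`);
  there is no spatially resolved field solver.
* In two-contact transients the counter-contact polarization is not
  separated; the reported excitation is total polarization minus the
  access step, and is recorded as such.

## A worked run

```{r pipeline}
cfg <- validate_config(list(
  generator = list(material = "PtNR",
                   diameters_m = c(100, 200, 400) * 1e-6),
  out_dir = tempfile("stimsafe-run"), seed = 7))
manifest <- run_pipeline(cfg)
str(manifest$results$safety_params)
```

The pipeline writes every spectrum, sweep and transient it used as
CSV + JSON sidecars, the fitted parameters with their unit convention,
a model-vs-Shannon safety map over the design grid, and a manifest with
file hashes so a run can be reproduced bit-for-bit from its seed.
```{r map}
head(read.csv(file.path(cfg$out_dir, "safety_map.csv")))
```
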