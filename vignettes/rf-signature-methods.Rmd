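---
title: "RF spectral signatures: model, calibration, and design notes"
author: "rfsig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RF spectral signatures: model, calibration, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfsig)
```

## The measurement and its model

An RF sweep sensor steps a signal generator across a fixed frequency grid
— 1500 to 3000 MHz in 0.2 MHz increments, 7501 frequencies — and records
one received-power value per dwell. Ten sweeps are averaged per frequency
into the solution's spectral signature. Power is in arbitrary sensor
units throughout: no published result depends on an absolute scale, only
on unitless L1 distances between signatures, so `rfsig` imposes none.

Identification is deliberately minimal: a blind scan is assigned the
concentration of the training signature nearest in L1 distance,

$$d(a,b) = \sum_f |a(f) - b(f)|,$$

with no normalization, baseline subtraction, or frequency weighting
beforehand. This mirrors the published analysis, which reduces each
comparison of two full spectra to this single raw sum.

## The synthetic generator and what it stands in for

The raw spectra behind the published experiments were withheld; only
scalar distance statistics were printed. The generator therefore exists to
reproduce the *protocol*, calibrated to those scalars:

$$R_c(f) = B(f) + g(c)\, s\, D(f) + \varepsilon(f)$$

* `B(f)` — smooth baseline, a sum of Gaussian components. Its shape is a
  qualitative default: baselines cancel in every distance the pipeline
  computes, so nothing is calibrated to it.
* `D(f)` — response profile, normalized so $\sum_f |D(f)| = 1$. With that
  normalization the noiseless L1 distance between concentrations $c_1$
  and $c_2$ is exactly $|g(c_1) - g(c_2)|\,s$, making the response scale
  $s$ interpretable as distance per unit concentration fraction.
* `g(c) = c + q c^2` — linear by default (`quadCoef = 0`). The quadratic
  knob exists because the published 1–5% distances grow slightly
  superlinearly (873,013 at 1% to 5,598,519 at 5%, about 28% above the
  linear extrapolation); the printed tables do not identify a functional
  form, so convexity is opt-in, not default.
* `ε(f)` — i.i.d. zero-mean Gaussian noise, sd `noiseSigma`, independent
  per frequency and per sweep. The published tables expose exactly one
  noise statistic (the rescan distance), which identifies exactly one
  noise parameter; anything richer would be invention. An optional smooth
  correlated drift term (`driftSigma` > 0) is available for sensitivity
  exploration but is off by default for the same reason.

Two closed forms tie the model to printed values. The difference of two
independent $n$-sweep means is Gaussian with sd $\sigma\sqrt{2/n}$ per
frequency, and the mean absolute value of a centred Gaussian is its sd
times $\sqrt{2/\pi}$, so the expected rescan ("self") distance over $N$
frequencies is

$$E[d_\text{self}] = N\,\sigma\,\sqrt{\tfrac{4}{\pi n}}.$$

`calibrateNoiseSigma()` inverts this: targeting the published rescan
distance 33,157 at $N = 7501$, $n = 10$ gives $\sigma \approx 12.39$
sensor units. `calibrateResponseScale()` sets $s$ = reference distance /
spacing, e.g. $864{,}963 / 0.01 \approx 8.65\times10^7$ per unit
fraction, i.e. 86.5 per ppm.

With both calibrations the four blinded experiment designs have
separation-to-noise-floor ratios between about 8 and 26, which is why the
simulated trials reproduce the published 100% identification accuracy in
every seeded replicate: the probability of a misassignment at those
ratios is negligible, because an L1 distance summed over 7501
frequencies concentrates tightly (relative sd below 1%).

### What passing simulations do and do not show

The generator emulates the distance *statistics* of the real sensor, not
its physics. Real spectra may have frequency-correlated noise, session
drifts shared between training and test scans, temperature sensitivity,
and non-additive concentration responses; none of these is identified by
the published scalars, and none is modeled by default. A passing
simulated trial therefore validates the pipeline's logic and the
published arithmetic — it is not additional evidence about the physical
sensor. Dielectric modeling (Debye/Cole–Cole permittivity) is explicitly
out of scope.

## Blind-trial mechanics

`generateExperiment()` follows the blinding protocol: labeled scans build
the training library; every solution is then re-scanned with independent
noise, the presentation order is drawn from a dedicated permutation seed,
labels are stripped, and the true order is kept as a sealed answer key.
All randomness flows through two named seeds (noise, permutation), both
recorded in every report, and regeneration under fixed seeds is bitwise
identical.

Assignment is independent nearest-neighbour per blind, because the
protocol presents solutions one at a time and nothing enforces a
bijection. A one-to-one mode (`runBlindTrial(exp, assignment =
"oneToOne")`) minimizes total distance over all bijections — enumerated
exactly, which is trivial at the at-most-seven solutions a trial
contains — as a comparison tool. Ties, which have measure zero under the
noise model but can occur in degenerate configurations, break toward the
lower concentration, deterministically. A blind recorded without data
propagates as an explicit no-data result and is excluded from the
accuracy denominator, matching the published treatment of the one missing
bleach scan.

Two identification routes exist because the published narrative is
ambiguous between them: `identifySignature()` matches full spectra
(distance to every training signature), while `matchBlindsScalar()`
matches each blind's scalar distance-to-reference against the training
column — the route the printed tables can actually verify. On the
packaged tables the scalar route assigns all 16 assignable blinds (17
listed, one no-data) correctly; calibrated simulations pass through the
full-spectrum route.

## Resolution arithmetic

`resolutionLimit(noiseFloor, referenceDistance, spacingPpm)` is the
published heuristic ratio, rounded to the nearest integer ppm. It is
homogeneous of degree zero in distance units. The four published
computations — 383, 249, 243 and 191 ppm — are reproduced exactly from
their printed operands, which ship as a fixture. Two deliberate
preservations of published arithmetic:

* the NaCl computation uses 692,414 although the corresponding distance
  table prints 694,212 (source of the difference unstated); the fixture
  stores the operand used in the published arithmetic and the table keeps
  its printed value;
* the NaOCl computation takes its spacing from the 0.4% (4000 ppm) pair,
  so the operation takes spacing explicitly rather than inferring it —
  the caller controls which pair defines the slope.

`estimateFromExperiment()` is the scan-based analogue: it measures a
realized noise floor from one rescan (as the published analysis did,
single realized value, not an expectation — both views are available via
`expectedSelfDistance()`) and the reference distance from the nearest
distinct training concentration. Under exp-1 calibration it lands within
Monte-Carlo scatter of 383 ppm; doubling `noiseSigma` doubles the
estimate in expectation, since the numerator is linear in sigma and the
denominator is noise-dominated only far below the working regime.

## Bench preparation arithmetic

`replacementVolume(container, fraction, purity)` = container x fraction /
purity, `soluteMass()`, `mixtureDensity()` (ideal volumetric mixing —
which regenerates every printed density row to 0.1 g/L, so no
excess-volume model is warranted by the data) and `massForVolume()` all
round to 0.1 of their unit (mL, g, g/L), half away from zero, matching
benchtop reporting precision. One published value resists the formula:
the 0.2% bleach replacement is printed as 105.2 mL where
3940 x 0.002 / 0.075 = 105.07 → 105.1 (and the printed 0.4%/0.6% volumes
are exact doubles/triples of 105.2). The package implements the formula
and documents the 0.1 mL discrepancy rather than chasing the printed
digit. Likewise the 2000 ppm solvent-series text says "six" solutions but
lists four concentrations; the four-concentration reading, consistent
with its distance table, is used.

## Numerical and scale choices

* Grid construction rejects steps that do not divide the span to within
  1e-6 of an integer count; frequencies are stored ascending, endpoints
  inclusive ((3000 − 1500)/0.2 + 1 = 7501).
* Sweep/signature CSVs are written with 17 significant digits, so
  write-read round trips reproduce doubles bit-exactly.
* Simulation tests run at two scales: closed-form checks and end-to-end
  replication at the full 7501-point grid (200 Monte-Carlo rescan
  replicates; 100 seeded trial replicates per blinded design), and
  distribution-shape properties (metric axioms, variance of the mean,
  accuracy-vs-noise monotonicity) on a few-hundred-point grid, since the
  generator model is grid-size agnostic. These sizes are the package's
  chosen test design, balancing Monte-Carlo error against runtime.
* The fifth (unblinded, fixed-volume) experiment design has no published
  noise floor of its own, so the replication driver reuses the
  calibration of the first design — same solvent system, same 1%
  spacing; its published distance column is comparable in magnitude,
  which is the claim that design existed to make.

## Known limitations

The pipeline reduces each spectrum pair to one number; it cannot separate
analytes whose signatures differ in shape but not in L1 distance, and it
assumes training and blind scans are exchangeable (no session drift).
The resolution limit is a heuristic signal-to-noise ratio, not a formal
detection-theoretic LOD. The generator's curve shapes are cosmetic;
only its distance statistics are calibrated.
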