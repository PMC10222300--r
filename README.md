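# rfsig

Chemometric analysis of radio-frequency (microwave band) sweep spectroscopy
of liquid solutions. An RF sensor sweeps 1500–3000 MHz in 0.2 MHz steps
(7501 frequencies), recording one received-power value per dwell; ten
sweeps are averaged into a per-frequency mean curve — the solution's
*spectral signature*. Solutions of a single solute at different
concentrations (water in isopropyl alcohol, NaCl or NaOCl in water) have
distinct signatures, so an unlabeled ("blind") scan can be identified by
nearest-neighbour matching, and the sensor's concentration resolution can
be estimated from how fast signatures separate per ppm of concentration.

`rfsig` implements the full pipeline for analysts working with such
sensors: signature construction and CSV I/O, L1 nearest-neighbour blind
identification, resolution-limit estimation, benchtop solution-preparation
arithmetic, and a calibrated synthetic sweep generator that replicates the
published blind-trial protocol end to end (the original raw spectra were
never released; only scalar distance tables were printed, and those tables
ship as fixtures).

## The method

For signatures $a, b$ on a shared grid of $N$ frequencies, the similarity
metric is the L1 (Manhattan) distance

$$d(a,b) = \sum_{f} |a(f) - b(f)|.$$

A training library holds one signature per known concentration; a blind is
assigned the concentration of its nearest library entry (ties toward the
lower concentration). The resolution limit follows from two scalars: the
**noise floor** $d_0$ (L1 distance between two independent scans of the
same solution — anything closer than this is indistinguishable from rescan
noise) and the **reference distance** $d_\Delta$ at a known spacing of
$\Delta$ ppm:

$$\text{resolution (ppm)} = \frac{d_0}{d_\Delta}\,\Delta .$$

The synthetic generator draws sweeps from
$R_c(f) = B(f) + g(c)\,s\,D(f) + \varepsilon(f)$ with $\sum_f |D(f)| = 1$,
so the noiseless inter-solution distance is exactly $|g(c_1)-g(c_2)|\,s$,
and i.i.d. Gaussian per-frequency noise $\varepsilon$. Two closed forms
calibrate it to printed statistics: the expected self-distance of two
$n$-sweep signatures is $N\sigma\sqrt{4/(\pi n)}$ (inverted by
`calibrateNoiseSigma()`), and $s$ = reference distance / spacing
(`calibrateResponseScale()`).

## Worked example

Calibrate the generator to the 10,000 ppm water-in-isopropanol experiment
(noise floor 33,157; 1% separation 864,963), simulate a six-solution blind
trial, and estimate the resolution limit from a fresh rescan:

```r
library(rfsig)
params <- calibratedParams(noiseFloor = 33157, referenceDistance = 864963,
                           spacingPpm = 10000, seed = 42L)
exp <- generateExperiment(params, concs = seq(0, 0.05, by = 0.01),
                          permutationSeed = 7L)
runBlindTrial(exp)
#> TrialReport: 6/6 assignable blinds correct (accuracy 1.000)

rescan <- simulateSignature(params, 0)
estimateFromExperiment(exp@training, rescan, 0)
#> ResolutionEstimate: noise floor 33113.1 / reference 864965 at 10000 ppm spacing
#>   slope 86.5 per ppm; resolution limit 383 ppm
```

All six blinds are identified correctly: the 1%-spacing separation
(~865,000) is ~26 times the rescan noise floor (~33,000), so
nearest-neighbour assignment has essentially no room to fail. The realized
resolution estimate, 383 ppm, says a concentration difference of roughly
0.04% is the smallest this noise level can distinguish from a rescan of
the same solution.

The published scalar arithmetic is re-verified in one call:

```r
all(replicateTables()$pass)
#> [1] TRUE
```

and `runBlindTrial(exp, assignment = "oneToOne")` swaps in an exact
minimum-total-distance bijection for comparison with the default
independent per-blind matching.

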