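## Central S4 containers. All spectral objects share a FrequencyGrid; grid
## equality is checked (not assumed) by every pairwise operation.

#' FrequencyGrid: the sampled RF axis
#'
#' An inclusive, strictly increasing frequency axis in MHz shared by all
#' sweeps and signatures in an analysis. The default acquisition grid spans
#' 1500--3000 MHz at 0.2 MHz steps, i.e. 7501 points.
#'
#' @slot startMhz First frequency (MHz).
#' @slot stopMhz Last frequency (MHz), included in the axis.
#' @slot stepMhz Step between samples (MHz), positive.
#' @slot nPoints Number of samples, `(stop - start)/step + 1`.
#' @seealso [makeGrid()], [frequencies()]
#' @export
setClass("FrequencyGrid",
  representation(
    startMhz = "numeric",
    stopMhz = "numeric",
    stepMhz = "numeric",
    nPoints = "integer"
  )
)

setValidity("FrequencyGrid", function(object) {
  msg <- character()
  if (!isScalarNumber(object@startMhz) || !isScalarNumber(object@stopMhz) ||
      !isScalarNumber(object@stepMhz) || length(object@nPoints) != 1L) {
    return("all slots must be finite scalars")
  }
  if (object@stepMhz <= 0) msg <- c(msg, "stepMhz must be > 0")
  if (object@startMhz >= object@stopMhz) msg <- c(msg, "startMhz must be < stopMhz")
  n <- round((object@stopMhz - object@startMhz) / object@stepMhz) + 1
  if (object@nPoints != n) {
    msg <- c(msg, sprintf("nPoints (%d) inconsistent with endpoints and step (expected %d)",
                          object@nPoints, as.integer(n)))
  }
  if (length(msg)) msg else TRUE
})

#' Sweep: one acquisition pass across the grid
#'
#' One pass of the signal generator over the frequency grid, recording a
#' single received-power value per dwell. Power is in arbitrary sensor
#' units; no absolute scale is imposed.
#'
#' @slot grid A [FrequencyGrid-class].
#' @slot power Numeric vector of received power, one value per grid point.
#' @slot sweepIndex Position of this pass within its acquisition (1-based).
#' @slot label Solution identifier, or `NA_character_` for a blinded scan.
#' @export
setClass("Sweep",
  representation(
    grid = "FrequencyGrid",
    power = "numeric",
    sweepIndex = "integer",
    label = "character"
  )
)

setValidity("Sweep", function(object) {
  msg <- character()
  if (length(object@power) != object@grid@nPoints) {
    msg <- c(msg, sprintf("power has %d values but grid has %d points",
                          length(object@power), object@grid@nPoints))
  }
  if (!all(is.finite(object@power))) msg <- c(msg, "power values must all be finite")
  if (length(object@sweepIndex) != 1L || object@sweepIndex < 1L) {
    msg <- c(msg, "sweepIndex must be a single positive integer")
  }
  if (length(object@label) != 1L) msg <- c(msg, "label must be a single string (or NA)")
  if (length(msg)) msg else TRUE
})

#' SpectralSignature: the per-frequency mean over sweeps
#'
#' The fingerprint of a solution: the arithmetic mean of received power at
#' each frequency over `nSweeps` repeated sweeps.
#'
#' @slot grid A [FrequencyGrid-class].
#' @slot meanPower Numeric vector, per-frequency mean power (sensor units).
#' @slot nSweeps Number of sweeps averaged (>= 1).
#' @slot label Solution identifier, or `NA_character_`.
#' @seealso [buildSignature()], [l1Distance()]
#' @export
setClass("SpectralSignature",
  representation(
    grid = "FrequencyGrid",
    meanPower = "numeric",
    nSweeps = "integer",
    label = "character"
  )
)

setValidity("SpectralSignature", function(object) {
  msg <- character()
  if (length(object@meanPower) != object@grid@nPoints) {
    msg <- c(msg, sprintf("meanPower has %d values but grid has %d points",
                          length(object@meanPower), object@grid@nPoints))
  }
  if (!all(is.finite(object@meanPower))) msg <- c(msg, "meanPower must be finite")
  if (length(object@nSweeps) != 1L || object@nSweeps < 1L) {
    msg <- c(msg, "nSweeps must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' SolutionSpec: what a labeled solution is
#'
#' A solvent, a solute, and the solute concentration as a dimensionless
#' fraction (by volume or by mass). `ppm(x)` gives the concentration in
#' parts per million (fraction times 1e6; 1% = 10,000 ppm).
#'
#' @slot solvent Solvent name (e.g. `"isopropyl alcohol"`).
#' @slot solute Solute name (e.g. `"deionized water"`).
#' @slot concentration Fraction in \[0, 1\].
#' @slot basis `"volume"` or `"mass"`.
#' @export
setClass("SolutionSpec",
  representation(
    solvent = "character",
    solute = "character",
    concentration = "numeric",
    basis = "character"
  )
)

setValidity("SolutionSpec", function(object) {
  msg <- character()
  if (!isScalarNumber(object@concentration) ||
      object@concentration < 0 || object@concentration > 1) {
    msg <- c(msg, "concentration must be a fraction in [0, 1]")
  }
  if (!(object@basis %in% c("volume", "mass"))) {
    msg <- c(msg, "basis must be 'volume' or 'mass'")
  }
  if (length(msg)) msg else TRUE
})

#' TrainingLibrary: labeled signatures of known concentrations
#'
#' The object blind scans are matched against: one signature per known
#' concentration, all on a single grid, concentrations unique.
#'
#' @slot signatures List of [SpectralSignature-class], one per solution.
#' @slot specs List of [SolutionSpec-class], parallel to `signatures`.
#' @seealso [trainingLibrary()], [identifySignature()]
#' @export
setClass("TrainingLibrary",
  representation(signatures = "list", specs = "list")
)

setValidity("TrainingLibrary", function(object) {
  msg <- character()
  if (length(object@signatures) == 0L) msg <- c(msg, "library must be non-empty")
  if (length(object@signatures) != length(object@specs)) {
    msg <- c(msg, "signatures and specs must have equal length")
  }
  if (!all(vapply(object@signatures, is, logical(1), "SpectralSignature"))) {
    msg <- c(msg, "signatures must all be SpectralSignature objects")
  }
  if (!all(vapply(object@specs, is, logical(1), "SolutionSpec"))) {
    msg <- c(msg, "specs must all be SolutionSpec objects")
  }
  if (!length(msg)) {
    g <- object@signatures[[1]]@grid
    if (!all(vapply(object@signatures, function(s) gridEqual(s@grid, g), logical(1)))) {
      msg <- c(msg, "all signatures must share one grid")
    }
    conc <- vapply(object@specs, function(s) s@concentration, numeric(1))
    if (anyDuplicated(conc)) msg <- c(msg, "concentrations must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' DensityModel: pure-component densities for ideal volumetric mixing
#'
#' @slot rhoSolvent Solvent density (g/L) at the reference temperature.
#' @slot rhoSolute Solute density (g/L).
#' @slot referenceTemp Reference temperature (degrees C).
#' @seealso [mixtureDensity()]
#' @export
setClass("DensityModel",
  representation(rhoSolvent = "numeric", rhoSolute = "numeric",
                 referenceTemp = "numeric")
)

setValidity("DensityModel", function(object) {
  if (object@rhoSolvent <= 0 || object@rhoSolute <= 0) {
    "densities must be positive"
  } else TRUE
})

#' GeneratorParams: the synthetic sweep model
#'
#' Parameters of the generative model standing in for withheld sensor data:
#' \deqn{R_c(f) = B(f) + g(c) \cdot s \cdot D(f) + \epsilon(f)}
#' where `B` is a smooth baseline, `D` a response profile normalized so its
#' absolute values sum to 1 over the grid (so the noiseless L1 distance
#' between concentrations `c1`, `c2` is exactly `|g(c1) - g(c2)| * s`),
#' `g(c) = c + quadCoef * c^2` (linear by default), and `eps` is i.i.d.
#' Gaussian per-frequency noise with standard deviation `noiseSigma`.
#'
#' Profiles are sums of Gaussian components given as data frames with
#' columns `center` (MHz), `width` (MHz), `amplitude`.
#'
#' @slot grid A [FrequencyGrid-class].
#' @slot baseline Data frame of baseline components (sensor units).
#' @slot response Data frame of response components (normalized on use).
#' @slot responseScale L1 distance units per unit concentration fraction.
#' @slot quadCoef Quadratic coefficient of `g(c)`; 0 for a linear response.
#' @slot noiseSigma Per-frequency noise standard deviation (sensor units).
#' @slot driftSigma Standard deviation of an optional smooth per-sweep
#'   drift curve (sensor units); 0 (default) disables it. The published
#'   tables expose only one noise statistic, which identifies `noiseSigma`
#'   alone, so drift is an off-by-default sensitivity knob.
#' @slot driftWidthMhz Correlation length of the drift curve (MHz).
#' @slot nSweeps Sweeps per signature (default 10).
#' @slot seed RNG seed for noise, or `NA` to use the current RNG stream.
#' @seealso [generatorParams()], [generateSweep()], [calibrateNoiseSigma()]
#' @export
setClass("GeneratorParams",
  representation(
    grid = "FrequencyGrid",
    baseline = "data.frame",
    response = "data.frame",
    responseScale = "numeric",
    quadCoef = "numeric",
    noiseSigma = "numeric",
    driftSigma = "numeric",
    driftWidthMhz = "numeric",
    nSweeps = "integer",
    seed = "integer"
  )
)

setValidity("GeneratorParams", function(object) {
  msg <- character()
  needed <- c("center", "width", "amplitude")
  for (nm in c("baseline", "response")) {
    df <- slot(object, nm)
    if (!all(needed %in% names(df))) {
      msg <- c(msg, sprintf("%s must have columns center, width, amplitude", nm))
    } else if (nrow(df) && (!all(is.finite(unlist(df[needed]))) || any(df$width <= 0))) {
      msg <- c(msg, sprintf("%s components must be finite with positive widths", nm))
    }
  }
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@driftSigma < 0) msg <- c(msg, "driftSigma must be >= 0")
  if (object@driftWidthMhz <= 0) msg <- c(msg, "driftWidthMhz must be > 0")
  if (object@responseScale < 0) msg <- c(msg, "responseScale must be >= 0")
  if (object@nSweeps < 1L) msg <- c(msg, "nSweeps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SimulatedExperiment: a full blind-trial data set
#'
#' Training signatures plus label-stripped blind sweep sets with a sealed
#' answer key, emulating the blind identification protocol: solutions are
#' scanned labeled to build the library, then re-scanned in an order
#' randomized by an independent party.
#'
#' @slot params The [GeneratorParams-class] used.
#' @slot concentrations Concentrations simulated (fractions).
#' @slot training A [TrainingLibrary-class].
#' @slot blindSweeps List (one element per blind, presentation order) of
#'   lists of label-stripped [Sweep-class] objects.
#' @slot answerKey True concentration of each blind, in presentation order.
#' @slot permutationSeed Seed used for the blinding permutation.
#' @seealso [generateExperiment()], [runBlindTrial()]
#' @export
setClass("SimulatedExperiment",
  representation(
    params = "GeneratorParams",
    concentrations = "numeric",
    training = "TrainingLibrary",
    blindSweeps = "list",
    answerKey = "numeric",
    permutationSeed = "integer"
  )
)

setValidity("SimulatedExperiment", function(object) {
  msg <- character()
  if (length(object@blindSweeps) != length(object@answerKey)) {
    msg <- c(msg, "one answer-key entry per blind sweep set required")
  }
  if (!setequal(object@answerKey, object@concentrations)) {
    msg <- c(msg, "answer key must be a permutation of the concentration list")
  }
  if (length(msg)) msg else TRUE
})

#' IdentificationResult: one blind matched to the library
#'
#' @slot assigned Assigned concentration (fraction), `NA` when `noData`.
#' @slot noData `TRUE` when the blind had no sweeps (scan missing).
#' @slot distances Named numeric: L1 distance to each training
#'   concentration (names are concentrations).
#' @slot margin Second-best distance minus best distance (>= 0); `NA` for a
#'   single-entry library or a no-data blind.
#' @export
setClass("IdentificationResult",
  representation(assigned = "numeric", noData = "logical",
                 distances = "numeric", margin = "numeric")
)

#' TrialReport: scored blind trial
#'
#' @slot assignments Named numeric, blind id -> assigned concentration
#'   (`NA` for excluded no-data blinds).
#' @slot truth Named numeric, blind id -> true concentration.
#' @slot nCorrect,nTotal Correct and assignable blind counts.
#' @slot accuracy `nCorrect / nTotal` over assignable (non-excluded) blinds.
#' @slot excluded Ids of blinds excluded as no-data.
#' @export
setClass("TrialReport",
  representation(assignments = "numeric", truth = "numeric",
                 nCorrect = "integer", nTotal = "integer",
                 accuracy = "numeric", excluded = "character")
)

#' ResolutionEstimate: the ratio-based resolution limit
#'
#' The heuristic smallest detectable concentration difference: the rescan
#' noise floor divided by the distance at a known spacing, expressed in ppm.
#'
#' @slot noiseFloor L1 distance between two independent scans of the same
#'   solution (rescan-vs-training).
#' @slot referenceDistance L1 distance at the known spacing.
#' @slot spacingPpm The known concentration spacing (ppm).
#' @slot slopePerPpm `referenceDistance / spacingPpm`, to one decimal.
#' @slot resolutionPpm `round(noiseFloor / referenceDistance * spacingPpm)`.
#' @seealso [resolutionLimit()], [estimateFromExperiment()]
#' @export
setClass("ResolutionEstimate",
  representation(noiseFloor = "numeric", referenceDistance = "numeric",
                 spacingPpm = "numeric", slopePerPpm = "numeric",
                 resolutionPpm = "numeric")
)

setValidity("ResolutionEstimate", function(object) {
  msg <- character()
  if (object@noiseFloor < 0) msg <- c(msg, "noiseFloor must be >= 0")
  if (object@referenceDistance <= 0) msg <- c(msg, "referenceDistance must be > 0")
  if (object@spacingPpm <= 0) msg <- c(msg, "spacingPpm must be > 0")
  if (length(msg)) msg else TRUE
})
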