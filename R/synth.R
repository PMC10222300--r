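## Synthetic sweep generator. The withheld sensor data are replaced by the
## additive model R_c(f) = B(f) + g(c) * s * D(f) + eps(f): only scalar L1
## distance statistics are calibrated (rescan noise floor, inter-solution
## separation), so the curve shapes of B and D are qualitative defaults.

## sum-of-Gaussians profile evaluation on a frequency axis
evalProfile <- function(components, freq) {
  y <- numeric(length(freq))
  if (nrow(components)) {
    for (i in seq_len(nrow(components))) {
      y <- y + components$amplitude[i] *
        exp(-0.5 * ((freq - components$center[i]) / components$width[i])^2)
    }
  }
  y
}

## default qualitative curve shapes (sensor units are arbitrary)
defaultBaseline <- function() {
  data.frame(center = c(1750, 2200, 2650, 2950),
             width = c(180, 260, 140, 90),
             amplitude = c(-42000, 26000, -18000, 9000))
}

defaultResponse <- function() {
  data.frame(center = c(1650, 2050, 2450, 2850),
             width = c(90, 130, 110, 70),
             amplitude = c(1, -0.65, 0.8, -0.45))
}

#' Construct generator parameters
#'
#' See [GeneratorParams-class] for the signal model. The response profile is
#' renormalized at evaluation time so that the sum of its absolute values
#' over the grid equals 1; `responseScale` therefore *is* the noiseless L1
#' distance per unit of `g(c)`.
#'
#' @param grid A [FrequencyGrid-class]; default the 1500--3000 MHz grid.
#' @param baseline,response Component data frames (columns `center`,
#'   `width`, `amplitude`); qualitative smooth defaults are provided.
#' @param responseScale L1 distance units per unit concentration fraction.
#' @param quadCoef Quadratic coefficient of `g(c) = c + quadCoef * c^2`;
#'   default 0 (linear response).
#' @param noiseSigma Per-frequency Gaussian noise sd (sensor units).
#' @param driftSigma Sd of an optional smooth per-sweep drift curve; 0
#'   (default) disables it.
#' @param driftWidthMhz Correlation length of the drift curve (MHz).
#' @param nSweeps Sweeps per signature, default 10.
#' @param seed Noise RNG seed, or `NA` to draw from the current RNG stream.
#' @return A [GeneratorParams-class].
#' @export
generatorParams <- function(grid = defaultGrid(),
                            baseline = defaultBaseline(),
                            response = defaultResponse(),
                            responseScale = 0,
                            quadCoef = 0,
                            noiseSigma = 0,
                            driftSigma = 0,
                            driftWidthMhz = 200,
                            nSweeps = 10L,
                            seed = NA_integer_) {
  new("GeneratorParams", grid = grid, baseline = baseline,
      response = response, responseScale = responseScale,
      quadCoef = quadCoef, noiseSigma = noiseSigma,
      driftSigma = driftSigma, driftWidthMhz = driftWidthMhz,
      nSweeps = as.integer(nSweeps), seed = as.integer(seed))
}

## concentration response g(c)
gOfC <- function(params, conc) conc + params@quadCoef * conc^2

## smooth correlated per-sweep drift: random Gaussian bumps spaced one
## correlation length apart, rescaled to sd driftSigma over the grid
driftCurve <- function(params) {
  g <- params@grid
  span <- g@stopMhz - g@startMhz
  k <- max(4L, ceiling(span / params@driftWidthMhz) + 1L)
  centers <- seq(g@startMhz, g@stopMhz, length.out = k)
  comp <- data.frame(center = centers, width = params@driftWidthMhz,
                     amplitude = stats::rnorm(k))
  y <- evalProfile(comp, frequencies(g))
  s <- stats::sd(y)
  if (s > 0) y * params@driftSigma / s else y
}

## deterministic part of a sweep at concentration conc
noiselessPower <- function(params, conc) {
  f <- frequencies(params@grid)
  d <- evalProfile(params@response, f)
  sa <- sum(abs(d))
  if (sa > 0) d <- d / sa
  evalProfile(params@baseline, f) + gOfC(params, conc) * params@responseScale * d
}

#' Generate one synthetic sweep
#'
#' Draws one acquisition pass at the given concentration: the deterministic
#' baseline-plus-response curve plus i.i.d. zero-mean Gaussian noise with
#' sd `noiseSigma` at every frequency. Noise is drawn from the *current*
#' RNG stream; seed it (or use the `seed` slot via
#' [generateExperiment()]) for reproducibility.
#'
#' @param params A [GeneratorParams-class].
#' @param concentration Solute fraction in \[0, 1\].
#' @param sweepIndex Index recorded on the sweep.
#' @param label Label recorded on the sweep (`NA` to blind it).
#' @return A [Sweep-class].
#' @export
generateSweep <- function(params, concentration, sweepIndex = 1L,
                          label = NA_character_) {
  stopifnot(isScalarNumber(concentration))
  if (concentration < 0 || concentration > 1) {
    stop("concentration must be in [0, 1]")
  }
  mu <- noiselessPower(params, concentration)
  if (params@driftSigma > 0) mu <- mu + driftCurve(params)
  if (params@noiseSigma > 0) {
    mu <- mu + stats::rnorm(params@grid@nPoints, 0, params@noiseSigma)
  }
  newSweep(params@grid, mu, sweepIndex = sweepIndex, label = label)
}

#' Simulate a full signature (nSweeps averaged sweeps)
#'
#' @inheritParams generateSweep
#' @return A [SpectralSignature-class] averaging `params@nSweeps` sweeps.
#' @export
simulateSignature <- function(params, concentration, label = NA_character_) {
  buildSignature(lapply(seq_len(params@nSweeps), function(i) {
    generateSweep(params, concentration, sweepIndex = i, label = label)
  }))
}

#' Expected rescan self-distance (noise floor)
#'
#' Closed form for the expected L1 distance between two independent
#' `nSweeps`-averaged signatures of the *same* solution. The per-frequency
#' difference is Gaussian with sd `sigma * sqrt(2/nSweeps)`; the mean
#' absolute value of a centred Gaussian is `sd * sqrt(2/pi)`, so the
#' expected distance is
#' \deqn{N \cdot \sigma \cdot \sqrt{4 / (\pi n)}}
#' over `N` frequencies. This is the model's analogue of the rescan
#' distance a sensor reports when the same solution is scanned twice.
#'
#' @param noiseSigma Per-frequency noise sd.
#' @param nFreq Number of frequencies (default 7501).
#' @param nSweeps Sweeps per signature (default 10).
#' @return Expected L1 self-distance (sensor units).
#' @export
#' @examples
#' expectedSelfDistance(1, 1, 2)  # sqrt(4/(2*pi)) = 0.7979
expectedSelfDistance <- function(noiseSigma, nFreq = 7501, nSweeps = 10) {
  stopifnot(noiseSigma >= 0, nFreq > 0, nSweeps > 0)
  nFreq * noiseSigma * sqrt(4 / (pi * nSweeps))
}

#' Calibrate the noise sd to a target self-distance
#'
#' Inverse of [expectedSelfDistance()]: the per-frequency sigma for which
#' the expected rescan distance equals `targetSelfDistance`.
#'
#' @param targetSelfDistance Target L1 self-distance (e.g. a printed rescan
#'   distance used as the noise floor).
#' @param nFreq,nSweeps Grid size and sweeps per signature.
#' @return Noise sd (sensor units).
#' @export
#' @examples
#' calibrateNoiseSigma(33157, 7501, 10)  # about 12.39
calibrateNoiseSigma <- function(targetSelfDistance, nFreq = 7501, nSweeps = 10) {
  stopifnot(targetSelfDistance >= 0, nFreq > 0, nSweeps > 0)
  targetSelfDistance / (nFreq * sqrt(4 / (pi * nSweeps)))
}

#' Calibrate the response scale to a target separation
#'
#' Sets `responseScale` so the noiseless L1 distance between two solutions
#' one `concentrationSpacing` apart (linear `g`) equals `targetDistance`.
#'
#' @param targetDistance Target inter-solution L1 distance.
#' @param concentrationSpacing Concentration spacing (fraction), > 0.
#' @return Response scale (distance units per unit fraction).
#' @export
#' @examples
#' calibrateResponseScale(864963, 0.01)  # 86,496,300 = 86.5 per ppm
calibrateResponseScale <- function(targetDistance, concentrationSpacing) {
  stopifnot(targetDistance >= 0)
  if (concentrationSpacing <= 0) stop("concentrationSpacing must be > 0")
  targetDistance / concentrationSpacing
}

#' Calibrated generator from printed distance statistics
#'
#' Convenience wrapper: builds [GeneratorParams-class] whose expected
#' rescan self-distance equals `noiseFloor` and whose noiseless separation
#' at `spacingPpm` equals `referenceDistance`.
#'
#' @param noiseFloor Target rescan L1 distance.
#' @param referenceDistance Target L1 distance at `spacingPpm`.
#' @param spacingPpm Concentration spacing of the reference pair (ppm).
#' @param grid,nSweeps,seed,quadCoef Passed to [generatorParams()].
#' @return A [GeneratorParams-class].
#' @export
calibratedParams <- function(noiseFloor, referenceDistance, spacingPpm,
                             grid = defaultGrid(), nSweeps = 10L,
                             seed = NA_integer_, quadCoef = 0) {
  generatorParams(
    grid = grid,
    responseScale = calibrateResponseScale(referenceDistance, spacingPpm / 1e6),
    quadCoef = quadCoef,
    noiseSigma = calibrateNoiseSigma(noiseFloor, nPoints(grid), nSweeps),
    nSweeps = nSweeps, seed = seed)
}

#' Generate a simulated blind-trial experiment
#'
#' Emulates the blind identification protocol: every concentration is
#' scanned labeled (`nSweeps` sweeps averaged) to build the training
#' library; then every solution is re-scanned with independent noise, the
#' presentation order is randomized with `permutationSeed`, labels are
#' stripped, and the true order is retained as a sealed answer key.
#'
#' @param params A [GeneratorParams-class]; if its `seed` slot is not `NA`
#'   the noise RNG is seeded with it, making the data set reproducible.
#' @param concs Numeric vector of at least two distinct concentrations.
#' @param permutationSeed Seed for the blinding permutation (independent of
#'   the noise seed).
#' @return A [SimulatedExperiment-class].
#' @export
generateExperiment <- function(params, concs, permutationSeed = 1L) {
  stopifnot(is.numeric(concs), length(concs) >= 2L)
  if (anyDuplicated(concs)) stop("concentrations must be distinct")
  set.seed(as.integer(permutationSeed))
  perm <- sample.int(length(concs))
  if (!is.na(params@seed)) set.seed(params@seed)
  training <- trainingLibrary(
    lapply(concs, function(cc) {
      simulateSignature(params, cc, label = sprintf("%g ppm", cc * 1e6))
    }),
    concs)
  blind <- lapply(concs[perm], function(cc) {
    lapply(seq_len(params@nSweeps), function(i) {
      generateSweep(params, cc, sweepIndex = i, label = NA_character_)
    })
  })
  names(blind) <- sprintf("Blind-%d", seq_along(blind))
  new("SimulatedExperiment", params = params, concentrations = concs,
      training = training, blindSweeps = blind,
      answerKey = concs[perm], permutationSeed = as.integer(permutationSeed))
}

setMethod("show", "SimulatedExperiment", function(object) {
  cat(sprintf(
    "SimulatedExperiment: %d solutions (%s ppm), %d sweeps each, sigma = %.4g, permutation seed %d\n",
    length(object@concentrations),
    paste(format(object@concentrations * 1e6), collapse = ", "),
    object@params@nSweeps, object@params@noiseSigma, object@permutationSeed))
})
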