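#' Construct a frequency grid
#'
#' Builds the inclusive sampled RF axis. The acquisition grid used for all
#' supported experiments spans 1500--3000 MHz at 0.2 MHz steps, giving
#' exactly 7501 frequencies; `defaultGrid()` returns it.
#'
#' @param startMhz,stopMhz Endpoints in MHz, both included in the axis.
#' @param stepMhz Positive step in MHz. `(stop - start)/step` must be an
#'   integer to within 1e-6, otherwise the grid is rejected.
#' @return A [FrequencyGrid-class].
#' @export
#' @examples
#' nPoints(makeGrid(1500, 3000, 0.2))  # 7501
#' frequencies(makeGrid(1500, 1501, 0.5))  # 1500.0 1500.5 1501.0
makeGrid <- function(startMhz, stopMhz, stepMhz) {
  stopifnot(isScalarNumber(startMhz), isScalarNumber(stopMhz),
            isScalarNumber(stepMhz))
  if (stepMhz <= 0) stop("stepMhz must be > 0")
  if (startMhz >= stopMhz) stop("startMhz must be < stopMhz")
  k <- (stopMhz - startMhz) / stepMhz
  if (abs(k - round(k)) > 1e-6) {
    stop(sprintf(
      "step %g MHz does not divide the span %g MHz evenly: (stop - start)/step = %.8f is not an integer",
      stepMhz, stopMhz - startMhz, k))
  }
  new("FrequencyGrid", startMhz = startMhz, stopMhz = stopMhz,
      stepMhz = stepMhz, nPoints = as.integer(round(k)) + 1L)
}

#' @rdname makeGrid
#' @export
defaultGrid <- function() makeGrid(1500, 3000, 0.2)

## exact grid equality: grids are constructed, not measured
gridEqual <- function(a, b) {
  a@startMhz == b@startMhz && a@stopMhz == b@stopMhz &&
    a@stepMhz == b@stepMhz && a@nPoints == b@nPoints
}

#' @rdname rfsig-accessors
#' @export
setMethod("frequencies", "FrequencyGrid", function(x) {
  seq(x@startMhz, by = x@stepMhz, length.out = x@nPoints)
})

#' @rdname rfsig-accessors
#' @export
setMethod("nPoints", "FrequencyGrid", function(x) x@nPoints)

#' Construct a single sweep
#'
#' @param grid A [FrequencyGrid-class].
#' @param power Numeric vector of received power (sensor units), one value
#'   per grid point, all finite.
#' @param sweepIndex 1-based index of this pass within its acquisition.
#' @param label Solution identifier, or `NA` for a blinded scan.
#' @return A [Sweep-class].
#' @export
newSweep <- function(grid, power, sweepIndex = 1L, label = NA_character_) {
  new("Sweep", grid = grid, power = as.numeric(power),
      sweepIndex = as.integer(sweepIndex), label = as.character(label))
}

#' Construct a spectral signature directly
#'
#' Usually signatures come from [buildSignature()]; this constructor exists
#' for fixtures and hand-built examples.
#'
#' @param grid A [FrequencyGrid-class].
#' @param meanPower Per-frequency mean power vector.
#' @param nSweeps Number of sweeps the mean represents (default 1).
#' @param label Solution identifier or `NA`.
#' @return A [SpectralSignature-class].
#' @export
newSignature <- function(grid, meanPower, nSweeps = 1L, label = NA_character_) {
  new("SpectralSignature", grid = grid, meanPower = as.numeric(meanPower),
      nSweeps = as.integer(nSweeps), label = as.character(label))
}

#' Describe a solution
#'
#' @param solvent,solute Component names.
#' @param concentration Solute fraction in \[0, 1\].
#' @param basis `"volume"` (default) or `"mass"`.
#' @return A [SolutionSpec-class].
#' @export
#' @examples
#' ppm(solutionSpec("isopropyl alcohol", "deionized water", 0.01))  # 10000
solutionSpec <- function(solvent, solute, concentration, basis = "volume") {
  new("SolutionSpec", solvent = solvent, solute = solute,
      concentration = concentration, basis = basis)
}

#' @rdname rfsig-accessors
#' @export
setMethod("ppm", "SolutionSpec", function(x) x@concentration * 1e6)

#' @rdname rfsig-accessors
#' @export
setMethod("concentrations", "SolutionSpec", function(x) x@concentration)

#' @rdname rfsig-accessors
#' @export
setMethod("power", "Sweep", function(x) x@power)

#' @rdname rfsig-accessors
#' @export
setMethod("label", "Sweep", function(x) x@label)

#' @rdname rfsig-accessors
#' @export
setMethod("meanPower", "SpectralSignature", function(x) x@meanPower)

#' @rdname rfsig-accessors
#' @export
setMethod("nSweeps", "SpectralSignature", function(x) x@nSweeps)

#' @rdname rfsig-accessors
#' @export
setMethod("label", "SpectralSignature", function(x) x@label)

#' Average sweeps into a spectral signature
#'
#' The signature of a solution is the arithmetic per-frequency mean of its
#' repeated sweeps (ten per acquisition in the supported protocol). All
#' sweeps must share one grid and one label.
#'
#' @param sweeps Non-empty list of [Sweep-class] objects.
#' @return A [SpectralSignature-class] with `nSweeps = length(sweeps)`.
#' @export
#' @examples
#' g <- makeGrid(1500, 1500.2, 0.2)
#' sig <- buildSignature(list(newSweep(g, c(1, 3)), newSweep(g, c(3, 5), 2)))
#' meanPower(sig)  # 2 4
buildSignature <- function(sweeps) {
  if (!is.list(sweeps) || length(sweeps) == 0L) {
    stop("no data: cannot build a signature from zero sweeps")
  }
  if (!all(vapply(sweeps, is, logical(1), "Sweep"))) {
    stop("sweeps must be a list of Sweep objects")
  }
  g <- sweeps[[1]]@grid
  lab <- sweeps[[1]]@label
  for (s in sweeps[-1]) {
    if (!gridEqual(s@grid, g)) stop("all sweeps must share one grid")
    if (!sameLabel(s@label, lab)) stop("all sweeps must share one label")
  }
  m <- if (length(sweeps) == 1L) {
    sweeps[[1]]@power
  } else {
    rowMeans(vapply(sweeps, function(s) s@power, numeric(g@nPoints)))
  }
  newSignature(g, m, nSweeps = length(sweeps), label = lab)
}

#' Build a training library
#'
#' @param signatures List of [SpectralSignature-class], one per solution,
#'   all on one grid.
#' @param concs Numeric vector of concentrations (fractions), parallel to
#'   `signatures`, all distinct.
#' @param solvent,solute,basis Passed to [solutionSpec()] for every entry.
#' @return A [TrainingLibrary-class] with entries sorted by concentration
#'   ascending (so nearest-neighbour ties resolve toward the lower
#'   concentration).
#' @export
trainingLibrary <- function(signatures, concs, solvent = "solvent",
                            solute = "solute", basis = "volume") {
  stopifnot(length(signatures) == length(concs))
  o <- order(concs)
  specs <- lapply(concs[o], function(cc) solutionSpec(solvent, solute, cc, basis))
  new("TrainingLibrary", signatures = signatures[o], specs = specs)
}

#' @rdname rfsig-accessors
#' @export
setMethod("concentrations", "TrainingLibrary", function(x) {
  vapply(x@specs, function(s) s@concentration, numeric(1))
})

#' @rdname rfsig-accessors
#' @export
setMethod("length", "TrainingLibrary", function(x) length(x@signatures))

setMethod("show", "FrequencyGrid", function(object) {
  cat(sprintf("FrequencyGrid: %g-%g MHz, step %g MHz, %d points\n",
              object@startMhz, object@stopMhz, object@stepMhz, object@nPoints))
})

setMethod("show", "Sweep", function(object) {
  cat(sprintf("Sweep #%d (%s): %d points, %g-%g MHz\n",
              object@sweepIndex,
              if (is.na(object@label)) "blinded" else object@label,
              object@grid@nPoints, object@grid@startMhz, object@grid@stopMhz))
})

setMethod("show", "SpectralSignature", function(object) {
  cat(sprintf("SpectralSignature (%s): mean of %d sweep(s) over %d frequencies\n",
              if (is.na(object@label)) "blinded" else object@label,
              object@nSweeps, object@grid@nPoints))
})

setMethod("show", "TrainingLibrary", function(object) {
  cat(sprintf("TrainingLibrary: %d solutions (%s ppm) on %d frequencies\n",
              length(object@signatures),
              paste(vapply(object@specs, function(s) format(ppm(s)), character(1)),
                    collapse = ", "),
              object@signatures[[1]]@grid@nPoints))
})
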