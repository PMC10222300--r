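## Resolving-power arithmetic: the noise floor (rescan self-distance) over
## the distance at a known concentration spacing gives the smallest
## concentration difference distinguishable from rescan noise.

#' Distance-per-ppm slope
#'
#' The L1 distance between two solutions a known spacing apart, divided by
#' that spacing in ppm: how far apart signatures move per ppm of
#' concentration difference.
#'
#' @param referenceDistance L1 distance at the known spacing.
#' @param spacingPpm Concentration spacing (ppm), > 0.
#' @return Distance units per ppm, rounded to one decimal.
#' @export
#' @examples
#' slopePerPpm(864963, 10000)  # 86.5
slopePerPpm <- function(referenceDistance, spacingPpm) {
  stopifnot(referenceDistance >= 0)
  if (spacingPpm <= 0) stop("spacingPpm must be > 0")
  roundHalfUp(referenceDistance / spacingPpm, 1)
}

#' Ratio-based resolution limit
#'
#' Solutions whose signature distance is below the rescan noise floor are
#' indistinguishable from a rescan of the same solution, so the smallest
#' resolvable concentration difference is the noise floor expressed in
#' concentration units through the reference pair:
#' `noiseFloor / referenceDistance * spacingPpm`, rounded to the nearest
#' integer ppm. The ratio is homogeneous of degree 0 in distance units.
#'
#' @param noiseFloor Rescan-vs-training L1 distance of one solution, >= 0.
#' @param referenceDistance L1 distance at the known spacing, > 0.
#' @param spacingPpm Concentration spacing of the reference pair (ppm).
#' @return Resolution limit (ppm), nearest integer.
#' @export
#' @examples
#' resolutionLimit(33157, 864963, 10000)  # 383
#' resolutionLimit(19475, 156608, 2000)   # 249
resolutionLimit <- function(noiseFloor, referenceDistance, spacingPpm) {
  if (noiseFloor < 0) stop("noiseFloor must be >= 0")
  if (referenceDistance <= 0) stop("referenceDistance must be > 0")
  if (spacingPpm <= 0) stop("spacingPpm must be > 0")
  roundHalfUp(noiseFloor / referenceDistance * spacingPpm, 0)
}

#' Compose a ResolutionEstimate from its operands
#'
#' @inheritParams resolutionLimit
#' @return A [ResolutionEstimate-class] with the derived slope and limit.
#' @export
resolutionEstimate <- function(noiseFloor, referenceDistance, spacingPpm) {
  new("ResolutionEstimate",
      noiseFloor = noiseFloor, referenceDistance = referenceDistance,
      spacingPpm = spacingPpm,
      slopePerPpm = slopePerPpm(referenceDistance, spacingPpm),
      resolutionPpm = resolutionLimit(noiseFloor, referenceDistance, spacingPpm))
}

#' Estimate the resolution limit from scans
#'
#' Measures the noise floor as the L1 distance between a rescan and the
#' training signature of the same solution, takes the reference distance as
#' the distance from that base solution to the nearest *distinct* training
#' concentration, and composes the ratio-based limit.
#'
#' @param lib A [TrainingLibrary-class] with at least two concentrations.
#' @param rescan A second, independent [SpectralSignature-class] of the
#'   reference solution (label must match the library entry's
#'   concentration via `referenceConcentration`).
#' @param referenceConcentration Concentration of the rescanned solution.
#' @return A [ResolutionEstimate-class].
#' @export
estimateFromExperiment <- function(lib, rescan, referenceConcentration) {
  concs <- concentrations(lib)
  if (length(concs) < 2L) {
    stop("library must contain at least two concentrations")
  }
  i <- which(concs == referenceConcentration)
  if (length(i) != 1L) stop("reference concentration is not in the library")
  base <- lib@signatures[[i]]
  noiseFloor <- l1Distance(rescan, base)
  j <- setdiff(seq_along(concs), i)
  nearest <- j[which.min(abs(concs[j] - referenceConcentration))]
  refDist <- l1Distance(lib@signatures[[nearest]], base)
  spacing <- abs(concs[nearest] - referenceConcentration) * 1e6
  resolutionEstimate(noiseFloor, refDist, spacing)
}

setMethod("show", "ResolutionEstimate", function(object) {
  cat(sprintf(
    "ResolutionEstimate: noise floor %.6g / reference %.6g at %g ppm spacing\n  slope %.1f per ppm; resolution limit %g ppm\n",
    object@noiseFloor, object@referenceDistance, object@spacingPpm,
    object@slopePerPpm, object@resolutionPpm))
})
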