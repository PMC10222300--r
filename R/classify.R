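## Nearest-neighbour identification in the L1 metric. No normalization,
## baseline subtraction or frequency weighting is applied before the
## distance: the metric is the raw sum of absolute differences.

#' @rdname l1Distance
#' @export
setMethod("l1Distance", signature("SpectralSignature", "SpectralSignature"),
  function(a, b) {
    if (!gridEqual(a@grid, b@grid)) {
      stop("signatures are on different frequency grids")
    }
    sum(abs(a@meanPower - b@meanPower))
  })

#' Identify a blind signature by its nearest neighbour
#'
#' Computes the L1 distance from the blind to every training signature and
#' assigns the concentration of the nearest one. Ties break toward the
#' lower concentration (the library is kept sorted ascending). A blind
#' built from zero sweeps cannot exist as a signature; pass `NULL` to
#' record a missing scan, which yields a `noData` result.
#'
#' @param blind A [SpectralSignature-class], or `NULL` for a missing scan.
#' @param lib A [TrainingLibrary-class] on the same grid.
#' @return An [IdentificationResult-class].
#' @export
identifySignature <- function(blind, lib) {
  stopifnot(is(lib, "TrainingLibrary"))
  concs <- concentrations(lib)
  if (is.null(blind)) {
    return(new("IdentificationResult", assigned = NA_real_, noData = TRUE,
               distances = stats::setNames(rep(NA_real_, length(concs)),
                                           format(concs)),
               margin = NA_real_))
  }
  stopifnot(is(blind, "SpectralSignature"))
  d <- vapply(lib@signatures, l1Distance, numeric(1), b = blind)
  names(d) <- format(concs)
  best <- which.min(d)  # first minimum = lowest concentration on ties
  margin <- if (length(d) > 1L) unname(sort(d)[2L] - d[best]) else NA_real_
  new("IdentificationResult", assigned = concs[best], noData = FALSE,
      distances = d, margin = margin)
}

setMethod("show", "IdentificationResult", function(object) {
  if (object@noData) {
    cat("IdentificationResult: no data\n")
  } else {
    cat(sprintf("IdentificationResult: assigned %g ppm (margin %.4g)\n",
                object@assigned * 1e6, object@margin))
  }
})

#' Distance table relative to a reference solution
#'
#' The tabular view used to report results: the L1 distance from every
#' training signature and every blind signature to the training signature
#' of one reference concentration. The reference's own row is 0 by the
#' metric identity; test rows are sorted ascending by distance ("ordered
#' by nearness").
#'
#' @param lib A [TrainingLibrary-class].
#' @param blinds Named list of [SpectralSignature-class] blinds (may
#'   contain `NULL` for missing scans); optional.
#' @param referenceConcentration A concentration present in `lib`.
#' @return A data frame with columns `role` (`"train"`/`"test"`), `label`,
#'   `ppm` (training concentration, `NA` for blinds), `distance` (`NA` for
#'   missing scans).
#' @export
distanceTable <- function(lib, blinds = list(), referenceConcentration) {
  concs <- concentrations(lib)
  i <- which(concs == referenceConcentration)
  if (length(i) != 1L) stop("reference concentration is not in the library")
  ref <- lib@signatures[[i]]
  train <- data.frame(
    role = "train",
    label = sprintf("%g ppm", concs * 1e6),
    ppm = concs * 1e6,
    distance = vapply(lib@signatures, l1Distance, numeric(1), b = ref))
  if (length(blinds) == 0L) return(train)
  if (is.null(names(blinds))) {
    names(blinds) <- sprintf("Blind-%d", seq_along(blinds))
  }
  test <- data.frame(
    role = "test",
    label = names(blinds),
    ppm = NA_real_,
    distance = vapply(blinds, function(b) {
      if (is.null(b)) NA_real_ else l1Distance(b, ref)
    }, numeric(1)))
  test <- test[order(test$distance, na.last = TRUE), ]
  out <- rbind(train, test)
  rownames(out) <- NULL
  out
}

#' Scalar matching of blinds by distance-to-reference
#'
#' Reproduces the printed-table identification route: each blind is known
#' only by its scalar L1 distance to the reference solution, and is
#' assigned the training concentration whose distance-to-reference is
#' nearest in absolute difference. The reference itself sits at distance 0
#' in the training map. Blinds with a missing distance (`NA`, "no data")
#' pass through unassigned.
#'
#' @param trainingDistances Named numeric: training distance-to-reference,
#'   names are concentrations in ppm; must include the reference at 0.
#' @param blindDistances Named numeric: blind distance-to-reference, `NA`
#'   for a missing scan.
#' @return Named numeric: assigned ppm per blind (`NA` where no data).
#' @export
#' @examples
#' train <- c("0" = 0, "10000" = 873013, "20000" = 1917048)
#' matchBlindsScalar(train, c("Blind-2" = 33157, "Blind-6" = 1910652))
matchBlindsScalar <- function(trainingDistances, blindDistances) {
  if (length(trainingDistances) == 0L) stop("empty training distance map")
  if (is.null(names(trainingDistances))) {
    stop("trainingDistances must be named by concentration (ppm)")
  }
  if (!any(trainingDistances == 0)) {
    stop("training map must include the reference solution at distance 0")
  }
  tppm <- as.numeric(names(trainingDistances))
  o <- order(tppm)  # ties toward the lower concentration
  tppm <- tppm[o]
  td <- trainingDistances[o]
  vapply(blindDistances, function(d) {
    if (is.na(d)) NA_real_ else tppm[which.min(abs(d - td))]
  }, numeric(1))
}

#' Run and score a simulated blind trial
#'
#' Builds a signature from each blinded sweep set (empty sets become
#' no-data results), identifies each against the training library, and
#' scores the assignments against the sealed answer key. No-data blinds
#' are excluded from the accuracy denominator.
#'
#' The default assignment is independent nearest-neighbour per blind — the
#' blinding protocol presents solutions one at a time, so nothing enforces
#' a bijection. `assignment = "oneToOne"` instead minimizes the total L1
#' distance over all bijections between blinds and training entries
#' (enumerated exactly; supported up to 9 assignable blinds), for
#' comparison.
#'
#' @param exp A [SimulatedExperiment-class].
#' @param assignment `"independent"` (default) or `"oneToOne"`.
#' @return A [TrialReport-class].
#' @export
runBlindTrial <- function(exp, assignment = c("independent", "oneToOne")) {
  stopifnot(is(exp, "SimulatedExperiment"))
  assignment <- match.arg(assignment)
  ids <- names(exp@blindSweeps)
  res <- lapply(exp@blindSweeps, function(sw) {
    sig <- if (length(sw) == 0L) NULL else buildSignature(sw)
    identifySignature(sig, exp@training)
  })
  assigned <- vapply(res, function(r) r@assigned, numeric(1))
  noData <- vapply(res, function(r) r@noData, logical(1))
  if (assignment == "oneToOne") {
    assigned[!noData] <- assignOneToOne(res[!noData],
                                        concentrations(exp@training))
  }
  truth <- stats::setNames(exp@answerKey, ids)
  ok <- !noData
  nCorrect <- sum(assigned[ok] == truth[ok])
  new("TrialReport",
      assignments = stats::setNames(assigned, ids),
      truth = truth,
      nCorrect = as.integer(nCorrect),
      nTotal = as.integer(sum(ok)),
      accuracy = nCorrect / sum(ok),
      excluded = ids[noData])
}

## exact minimum-total-distance bijection by enumeration (trials have at
## most 7 solutions, so k! stays tiny)
assignOneToOne <- function(results, concs) {
  k <- length(results)
  if (k > 9L) stop("one-to-one assignment supported for up to 9 blinds")
  D <- do.call(rbind, lapply(results, function(r) unname(r@distances)))
  perms <- permutationsOf(seq_len(ncol(D)), k)
  costs <- vapply(perms, function(p) sum(D[cbind(seq_len(k), p)]), numeric(1))
  concs[perms[[which.min(costs)]]]
}

## all ordered k-tuples of distinct elements of x (k-permutations)
permutationsOf <- function(x, k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutationsOf(x[-i], k - 1L)) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

setMethod("show", "TrialReport", function(object) {
  cat(sprintf("TrialReport: %d/%d assignable blinds correct (accuracy %.3f)%s\n",
              object@nCorrect, object@nTotal, object@accuracy,
              if (length(object@excluded)) {
                sprintf("; excluded (no data): %s",
                        paste(object@excluded, collapse = ", "))
              } else ""))
})
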