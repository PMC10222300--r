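## Orchestration: the five-experiment replication driver. Each experiment
## is a calibrated synthetic blind trial plus a distance table and a
## resolution estimate; the bundle also re-verifies every published scalar
## via replicateTables(). All randomness flows through seeds derived from
## one base seed and recorded in the report.

#' Default replication configuration
#'
#' One entry per supported experiment design:
#' \describe{
#'   \item{exp1}{water in isopropyl alcohol, 0--5% by volume, 10,000 ppm
#'     spacing; calibration noise floor 33,157, reference 864,963.}
#'   \item{exp2}{water in isopropyl alcohol, 0--0.6%, 2000 ppm spacing;
#'     19,475 / 156,608.}
#'   \item{exp3}{NaCl in water by mass, 0--0.4%, 2000 ppm spacing;
#'     84,262 / 692,414.}
#'   \item{exp4}{NaOCl in water, 0--0.6%, 2000 ppm spacing; 96,840 /
#'     2,026,160 at the 4000 ppm pair.}
#'   \item{exp5}{exp1's list plus 100% water, fixed 1 L volume; no
#'     published noise floor of its own, so exp1's calibration is reused
#'     (same solvent system and spacing).}
#' }
#' Calibration targets are the published rescan and separation distances;
#' per-experiment noise and permutation seeds are derived from `seed`.
#'
#' @param seed Base seed (integer).
#' @return A list with elements `seed` and `experiments`.
#' @export
defaultRunConfig <- function(seed = 1L) {
  seed <- as.integer(seed)
  exps <- list(
    list(name = "exp1", solvent = "isopropyl alcohol", solute = "deionized water",
         basis = "volume", concentrations = c(0, 0.01, 0.02, 0.03, 0.04, 0.05),
         noiseFloor = 33157, referenceDistance = 864963, spacingPpm = 10000),
    list(name = "exp2", solvent = "isopropyl alcohol", solute = "deionized water",
         basis = "volume", concentrations = c(0, 0.002, 0.004, 0.006),
         noiseFloor = 19475, referenceDistance = 156608, spacingPpm = 2000),
    list(name = "exp3", solvent = "deionized water", solute = "NaCl",
         basis = "mass", concentrations = c(0, 0.002, 0.004),
         noiseFloor = 84262, referenceDistance = 692414, spacingPpm = 2000),
    list(name = "exp4", solvent = "deionized water", solute = "NaOCl",
         basis = "volume", concentrations = c(0, 0.002, 0.004, 0.006),
         noiseFloor = 96840, referenceDistance = 2026160, spacingPpm = 4000),
    list(name = "exp5", solvent = "isopropyl alcohol", solute = "deionized water",
         basis = "volume", concentrations = c(0, 0.01, 0.02, 0.03, 0.04, 0.05, 1),
         noiseFloor = 33157, referenceDistance = 864963, spacingPpm = 10000))
  for (i in seq_along(exps)) {
    exps[[i]]$noiseSeed <- seed + i
    exps[[i]]$permutationSeed <- seed + 100L + i
  }
  list(seed = seed, experiments = exps)
}

#' Read a replication configuration file
#'
#' Configurations are JSON with the same shape as [defaultRunConfig()]:
#' a top-level `seed` and an `experiments` array whose entries carry
#' `name`, `concentrations`, `noiseFloor`, `referenceDistance`,
#' `spacingPpm` and optionally `noiseSeed` / `permutationSeed` (derived
#' from `seed` when absent, as in [defaultRunConfig()]).
#'
#' @param path Path to a JSON configuration file.
#' @return A configuration list accepted by [runReplication()].
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  for (i in seq_along(cfg$experiments)) {
    e <- cfg$experiments[[i]]
    e$concentrations <- as.numeric(unlist(e$concentrations))
    if (is.null(e$noiseSeed)) e$noiseSeed <- cfg$seed + i
    if (is.null(e$permutationSeed)) e$permutationSeed <- cfg$seed + 100L + i
    e$noiseSeed <- as.integer(e$noiseSeed)
    e$permutationSeed <- as.integer(e$permutationSeed)
    cfg$experiments[[i]] <- e
  }
  cfg
}

## run one configured experiment end to end
runOneExperiment <- function(ec, grid) {
  params <- calibratedParams(ec$noiseFloor, ec$referenceDistance,
                             ec$spacingPpm, grid = grid,
                             seed = ec$noiseSeed)
  exp <- generateExperiment(params, ec$concentrations,
                            permutationSeed = ec$permutationSeed)
  trial <- runBlindTrial(exp)
  blindSigs <- lapply(exp@blindSweeps, function(sw) {
    if (length(sw)) buildSignature(sw) else NULL
  })
  refConc <- min(ec$concentrations)
  dtab <- distanceTable(exp@training, blindSigs, refConc)
  rescan <- simulateSignature(params, refConc)
  res <- estimateFromExperiment(exp@training, rescan, refConc)
  list(name = ec$name,
       seeds = c(noise = ec$noiseSeed, permutation = ec$permutationSeed),
       calibration = c(noiseFloor = ec$noiseFloor,
                       referenceDistance = ec$referenceDistance,
                       spacingPpm = ec$spacingPpm,
                       noiseSigma = params@noiseSigma,
                       responseScale = params@responseScale),
       trial = trial, distanceTable = dtab, resolution = res)
}

#' Run the full replication bundle
#'
#' For every configured experiment: calibrate the generator to the
#' published noise floor and separation, generate a blinded data set, run
#' and score the blind trial, tabulate distances to the base solution, and
#' estimate the resolution limit from a fresh rescan. Also re-verifies all
#' published scalar arithmetic via [replicateTables()]. Reruns with the
#' same config are byte-identical.
#'
#' @param config A configuration list from [defaultRunConfig()].
#' @param grid Acquisition grid, default 1500--3000 MHz at 0.2 MHz.
#' @return A list of class `"replicationReport"` with elements `config`,
#'   `experiments` (each carrying its [TrialReport-class], distance table
#'   and [ResolutionEstimate-class]), `fixtures` (the [replicateTables()]
#'   data frame) and `allPass`.
#' @export
runReplication <- function(config = defaultRunConfig(), grid = defaultGrid()) {
  if (is.null(config$experiments)) stop("config must list experiments")
  for (ec in config$experiments) {
    need <- c("name", "concentrations", "noiseFloor", "referenceDistance",
              "spacingPpm", "noiseSeed", "permutationSeed")
    miss <- need[!need %in% names(ec)]
    if (length(miss)) {
      stop(sprintf("experiment '%s': missing config fields: %s",
                   if (is.null(ec$name)) "?" else ec$name,
                   paste(miss, collapse = ", ")))
    }
    if (length(ec$concentrations) < 2L) {
      stop(sprintf("experiment '%s': need at least two concentrations", ec$name))
    }
  }
  experiments <- lapply(config$experiments, runOneExperiment, grid = grid)
  names(experiments) <- vapply(experiments, `[[`, character(1), "name")
  fixtures <- replicateTables()
  out <- list(config = config,
              experiments = experiments,
              fixtures = fixtures,
              allPass = all(fixtures$pass) &&
                all(vapply(experiments, function(e) e$trial@accuracy == 1,
                           logical(1))))
  class(out) <- "replicationReport"
  out
}

#' @export
print.replicationReport <- function(x, ...) {
  cat("Replication report (base seed", x$config$seed, ")\n")
  for (e in x$experiments) {
    cat(sprintf("  %s: accuracy %.3f (%d/%d), resolution %g ppm\n",
                e$name, e$trial@accuracy, e$trial@nCorrect, e$trial@nTotal,
                e$resolution@resolutionPpm))
  }
  cat(sprintf("  fixture checks: %d/%d pass\n",
              sum(x$fixtures$pass), nrow(x$fixtures)))
  cat(if (isTRUE(x$allPass)) "  ALL PASS\n" else "  FAILURES PRESENT\n")
  invisible(x)
}

#' Write a replication report bundle to disk
#'
#' Emits `report.json` (seeds, calibrations, trial scores, resolution
#' estimates, fixture checks) plus one distance-table CSV per experiment
#' and `fixture_checks.csv`.
#'
#' @param report A `"replicationReport"` from [runReplication()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReplicationReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- list(
    seed = report$config$seed,
    experiments = lapply(report$experiments, function(e) {
      list(name = e$name, seeds = as.list(e$seeds),
           calibration = as.list(e$calibration),
           accuracy = e$trial@accuracy,
           n_correct = e$trial@nCorrect, n_total = e$trial@nTotal,
           excluded = e$trial@excluded,
           assignments = as.list(e$trial@assignments),
           truth = as.list(e$trial@truth),
           resolution = list(noise_floor = e$resolution@noiseFloor,
                             reference_distance = e$resolution@referenceDistance,
                             spacing_ppm = e$resolution@spacingPpm,
                             slope_per_ppm = e$resolution@slopePerPpm,
                             resolution_ppm = e$resolution@resolutionPpm))
    }),
    fixture_checks = report$fixtures,
    all_pass = report$allPass)
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (e in report$experiments) {
    utils::write.csv(e$distanceTable,
                     file.path(dir, sprintf("distance_table_%s.csv", e$name)),
                     row.names = FALSE)
  }
  utils::write.csv(report$fixtures, file.path(dir, "fixture_checks.csv"),
                   row.names = FALSE)
  invisible(dir)
}
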