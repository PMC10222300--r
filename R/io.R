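## Sweep / signature CSV dialect.
## Sweeps:     frequency_mhz,power,sweep_index,label  (one row per frequency per sweep)
## Signatures: frequency_mhz,mean_power,n_sweeps,label
## UTF-8, '.' decimal separator; floats written with 17 significant digits so
## a write/read round trip reproduces every double bit-exactly.

fmtNum <- function(x) formatC(x, format = "g", digits = 17)

## infer and validate a uniform ascending grid from a frequency column
inferGrid <- function(freq) {
  if (length(freq) < 2L) stop("need at least two frequencies to infer a grid")
  d <- diff(freq)
  if (any(d <= 0)) stop("frequency column must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * mean(d)) stop("frequency column is not uniformly spaced")
  makeGrid(freq[1L], freq[length(freq)], mean(d))
}

#' Read and write sweep CSV files
#'
#' `writeSweepsCsv()` writes a list of sweeps to one CSV (one row per
#' frequency per sweep, header `frequency_mhz,power,sweep_index,label`);
#' `readSweepsCsv()` reads it back, inferring and validating the grid. The
#' round trip is lossless: floats are written at full double precision.
#' Files with missing power cells, non-increasing frequencies, or sweeps on
#' differing grids are rejected.
#'
#' @param sweeps Non-empty list of [Sweep-class] objects on one grid.
#' @param path File path.
#' @return `readSweepsCsv()` returns a list of [Sweep-class] objects in
#'   file order; `writeSweepsCsv()` returns `path` invisibly.
#' @export
writeSweepsCsv <- function(sweeps, path) {
  stopifnot(is.list(sweeps), length(sweeps) > 0L)
  rows <- lapply(sweeps, function(s) {
    data.frame(frequency_mhz = fmtNum(frequencies(s@grid)),
               power = fmtNum(s@power),
               sweep_index = s@sweepIndex,
               label = ifelse(is.na(s@label), "", s@label),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSweepsCsv
#' @export
readSweepsCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(frequency_mhz = "numeric",
                                       power = "numeric",
                                       sweep_index = "integer",
                                       label = "character"))
  needed <- c("frequency_mhz", "power", "sweep_index", "label")
  if (!all(needed %in% names(df))) {
    stop("sweep CSV must have columns frequency_mhz, power, sweep_index, label")
  }
  if (anyNA(df$frequency_mhz) || anyNA(df$power) || anyNA(df$sweep_index)) {
    stop("sweep CSV contains missing frequency, power or sweep_index values")
  }
  df$label[df$label == ""] <- NA_character_
  key <- paste(df$label, df$sweep_index, sep = "\r")
  parts <- split(df, factor(key, levels = unique(key)))
  grid <- NULL
  sweeps <- lapply(parts, function(p) {
    g <- inferGrid(p$frequency_mhz)
    if (is.null(grid)) grid <<- g
    else if (!gridEqual(g, grid)) stop("sweeps in one file must share one grid")
    newSweep(grid, p$power, sweepIndex = p$sweep_index[1L], label = p$label[1L])
  })
  unname(sweeps)
}

#' Read and write signature CSV files
#'
#' One row per frequency, header `frequency_mhz,mean_power,n_sweeps,label`.
#' Lossless at full double precision, like the sweep dialect.
#'
#' @param signature A [SpectralSignature-class].
#' @param path File path.
#' @return `readSignatureCsv()` returns a [SpectralSignature-class];
#'   `writeSignatureCsv()` returns `path` invisibly.
#' @export
writeSignatureCsv <- function(signature, path) {
  df <- data.frame(frequency_mhz = fmtNum(frequencies(signature@grid)),
                   mean_power = fmtNum(signature@meanPower),
                   n_sweeps = signature@nSweeps,
                   label = ifelse(is.na(signature@label), "", signature@label),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSignatureCsv
#' @export
readSignatureCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(frequency_mhz = "numeric",
                                       mean_power = "numeric",
                                       n_sweeps = "integer",
                                       label = "character"))
  if (anyNA(df$frequency_mhz) || anyNA(df$mean_power)) {
    stop("signature CSV contains missing values")
  }
  lab <- df$label[1L]
  if (is.na(lab) || lab == "") lab <- NA_character_
  newSignature(inferGrid(df$frequency_mhz), df$mean_power,
               nSweeps = df$n_sweeps[1L], label = lab)
}
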