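#' @name rfsig-accessors
#' @title Accessors for rfsig classes
#' @description Slot accessors. User code should use these rather than `@`.
#' @param x An rfsig object.
#' @param object An rfsig object (for `show`).
NULL

#' @describeIn rfsig-accessors The reconstructed frequency axis (MHz),
#'   strictly increasing, endpoints inclusive.
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @describeIn rfsig-accessors Number of grid points.
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @describeIn rfsig-accessors Received power vector (sensor units).
#' @export
setGeneric("power", function(x) standardGeneric("power"))

#' @describeIn rfsig-accessors Per-frequency mean power of a signature.
#' @export
setGeneric("meanPower", function(x) standardGeneric("meanPower"))

#' @describeIn rfsig-accessors Number of sweeps averaged into a signature.
#' @export
setGeneric("nSweeps", function(x) standardGeneric("nSweeps"))

#' @describeIn rfsig-accessors Solution label (may be `NA` for blinds).
#' @export
setGeneric("label", function(x) standardGeneric("label"))

#' @describeIn rfsig-accessors Concentration(s) as dimensionless fractions.
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @describeIn rfsig-accessors Concentration in parts per million.
#' @export
setGeneric("ppm", function(x) standardGeneric("ppm"))

#' L1 (Manhattan) distance between two spectral signatures
#'
#' The sum over all frequencies of the absolute differences of the
#' per-frequency mean power: `sum(|a(f) - b(f)|)`. This single number is the
#' similarity metric used for nearest-neighbour identification.
#'
#' @param a,b [SpectralSignature-class] objects on identical grids.
#' @return Non-negative scalar distance (sensor units).
#' @export
#' @examples
#' g <- makeGrid(1500, 1500.2, 0.2)
#' s1 <- newSignature(g, c(0, 0))
#' s2 <- newSignature(g, c(1, 2))
#' l1Distance(s1, s2)  # 3
setGeneric("l1Distance", function(a, b) standardGeneric("l1Distance"))
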