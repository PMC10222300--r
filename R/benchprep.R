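## Benchtop solution-preparation arithmetic for the supported experiment
## designs: remove-and-replace volume fractions, solute masses for mass
## fractions, and ideal-mixing densities / masses-for-fixed-volume.
## All results are reported to 0.1 (mL, g, g/L), rounding half away from
## zero, matching benchtop balance/graduation precision.

#' Replacement volume for a target volume fraction
#'
#' To make a solution with solute volume fraction `targetFraction` in a
#' full container, remove `container * fraction / purity` millilitres of
#' solvent and replace them with the solute stock (`stockPurity` < 1 when
#' the stock is itself a dilution, e.g. commercial bleach at 7.5% NaOCl).
#'
#' @param containerMl Container volume (mL).
#' @param targetFraction Target solute volume fraction in \[0, 1\].
#' @param stockPurity Solute fraction of the replacement stock, in (0, 1\].
#' @return Volume to remove and replace (mL), rounded to 0.1 mL.
#' @export
#' @examples
#' replacementVolume(3940, 0.01)            # 39.4
#' replacementVolume(3940, 0.002)           # 7.9
#' replacementVolume(3940, 0.002, 0.075)    # 105.1 (7.5% bleach stock)
replacementVolume <- function(containerMl, targetFraction, stockPurity = 1.0) {
  stopifnot(isScalarNumber(containerMl), containerMl > 0,
            isScalarNumber(targetFraction), isScalarNumber(stockPurity))
  if (stockPurity <= 0 || stockPurity > 1) stop("stockPurity must be in (0, 1]")
  if (targetFraction < 0 || targetFraction > 1) stop("targetFraction must be in [0, 1]")
  v <- containerMl * targetFraction / stockPurity
  if (v > containerMl) {
    stop(sprintf("replacement volume %.1f mL exceeds the container (%g mL)", v, containerMl))
  }
  roundHalfUp(v, 1)
}

#' Solute mass for a target mass fraction
#'
#' @param totalMassG Total solvent mass (g).
#' @param massFraction Target solute mass fraction in \[0, 1\].
#' @return Solute mass to mix in (g), rounded to 0.1 g.
#' @export
#' @examples
#' soluteMass(3000, 0.002)  # 6
#' soluteMass(3000, 0.004)  # 12
soluteMass <- function(totalMassG, massFraction) {
  stopifnot(isScalarNumber(totalMassG), isScalarNumber(massFraction))
  if (totalMassG < 0) stop("totalMassG must be >= 0")
  if (massFraction < 0 || massFraction > 1) stop("massFraction must be in [0, 1]")
  roundHalfUp(totalMassG * massFraction, 1)
}

#' Pure-component density model
#'
#' Defaults are the 25 degree C densities of isopropyl alcohol (solvent,
#' 780.80 g/L) and water (solute, 997.07 g/L).
#'
#' @param rhoSolvent,rhoSolute Pure densities (g/L).
#' @param referenceTemp Reference temperature (degrees C).
#' @return A [DensityModel-class].
#' @export
densityModel <- function(rhoSolvent = 780.80, rhoSolute = 997.07,
                         referenceTemp = 25) {
  new("DensityModel", rhoSolvent = rhoSolvent, rhoSolute = rhoSolute,
      referenceTemp = referenceTemp)
}

#' Ideal-mixing density of a binary solution
#'
#' Linear volumetric mixing, `(1 - c) * rhoSolvent + c * rhoSolute`. With
#' the default model this regenerates the reference water-in-isopropanol
#' density table (0--5% and 100% water) to 0.1 g/L. No excess-volume
#' correction is applied.
#'
#' @param soluteVolFrac Solute volume fraction in \[0, 1\].
#' @param model A [DensityModel-class]; default water in isopropyl alcohol.
#' @return Mixture density (g/L), rounded to 0.1 g/L.
#' @export
#' @examples
#' mixtureDensity(0)     # 780.8
#' mixtureDensity(0.02)  # 785.1
#' mixtureDensity(1)     # 997.1
mixtureDensity <- function(soluteVolFrac, model = densityModel()) {
  stopifnot(is.numeric(soluteVolFrac), all(is.finite(soluteVolFrac)))
  if (any(soluteVolFrac < 0 | soluteVolFrac > 1)) {
    stop("soluteVolFrac must be in [0, 1]")
  }
  roundHalfUp((1 - soluteVolFrac) * model@rhoSolvent +
                soluteVolFrac * model@rhoSolute, 1)
}

#' Mass needed to fill a fixed volume
#'
#' Used to dispense an exact volume on a balance: the mass of solution
#' whose volume is `volumeL` litres at density `densityGL`.
#'
#' @param volumeL Target volume (L).
#' @param densityGL Solution density (g/L).
#' @return Mass (g), rounded to 0.1 g.
#' @export
#' @examples
#' massForVolume(1, 780.8)  # 780.8
massForVolume <- function(volumeL, densityGL) {
  stopifnot(isScalarNumber(volumeL), isScalarNumber(densityGL))
  if (volumeL < 0) stop("volumeL must be >= 0")
  if (densityGL <= 0) stop("densityGL must be > 0")
  roundHalfUp(volumeL * densityGL, 1)
}

#' Preparation table for a set of target fractions
#'
#' One row per target: the replacement volume (volume basis), the mixture
#' density under ideal mixing, and the mass needed for 1 L at that density.
#'
#' @param targetFractions Numeric vector of target volume fractions.
#' @param containerMl Container volume (mL), default 3940.
#' @param stockPurity Replacement-stock purity, default 1.
#' @param model [DensityModel-class] for the density columns.
#' @return A data frame with columns `fraction`, `ppm`, `replace_ml`,
#'   `density_g_per_l`, `mass_for_1l_g`.
#' @export
preparationTable <- function(targetFractions, containerMl = 3940,
                             stockPurity = 1.0, model = densityModel()) {
  rv <- vapply(targetFractions, replacementVolume, numeric(1),
               containerMl = containerMl, stockPurity = stockPurity)
  dens <- mixtureDensity(targetFractions, model)
  data.frame(
    fraction = targetFractions,
    ppm = targetFractions * 1e6,
    replace_ml = rv,
    density_g_per_l = dens,
    mass_for_1l_g = vapply(dens, function(d) massForVolume(1, d), numeric(1))
  )
}
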