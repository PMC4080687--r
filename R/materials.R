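# Scanner reference energy (keV) used for the HU calibration of
# reconstructions: HU = 1000 * (mu - mu_water) / mu_water at this energy.
REF_ENERGY_KEV <- 80

# Shared energy grid of the shipped attenuation tables (keV).
TABLE_ENERGIES <- c(40, 50, 60, 80, 100, 150)

#' Construct a material
#'
#' @param name material name.
#' @param density physical density in g/cm^3.
#' @param energies keV bin centers of the mass attenuation table.
#' @param massAtten mass attenuation coefficients in cm^2/g.
#' @param referenceHU nominal HU at the scanner reference energy, `NA` if
#'   not pinned.
#' @return a [Material-class].
#' @export
material <- function(name, density, energies, massAtten, referenceHU = NA_real_) {
  new("Material", name = name, density = density,
      energies = as.numeric(energies), massAtten = as.numeric(massAtten),
      referenceHU = as.numeric(referenceHU))
}

#' Built-in material table
#'
#' Materials known to the simulator: air, water, Solid Water (the
#' water-equivalent phantom plastic, ~11 HU), soft tissue, cortical bone,
#' titanium, steel (iron) and gold, each with a tabulated mass attenuation
#' coefficient over 40-150 keV. The titanium table is anchored at
#' 0.405 cm^2/g at 80 keV, which together with its density of 4.59 g/cm^3
#' gives the linear attenuation coefficient of 1.86 cm^-1 that drives the
#' photon-starvation artifacts around titanium inserts. The remaining
#' tables are synthetic: smooth, monotone values representative of the
#' diagnostic range (absorption edges are not modelled), adequate for
#' producing beam hardening but not for dosimetry.
#'
#' @return named list of [Material-class] objects.
#' @examples
#' linearAttenuation(materialTable()$titanium, 80)  # ~1.86 cm^-1
#' @export
materialTable <- function() {
  E <- TABLE_ENERGIES
  water <- c(0.2683, 0.2269, 0.2059, 0.1837, 0.1707, 0.1505)
  list(
    air = material("air", 0.0012, E,
                   c(0.2485, 0.2080, 0.1875, 0.1662, 0.1541, 0.1356),
                   referenceHU = -1000),
    water = material("water", 1.000, E, water, referenceHU = 0),
    solid_water = material("solid_water", 1.011, E, water, referenceHU = 11),
    soft_tissue = material("soft_tissue", 1.030, E, water, referenceHU = 30),
    bone = material("bone", 1.920, E,
                    c(0.6655, 0.4242, 0.3148, 0.2229, 0.1855, 0.1480)),
    titanium = material("titanium", 4.590, E,
                        c(1.460, 0.840, 0.590, 0.405, 0.330, 0.240)),
    steel = material("steel", 7.870, E,
                     c(3.630, 1.960, 1.210, 0.595, 0.372, 0.196)),
    gold = material("gold", 19.320, E,
                    c(10.80, 6.20, 3.90, 1.830, 1.200, 0.700))
  )
}

#' Linear attenuation coefficient of a material
#'
#' Density times the mass attenuation coefficient interpolated (linearly)
#' at the requested energy. Energies outside the tabulated range are a hard
#' error rather than an extrapolation.
#'
#' @param m a [Material-class].
#' @param energy photon energy in keV (vectorized).
#' @return linear attenuation in cm^-1.
#' @examples
#' linearAttenuation(materialTable()$titanium, 80)  # 0.405 * 4.59 = 1.86
#' @export
linearAttenuation <- function(m, energy) {
  if (any(energy < min(m@energies) - 1e-9) ||
      any(energy > max(m@energies) + 1e-9))
    stop(sprintf("energy outside tabulated range [%g, %g] keV for '%s'",
                 min(m@energies), max(m@energies), m@name))
  m@density * approx(m@energies, m@massAtten, xout = energy, rule = 1)$y
}

# mu of water at the reference energy, the HU calibration constant.
muWaterRef <- function() {
  linearAttenuation(materialTable()$water, REF_ENERGY_KEV)
}

#' Convert between linear attenuation and Hounsfield units
#'
#' Uses the scanner calibration `HU = 1000 (mu - mu_water) / mu_water`
#' with water's attenuation at the reference energy (80 keV).
#'
#' @param mu linear attenuation, cm^-1.
#' @param hu Hounsfield units.
#' @return the converted values.
#' @export
huFromMu <- function(mu) {
  muw <- muWaterRef()
  1000 * (mu - muw) / muw
}

#' @rdname huFromMu
#' @export
muFromHu <- function(hu) {
  muw <- muWaterRef()
  muw * (1 + hu / 1000)
}

#' Construct a spectrum
#'
#' @param energies keV bin centers.
#' @param weights relative fluence per bin; normalized to sum 1.
#' @return a [Spectrum-class].
#' @export
spectrum <- function(energies, weights = rep(1, length(energies))) {
  new("Spectrum", energies = as.numeric(energies),
      weights = as.numeric(weights) / sum(weights))
}

#' @rdname spectrum
#' @param energy single energy in keV for the monochromatic limit.
#' @export
monoSpectrum <- function(energy = REF_ENERGY_KEV) spectrum(energy, 1)

#' Default polychromatic tube spectrum
#'
#' Three bins at 60/80/100 keV with weights 0.3/0.45/0.25 — the minimal
#' spectral structure that produces beam hardening (effective attenuation
#' decreasing with pathlength) behind thick metal.
#'
#' @return a [Spectrum-class].
#' @export
defaultSpectrum <- function() spectrum(c(60, 80, 100), c(0.30, 0.45, 0.25))
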