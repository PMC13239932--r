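# Material table and configuration constructors for the simulator.

# Water linear attenuation (1/mm) at the two effective energies of the
# spectral model (roughly 50 and 70 keV).
.MU_WATER_LOW <- 0.0227
.MU_WATER_HIGH <- 0.0193

#' Default phantom material table
#'
#' Materials of the single-insert phantom: the 3-D printed resin body
#' (density 1.09 g/cm3), the solid-water housing/control, and the three
#' metal cores (aluminum, titanium, 316 stainless steel). Attenuation
#' pairs follow water at the two effective energies for the soft
#' materials and are scaled up with an additional low-energy
#' (photoelectric) boost for the metals so that polychromatic projections
#' beam-harden; nominal HU are the reference CT numbers used by the
#' digital phantom's ground-truth volume (resin +90, solid water 0,
#' aluminum +1200, titanium +8000, stainless steel +12000).
#'
#' @return Named list of \linkS4class{MaterialSpec}: air, resin,
#'   solid_water, aluminum, titanium, stainless_steel.
#' @examples
#' defaultMaterials()$titanium
#' @export
defaultMaterials <- function() {
  list(
    air = materialSpec("air", density = 0.0012, muLow = 0, muHigh = 0,
                       nominalHU = -1000),
    resin = materialSpec("resin", density = 1.09,
                         muLow = 1.09 * .MU_WATER_LOW,
                         muHigh = 1.09 * .MU_WATER_HIGH, nominalHU = 90),
    solid_water = materialSpec("solid_water", density = 1.04,
                               muLow = .MU_WATER_LOW, muHigh = .MU_WATER_HIGH,
                               nominalHU = 0),
    aluminum = materialSpec("aluminum", density = 2.70,
                            muLow = 2.9 * .MU_WATER_LOW,
                            muHigh = 2.2 * .MU_WATER_HIGH, nominalHU = 1200),
    titanium = materialSpec("titanium", density = 4.51,
                            muLow = 14 * .MU_WATER_LOW,
                            muHigh = 9 * .MU_WATER_HIGH, nominalHU = 8000),
    stainless_steel = materialSpec("stainless_steel", density = 7.87,
                                   muLow = 22 * .MU_WATER_LOW,
                                   muHigh = 13 * .MU_WATER_HIGH,
                                   nominalHU = 12000)
  )
}

#' Construct a PhantomSpec
#'
#' Defaults are the physical phantom: 119.0 mm resin body, 50.0 mm depth,
#' 28.0 mm solid-water housing channel, 12.7 mm metal core.
#'
#' @param coreMaterial \linkS4class{MaterialSpec} of the insert core
#'   (default solid water, i.e. the control insert).
#' @param bodyDiameter,bodyDepth,channelDiameter,coreDiameter mm.
#' @param bodyMaterial,housingMaterial \linkS4class{MaterialSpec}.
#' @return A \linkS4class{PhantomSpec}.
#' @examples
#' phantomSpec(coreMaterial = defaultMaterials()$titanium)
#' @export
phantomSpec <- function(coreMaterial = defaultMaterials()$solid_water,
                        bodyDiameter = 119.0, bodyDepth = 50.0,
                        channelDiameter = 28.0, coreDiameter = 12.7,
                        bodyMaterial = defaultMaterials()$resin,
                        housingMaterial = defaultMaterials()$solid_water) {
  new("PhantomSpec", bodyDiameter = bodyDiameter, bodyDepth = bodyDepth,
      channelDiameter = channelDiameter, coreDiameter = coreDiameter,
      bodyMaterial = bodyMaterial, housingMaterial = housingMaterial,
      coreMaterial = coreMaterial)
}

#' Construct a SimConfig
#'
#' @param gridSize voxels per side (default 256).
#' @param pixelSpacing mm/voxel (default 0.5, a 128 mm field of view).
#' @param sliceThickness mm (default 2).
#' @param nSlices axial slices (default 5).
#' @param nAngles projections over 180 degrees (default 180).
#' @param spectrumWeights \code{c(wLow, wHigh)} summing to 1
#'   (default 0.35/0.65).
#' @param photonsPerRay expected unattenuated photons per detector element
#'   (default 1e7, giving roughly 13 HU of annular noise at the default
#'   geometry: a low-noise QA acquisition); \code{Inf} turns Poisson noise
#'   off.
#' @param photonFloor minimum detected count before the log (default 10).
#' @param noiseSeed integer master seed (default 1).
#' @param metalHuThreshold HU threshold for metal-trace segmentation in
#'   the reference MAR (default 2500).
#' @return A \linkS4class{SimConfig}.
#' @examples
#' simConfig(gridSize = 128, nSlices = 3)
#' @export
simConfig <- function(gridSize = 256L, pixelSpacing = 0.5, sliceThickness = 2,
                      nSlices = 5L, nAngles = 180L,
                      spectrumWeights = c(0.35, 0.65), photonsPerRay = 1e7,
                      photonFloor = 10, noiseSeed = 1L,
                      metalHuThreshold = 2500) {
  new("SimConfig", gridSize = as.integer(gridSize),
      pixelSpacing = pixelSpacing, sliceThickness = sliceThickness,
      nSlices = as.integer(nSlices), nAngles = as.integer(nAngles),
      spectrumWeights = spectrumWeights, photonsPerRay = photonsPerRay,
      photonFloor = photonFloor, noiseSeed = as.integer(noiseSeed),
      metalHuThreshold = metalHuThreshold)
}

#' Construct a RadialConfig
#'
#' @param radii mm distances from the insert centre (default
#'   \code{c(12.7, 28.0, 38.0)}: near, mid, far).
#' @param nAngles samples per circle (default 360).
#' @param nSlices consecutive slices analyzed (default 5).
#' @return A \linkS4class{RadialConfig}.
#' @export
radialConfig <- function(radii = c(12.7, 28.0, 38.0), nAngles = 360L,
                         nSlices = 5L) {
  new("RadialConfig", radii = radii, nAngles = as.integer(nAngles),
      nSlices = as.integer(nSlices))
}

#' Construct an AnnulusSpec
#'
#' @param innerRadius,outerRadius mm (defaults 15.0 and 45.0: outside the
#'   28 mm insert channel, inside the 119 mm phantom body).
#' @return An \linkS4class{AnnulusSpec}.
#' @export
annulusSpec <- function(innerRadius = 15.0, outerRadius = 45.0) {
  new("AnnulusSpec", innerRadius = innerRadius, outerRadius = outerRadius)
}
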