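#' @import methods
NULL

# ---------------------------------------------------------------------------
# Core containers
# ---------------------------------------------------------------------------

#' ImageVolume: a 3-D grid of CT numbers
#'
#' The universal currency of every metric in the package: a 3-D array of CT
#' numbers in Hounsfield units (HU) together with its voxel geometry. Voxels
#' are stored as \code{array[row, col, slice]} with R's 1-based indexing;
#' in-plane spacing is assumed isotropic (mm/voxel) and physical positions
#' refer to voxel centres.
#'
#' CT numbers below -1024 HU are clamped on construction (the conventional
#' air floor of 12-bit CT); all values must be finite.
#'
#' @slot voxels numeric 3-D array of HU, \code{[row, col, slice]}.
#' @slot pixelSpacing in-plane spacing, mm/voxel (> 0, isotropic).
#' @slot sliceThickness slice thickness, mm (> 0).
#' @slot originCenter optional \code{c(row, col)} voxel coordinate (1-based,
#'   possibly fractional) of the phantom axis; \code{NA} when unknown.
#' @exportClass ImageVolume
setClass("ImageVolume",
  representation(
    voxels = "array",
    pixelSpacing = "numeric",
    sliceThickness = "numeric",
    originCenter = "numeric"
  ),
  prototype(originCenter = c(NA_real_, NA_real_))
)

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3-D array [row, col, slice]")
  if (!all(is.finite(object@voxels)))
    msg <- c(msg, "all CT numbers must be finite")
  else if (min(object@voxels) < -1024)
    msg <- c(msg, "CT numbers below -1024 HU must be clamped on ingest")
  if (length(object@pixelSpacing) != 1L || !is.finite(object@pixelSpacing) ||
      object@pixelSpacing <= 0)
    msg <- c(msg, "pixelSpacing must be a single positive number")
  if (length(object@sliceThickness) != 1L || !is.finite(object@sliceThickness) ||
      object@sliceThickness <= 0)
    msg <- c(msg, "sliceThickness must be a single positive number")
  if (length(object@originCenter) != 2L)
    msg <- c(msg, "originCenter must have length 2 (row, col)")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageVolume
#'
#' @param voxels 3-D numeric array of CT numbers (HU), \code{[row, col, slice]};
#'   a matrix is promoted to a single-slice volume.
#' @param pixelSpacing in-plane mm/voxel.
#' @param sliceThickness slice thickness in mm.
#' @param originCenter optional \code{c(row, col)} phantom-axis coordinate.
#' @return An \linkS4class{ImageVolume}. Values below -1024 HU are clamped.
#' @examples
#' vol <- imageVolume(array(0, c(64, 64, 3)), pixelSpacing = 0.5,
#'                    sliceThickness = 2)
#' dim(voxels(vol))
#' @export
imageVolume <- function(voxels, pixelSpacing, sliceThickness,
                        originCenter = c(NA_real_, NA_real_)) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  voxels[voxels < -1024] <- -1024
  new("ImageVolume", voxels = voxels, pixelSpacing = as.numeric(pixelSpacing),
      sliceThickness = as.numeric(sliceThickness),
      originCenter = as.numeric(originCenter))
}

# ---------------------------------------------------------------------------
# Materials and phantom geometry
# ---------------------------------------------------------------------------

#' MaterialSpec: physical description of a phantom material
#'
#' Linear attenuation is carried at two effective energies (a "low" and a
#' "high" spectral component); the physical beam-hardening ordering
#' muLow >= muHigh is enforced. \code{nominalHU} is the CT number the
#' material is expected to reconstruct to at the reference (effective)
#' energy and is used by the digital phantom's ground-truth volume.
#'
#' @slot name material label.
#' @slot density g/cm^3 (> 0).
#' @slot muLow,muHigh linear attenuation, 1/mm, at the low/high energy.
#' @slot nominalHU expected reconstructed CT number, HU.
#' @exportClass MaterialSpec
setClass("MaterialSpec",
  representation(name = "character", density = "numeric",
                 muLow = "numeric", muHigh = "numeric", nominalHU = "numeric"))

setValidity("MaterialSpec", function(object) {
  msg <- character()
  if (object@density <= 0) msg <- c(msg, "density must be positive")
  if (object@muLow < 0 || object@muHigh < 0)
    msg <- c(msg, "attenuation coefficients must be nonnegative")
  if (object@muLow < object@muHigh)
    msg <- c(msg, "muLow must be >= muHigh (beam-hardening ordering)")
  if (length(msg)) msg else TRUE
})

#' @rdname MaterialSpec-class
#' @param name,density,muLow,muHigh,nominalHU see slots.
#' @return A \linkS4class{MaterialSpec}.
#' @export
materialSpec <- function(name, density, muLow, muHigh, nominalHU) {
  new("MaterialSpec", name = name, density = density, muLow = muLow,
      muHigh = muHigh, nominalHU = nominalHU)
}

#' PhantomSpec: geometry of the cylindrical single-insert phantom
#'
#' Defaults reproduce the physical phantom the metrics were designed around:
#' a 11.9 cm diameter, 5.0 cm deep resin body with a central 28.0 mm
#' channel holding an insert whose 12.7 mm metal core sits concentrically
#' in a solid-water housing.
#'
#' @slot bodyDiameter,bodyDepth,channelDiameter,coreDiameter mm.
#' @slot bodyMaterial,housingMaterial,coreMaterial \linkS4class{MaterialSpec}.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(bodyDiameter = "numeric", bodyDepth = "numeric",
                 channelDiameter = "numeric", coreDiameter = "numeric",
                 bodyMaterial = "MaterialSpec", housingMaterial = "MaterialSpec",
                 coreMaterial = "MaterialSpec"))

setValidity("PhantomSpec", function(object) {
  if (!(object@coreDiameter < object@channelDiameter &&
        object@channelDiameter < object@bodyDiameter))
    return("need coreDiameter < channelDiameter < bodyDiameter")
  TRUE
})

#' SimConfig: acquisition/reconstruction settings for the simulator
#'
#' @slot gridSize voxels per side of the square in-plane grid.
#' @slot pixelSpacing mm/voxel in-plane.
#' @slot sliceThickness mm.
#' @slot nSlices number of axial slices.
#' @slot nAngles projection count over 180 degrees (>= 90).
#' @slot spectrumWeights \code{c(wLow, wHigh)}, nonnegative, summing to 1.
#' @slot photonsPerRay expected unattenuated photon count per detector
#'   element; \code{Inf} disables Poisson noise.
#' @slot photonFloor minimum detected count before the log (photon
#'   starvation model), >= 1.
#' @slot noiseSeed integer master seed; per-material and per-slice offsets
#'   are derived deterministically from it.
#' @slot metalHuThreshold HU threshold segmenting the metal trace for the
#'   reference MAR (default 2500).
#' @exportClass SimConfig
setClass("SimConfig",
  representation(gridSize = "integer", pixelSpacing = "numeric",
                 sliceThickness = "numeric", nSlices = "integer",
                 nAngles = "integer", spectrumWeights = "numeric",
                 photonsPerRay = "numeric", photonFloor = "numeric",
                 noiseSeed = "integer", metalHuThreshold = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (any(object@spectrumWeights < 0) ||
      abs(sum(object@spectrumWeights) - 1) > 1e-8)
    msg <- c(msg, "spectrumWeights must be nonnegative and sum to 1")
  if (object@photonFloor < 1) msg <- c(msg, "photonFloor must be >= 1")
  if (object@nAngles < 90L) msg <- c(msg, "nAngles must be >= 90")
  if (!is.infinite(object@photonsPerRay) && object@photonsPerRay <= 0)
    msg <- c(msg, "photonsPerRay must be positive")
  if (length(msg)) msg else TRUE
})

#' DigitalPhantom: rasterized phantom ready for simulation
#'
#' Produced by \code{\link{buildDigitalPhantom}}: per-energy linear
#' attenuation maps of one axial slice plus the ground-truth HU volume.
#'
#' @slot muLow,muHigh matrices of linear attenuation (1/mm).
#' @slot truthHU \linkS4class{ImageVolume} of nominal CT numbers.
#' @slot spec the \linkS4class{PhantomSpec} used.
#' @slot config the \linkS4class{SimConfig} used.
#' @exportClass DigitalPhantom
setClass("DigitalPhantom",
  representation(muLow = "matrix", muHigh = "matrix", truthHU = "ImageVolume",
                 spec = "PhantomSpec", config = "SimConfig"))

# ---------------------------------------------------------------------------
# Paired scans
# ---------------------------------------------------------------------------

#' ScanPair: geometry-matched non-MAR and MAR reconstructions
#'
#' @slot nonMAR,mar \linkS4class{ImageVolume}s of identical grid shape,
#'   pixel spacing and slice thickness.
#' @slot scannerLabel free-text scanner/algorithm label.
#' @slot material \linkS4class{MaterialSpec} of the insert core.
#' @exportClass ScanPair
setClass("ScanPair",
  representation(nonMAR = "ImageVolume", mar = "ImageVolume",
                 scannerLabel = "character", material = "MaterialSpec"))

setValidity("ScanPair", function(object) {
  msg <- character()
  if (!identical(dim(object@nonMAR@voxels), dim(object@mar@voxels)))
    msg <- c(msg, "grid shape mismatch between non-MAR and MAR volumes")
  if (!isTRUE(all.equal(object@nonMAR@pixelSpacing, object@mar@pixelSpacing)))
    msg <- c(msg, "pixelSpacing mismatch between non-MAR and MAR volumes")
  if (!isTRUE(all.equal(object@nonMAR@sliceThickness, object@mar@sliceThickness)))
    msg <- c(msg, "sliceThickness mismatch between non-MAR and MAR volumes")
  if (length(msg)) msg else TRUE
})

#' ScanSet: one scanner's pairs for every insert material
#'
#' Holds one \linkS4class{ScanPair} per insert material, exactly one of
#' which (solid water) is the control against which baselines are defined.
#'
#' @slot pairs named list of \linkS4class{ScanPair}s.
#' @slot control name of the control (solid water) entry in \code{pairs}.
#' @slot seedLog named integer vector of the per-material seeds actually
#'   used by the simulator (empty for scanner data).
#' @exportClass ScanSet
setClass("ScanSet",
  representation(pairs = "list", control = "character", seedLog = "integer"))

setValidity("ScanSet", function(object) {
  if (!all(vapply(object@pairs, is, logical(1), "ScanPair")))
    return("pairs must all be ScanPair objects")
  if (length(object@control) != 1L || !object@control %in% names(object@pairs))
    return("exactly one control entry (by name) must exist in pairs")
  TRUE
})

# ---------------------------------------------------------------------------
# Analysis configuration and results
# ---------------------------------------------------------------------------

#' RadialConfig: circular-profile sampling settings
#'
#' @slot radii mm distances from the insert centre, strictly increasing
#'   (defaults 12.7, 28.0, 38.0 mm: near / mid / far).
#' @slot nAngles samples per circle (>= 36).
#' @slot nSlices consecutive slices analyzed (default 5).
#' @exportClass RadialConfig
setClass("RadialConfig",
  representation(radii = "numeric", nAngles = "integer", nSlices = "integer"))

setValidity("RadialConfig", function(object) {
  msg <- character()
  if (is.unsorted(object@radii, strictly = TRUE))
    msg <- c(msg, "radii must be strictly increasing")
  if (any(object@radii <= 0)) msg <- c(msg, "radii must be positive")
  if (object@nAngles < 36L) msg <- c(msg, "nAngles must be >= 36")
  if (object@nSlices < 1L) msg <- c(msg, "nSlices must be >= 1")
  if (length(msg)) msg else TRUE
})

#' CircularProfileSet: sampled circular profiles
#'
#' @slot values array \code{[angle, radius, slice]} of HU samples.
#' @slot radii mm radii sampled.
#' @slot angles radians, uniform over [0, 2*pi).
#' @slot sliceIndices volume slice indices sampled.
#' @slot center per-slice sampling centre, matrix \code{[slice, c(row, col)]}.
#' @exportClass CircularProfileSet
setClass("CircularProfileSet",
  representation(values = "array", radii = "numeric", angles = "numeric",
                 sliceIndices = "integer", center = "matrix"))

#' AnnulusSpec: the donut mask of the volumetric analysis
#'
#' Defaults follow the standard analysis: inner radius 15.0 mm (excluding
#' the insert channel), outer radius 45.0 mm (inside the phantom body).
#' Both boundaries are closed: a voxel centre exactly at a boundary radius
#' is included.
#'
#' @slot innerRadius,outerRadius mm, 0 < inner < outer.
#' @exportClass AnnulusSpec
setClass("AnnulusSpec",
  representation(innerRadius = "numeric", outerRadius = "numeric"))

setValidity("AnnulusSpec", function(object) {
  if (!(object@innerRadius > 0 && object@innerRadius < object@outerRadius))
    return("need 0 < innerRadius < outerRadius")
  TRUE
})

#' BaselineReference: solid-water control statistics
#'
#' Per-radius circular-profile means and the annular mean of the solid-water
#' control scan, computed separately for the non-MAR and MAR arms. Every
#' deviation metric in the package is defined against these values.
#'
#' @slot radii mm radii of \code{perRadiusMean} rows.
#' @slot perRadiusMean matrix \code{[radius, arm]}, columns "nonMAR", "MAR".
#' @slot globalMean named numeric(2): mean over all sampled circle values
#'   per arm (the single-global-baseline alternative).
#' @slot annulusMean named numeric(2): mean HU over the donut mask per arm.
#' @slot source label of the control scan.
#' @slot spacing in-plane mm/voxel of the control scan, used to reject
#'   deviation computations against geometry-mismatched volumes.
#' @exportClass BaselineReference
setClass("BaselineReference",
  representation(radii = "numeric", perRadiusMean = "matrix",
                 globalMean = "numeric", annulusMean = "numeric",
                 source = "character", spacing = "numeric"))

setValidity("BaselineReference", function(object) {
  if (!all(is.finite(object@perRadiusMean)) ||
      !all(is.finite(object@annulusMean)))
    return("baseline statistics must be finite")
  TRUE
})

#' DiameterResult: geometric accuracy of the reconstructed metal core
#'
#' @slot perSliceDiameters mm, one per analyzed slice (NA where
#'   segmentation failed).
#' @slot meanDiameter mm, mean of per-slice diameters.
#' @slot diameterErrorMM mean of |d_i - dTrue| over slices.
#' @slot diameterErrorSD SD of |d_i - dTrue| over slices.
#' @slot percentError mean of |d_i - dTrue| / dTrue * 100.
#' @slot percentErrorSD SD of the per-slice percent errors.
#' @slot dTrue mm, the known physical diameter (default 12.7).
#' @slot failedSlices indices of slices where segmentation failed.
#' @exportClass DiameterResult
setClass("DiameterResult",
  representation(perSliceDiameters = "numeric", meanDiameter = "numeric",
                 diameterErrorMM = "numeric", diameterErrorSD = "numeric",
                 percentError = "numeric", percentErrorSD = "numeric",
                 dTrue = "numeric", failedSlices = "integer"))

#' MErrorResult: annular bad-voxel statistics and the M-error index
#'
#' For each arm: the percentage of annulus voxels whose CT number deviates
#' beyond the threshold from the expected solid-water value, its SD across
#' slices, the mean absolute deviation of those bad voxels, and the
#' composite index M_error = badFraction/100 * mean|dCTN|_bad. deltaMError
#' is M_error(non-MAR) - M_error(MAR); higher values indicate greater
#' artifact suppression by MAR.
#'
#' @slot badFractionPct,badFractionSD,meanAbsDctnBad,mError named
#'   numeric(2), elements "nonMAR" and "MAR".
#' @slot deltaMError numeric(1).
#' @slot thresholdHU HU classification threshold (default 40; strict
#'   inequality).
#' @slot nSlices number of slices analyzed.
#' @exportClass MErrorResult
setClass("MErrorResult",
  representation(badFractionPct = "numeric", badFractionSD = "numeric",
                 meanAbsDctnBad = "numeric", mError = "numeric",
                 deltaMError = "numeric", thresholdHU = "numeric",
                 nSlices = "integer"))

setValidity("MErrorResult", function(object) {
  ok <- abs(object@mError -
            object@badFractionPct / 100 * object@meanAbsDctnBad) < 1e-9
  if (!all(ok)) return("mError must equal badFractionPct/100 * meanAbsDctnBad")
  if (any(object@mError < 0)) return("mError must be nonnegative")
  TRUE
})

#' DeltaCTNHistogram: accumulated histogram of annular CT-number deviations
#'
#' Deviations are binned at fixed (default 5 HU) intervals with edges
#' aligned to multiples of the bin width; \code{cumulativeFraction[i]} is
#' the fraction of annulus voxels with deviation <= \code{binEdges[i]}.
#'
#' @slot binEdges HU right edges.
#' @slot cumulativeFraction non-decreasing, ending at exactly 1.
#' @slot signedMode TRUE for signed deviations, FALSE for absolute.
#' @slot binWidth HU.
#' @exportClass DeltaCTNHistogram
setClass("DeltaCTNHistogram",
  representation(binEdges = "numeric", cumulativeFraction = "numeric",
                 signedMode = "logical", binWidth = "numeric"))

setValidity("DeltaCTNHistogram", function(object) {
  msg <- character()
  if (length(object@binEdges) != length(object@cumulativeFraction))
    msg <- c(msg, "binEdges and cumulativeFraction lengths differ")
  if (is.unsorted(object@cumulativeFraction))
    msg <- c(msg, "cumulativeFraction must be non-decreasing")
  n <- length(object@cumulativeFraction)
  if (n && object@cumulativeFraction[n] != 1)
    msg <- c(msg, "cumulativeFraction must end at exactly 1")
  if (length(msg)) msg else TRUE
})

#' DiffMap: a CT-number difference map with display clipping
#'
#' delta = CTN(non-MAR) - CTN(MAR) on one axial slice. Percentile clipping
#' sets only the display range; stored delta values are never altered.
#'
#' @slot delta matrix of HU differences.
#' @slot clipLoPct,clipHiPct percentiles used for the display range.
#' @slot displayRange numeric(2) HU after clipping (NA before clipping).
#' @slot sharedScale optional fixed HU range for cross-system comparison
#'   (numeric(2) or NA).
#' @exportClass DiffMap
setClass("DiffMap",
  representation(delta = "matrix", clipLoPct = "numeric", clipHiPct = "numeric",
                 displayRange = "numeric", sharedScale = "numeric"),
  prototype(clipLoPct = NA_real_, clipHiPct = NA_real_,
            displayRange = c(NA_real_, NA_real_),
            sharedScale = c(NA_real_, NA_real_)))

setValidity("DiffMap", function(object) {
  dr <- object@displayRange
  if (all(is.finite(dr)) && dr[1] >= dr[2])
    return("displayRange lower bound must be below upper bound")
  TRUE
})
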