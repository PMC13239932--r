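# Accessor generics and show methods. Slots are never accessed with @ by
# user code; these accessors are the supported surface.

#' @name accessors
#' @title Accessors for MARbench classes
#' @param object an object of the documented class.
#' @param arm which reconstruction arm, "nonMAR" or "MAR".
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setMethod("voxels", "ImageVolume", function(object) object@voxels)

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "ImageVolume", function(object) object@pixelSpacing)

#' @rdname accessors
#' @export
setGeneric("sliceThickness", function(object) standardGeneric("sliceThickness"))
#' @rdname accessors
#' @export
setMethod("sliceThickness", "ImageVolume", function(object) object@sliceThickness)

#' @rdname accessors
#' @export
setGeneric("nSlices", function(object) standardGeneric("nSlices"))
#' @rdname accessors
#' @export
setMethod("nSlices", "ImageVolume", function(object) dim(object@voxels)[3L])

#' @rdname accessors
#' @export
setGeneric("armVolume", function(object, arm = c("nonMAR", "MAR"))
  standardGeneric("armVolume"))
#' @rdname accessors
#' @export
setMethod("armVolume", "ScanPair", function(object, arm = c("nonMAR", "MAR")) {
  arm <- match.arg(arm)
  if (arm == "nonMAR") object@nonMAR else object@mar
})

#' @rdname accessors
#' @export
setGeneric("insertMaterial", function(object) standardGeneric("insertMaterial"))
#' @rdname accessors
#' @export
setMethod("insertMaterial", "ScanPair", function(object) object@material)

#' @rdname accessors
#' @export
setGeneric("scanPairs", function(object) standardGeneric("scanPairs"))
#' @rdname accessors
#' @export
setMethod("scanPairs", "ScanSet", function(object) object@pairs)

#' @rdname accessors
#' @export
setGeneric("controlPair", function(object) standardGeneric("controlPair"))
#' @rdname accessors
#' @export
setMethod("controlPair", "ScanSet", function(object)
  object@pairs[[object@control]])

#' @rdname accessors
#' @export
setGeneric("mErrorIndex", function(object, ...) standardGeneric("mErrorIndex"))

#' @rdname accessors
#' @export
setGeneric("deltaValues", function(object) standardGeneric("deltaValues"))
#' @rdname accessors
#' @export
setMethod("deltaValues", "DiffMap", function(object) object@delta)

#' @rdname accessors
#' @export
setGeneric("displayRange", function(object) standardGeneric("displayRange"))
#' @rdname accessors
#' @export
setMethod("displayRange", "DiffMap", function(object) object@displayRange)

# -- show methods -----------------------------------------------------------

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume: %d x %d x %d voxels, %.3g mm in-plane, %.3g mm slices\n",
              d[1], d[2], d[3], object@pixelSpacing, object@sliceThickness))
  cat(sprintf("  HU range: [%.1f, %.1f]\n", min(object@voxels), max(object@voxels)))
})

setMethod("show", "MaterialSpec", function(object) {
  cat(sprintf("MaterialSpec '%s': density %.3g g/cm3, mu %.4g/%.4g 1/mm, nominal %+.0f HU\n",
              object@name, object@density, object@muLow, object@muHigh,
              object@nominalHU))
})

setMethod("show", "ScanPair", function(object) {
  cat(sprintf("ScanPair [%s, insert: %s]\n", object@scannerLabel,
              object@material@name))
  cat("  non-MAR: "); show(object@nonMAR)
  cat("  MAR:     "); show(object@mar)
})

setMethod("show", "ScanSet", function(object) {
  cat(sprintf("ScanSet: %d pairs (control: %s)\n", length(object@pairs),
              object@control))
  for (nm in names(object@pairs))
    cat(sprintf("  %-16s %s\n", nm,
                if (nm == object@control) "[control]" else ""))
})

setMethod("show", "BaselineReference", function(object) {
  cat(sprintf("BaselineReference from %s\n", object@source))
  m <- object@perRadiusMean
  for (i in seq_along(object@radii))
    cat(sprintf("  r = %5.1f mm: nonMAR %8.2f HU, MAR %8.2f HU\n",
                object@radii[i], m[i, "nonMAR"], m[i, "MAR"]))
  cat(sprintf("  annulus mean: nonMAR %8.2f HU, MAR %8.2f HU\n",
              object@annulusMean["nonMAR"], object@annulusMean["MAR"]))
})

setMethod("show", "DiameterResult", function(object) {
  cat(sprintf("DiameterResult (d_true = %.2f mm, %d slices)\n", object@dTrue,
              length(object@perSliceDiameters)))
  cat(sprintf("  mean diameter: %.2f mm\n", object@meanDiameter))
  cat(sprintf("  diameter error: %.2f +/- %.2f mm\n", object@diameterErrorMM,
              object@diameterErrorSD))
  cat(sprintf("  percent error: %.2f +/- %.2f %%\n", object@percentError,
              object@percentErrorSD))
  if (length(object@failedSlices))
    cat("  failed slices:", paste(object@failedSlices, collapse = ", "), "\n")
})

setMethod("show", "MErrorResult", function(object) {
  cat(sprintf("MErrorResult (|dCTN| > %g HU, %d slices)\n", object@thresholdHU,
              object@nSlices))
  for (arm in c("nonMAR", "MAR"))
    cat(sprintf("  %-7s bad %.2f +/- %.2f %%, mean|dCTN|_bad %.1f HU, M_error %.2f\n",
                arm, object@badFractionPct[arm], object@badFractionSD[arm],
                object@meanAbsDctnBad[arm], object@mError[arm]))
  cat(sprintf("  delta M_error: %.2f\n", object@deltaMError))
})

setMethod("show", "DiffMap", function(object) {
  cat(sprintf("DiffMap: %d x %d, delta range [%.1f, %.1f] HU\n",
              nrow(object@delta), ncol(object@delta), min(object@delta),
              max(object@delta)))
  if (all(is.finite(object@displayRange)))
    cat(sprintf("  display range (P%g-P%g): [%.2f, %.2f] HU\n",
                object@clipLoPct, object@clipHiPct, object@displayRange[1],
                object@displayRange[2]))
})

setMethod("show", "DeltaCTNHistogram", function(object) {
  cat(sprintf("DeltaCTNHistogram: %d bins of %g HU (%s mode), edges [%g, %g]\n",
              length(object@binEdges), object@binWidth,
              if (object@signedMode) "signed" else "absolute",
              min(object@binEdges), max(object@binEdges)))
})
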