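# Volumetric annular analysis: bad-voxel classification, the composite
# M-error index, and accumulated delta-CTN histograms.

#' Build the donut mask for one slice
#'
#' A voxel is included iff its centre lies between the inner and outer
#' radii (both boundaries closed), distances in mm from \code{center}.
#'
#' @param shape \code{c(nrow, ncol)} of the slice.
#' @param spec an \linkS4class{AnnulusSpec}.
#' @param spacing mm/voxel.
#' @param center \code{c(row, col)}, 1-based.
#' @return logical matrix.
#' @export
annularMask <- function(shape, spec, spacing, center) {
  rVox <- spec@outerRadius / spacing
  if (center[1L] - rVox < 1 || center[1L] + rVox > shape[1L] ||
      center[2L] - rVox < 1 || center[2L] + rVox > shape[2L])
    stop("outer radius ", spec@outerRadius, " mm exceeds the image extent")
  d2 <- .distSq(shape[1L], shape[2L], center, spacing)
  d2 >= spec@innerRadius^2 & d2 <= spec@outerRadius^2
}

#' Summarize bad voxels from per-slice deviations
#'
#' The computational core of the bad-voxel analysis, exposed directly so
#' that hand-enumerable toy inputs can exercise it: given per-slice vectors
#' of CT-number deviations from the expected solid-water value, classifies
#' a voxel as bad iff |deviation| strictly exceeds the threshold, and
#' returns the pooled bad fraction (percent of all voxels), its SD across
#' slices, and the mean absolute deviation of the bad voxels (0 when there
#' are none).
#'
#' @param deltaBySlice list of numeric vectors, one per slice.
#' @param thresholdHU classification threshold (default 40 HU).
#' @return list with badFractionPct, badFractionSD, meanAbsDctnBad,
#'   nVoxels, nBad.
#' @examples
#' badVoxelSummary(list(c(0, 10, 39, 40, -40, 41, -41, 100, -100)))
#' @export
badVoxelSummary <- function(deltaBySlice, thresholdHU = 40) {
  stopifnot(length(deltaBySlice) >= 1L)
  bad <- lapply(deltaBySlice, function(d) abs(d) > thresholdHU)
  nVox <- sum(lengths(deltaBySlice))
  if (nVox == 0L) stop("empty annulus: no voxels to classify")
  nBad <- as.integer(sum(vapply(bad, sum, numeric(1))))
  perSlicePct <- vapply(seq_along(bad), function(i)
    100 * mean(bad[[i]]), numeric(1))
  absBad <- abs(unlist(deltaBySlice, use.names = FALSE))
  absBad <- absBad[absBad > thresholdHU]
  list(badFractionPct = 100 * nBad / nVox,
       badFractionSD = .sd0(perSlicePct),
       meanAbsDctnBad = if (nBad > 0) mean(absBad) else 0,
       nVoxels = nVox, nBad = nBad)
}

# Resolve a baseline argument (BaselineReference or fixed HU constant) to
# the expected solid-water HU for one arm.
.baselineHU <- function(baseline, arm) {
  if (is(baseline, "BaselineReference")) baseline@annulusMean[[arm]]
  else if (is.numeric(baseline) && length(baseline) == 1L) baseline
  else stop("baseline must be a BaselineReference or a single HU value")
}

# Per-slice annulus deviation vectors of one volume.
.annulusDeltas <- function(volume, baselineHU, annulus, slices) {
  lapply(slices, function(s) {
    sl <- volume@voxels[, , s]
    ctr <- findInsertCenter(sl, volume@pixelSpacing)
    sl[annularMask(dim(sl), annulus, volume@pixelSpacing, ctr)] - baselineHU
  })
}

#' Bad-voxel statistics of one reconstruction arm
#'
#' Applies the donut mask to each analyzed slice, computes the CT-number
#' deviation of every annulus voxel from the expected solid-water value
#' (the control's annular mean of the matching arm, or a fixed constant),
#' and summarizes voxels deviating beyond the threshold.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param baseline a \linkS4class{BaselineReference} or a single expected
#'   HU value.
#' @param annulus an \linkS4class{AnnulusSpec}.
#' @param arm which arm's baseline to use when \code{baseline} is a
#'   \linkS4class{BaselineReference}.
#' @param thresholdHU classification threshold, strict (default 40 HU).
#' @param slices slice indices analyzed (default: all).
#' @return list as \code{\link{badVoxelSummary}}, plus thresholdHU,
#'   baselineHU and nSlices.
#' @export
badVoxelStats <- function(volume, baseline, annulus = annulusSpec(),
                          arm = c("nonMAR", "MAR"), thresholdHU = 40,
                          slices = NULL) {
  arm <- match.arg(arm)
  if (is.null(slices)) slices <- seq_len(nSlices(volume))
  base <- .baselineHU(baseline, arm)
  out <- badVoxelSummary(.annulusDeltas(volume, base, annulus, slices),
                         thresholdHU)
  out$thresholdHU <- thresholdHU
  out$baselineHU <- base
  out$nSlices <- length(slices)
  out
}

#' @rdname accessors
#' @param meanAbsDctnBad mean |deviation| of bad voxels, HU (numeric
#'   method).
#' @export
setMethod("mErrorIndex", "list", function(object, ...)
  object$badFractionPct / 100 * object$meanAbsDctnBad)

#' @rdname accessors
#' @export
setMethod("mErrorIndex", "numeric", function(object, meanAbsDctnBad, ...)
  object / 100 * meanAbsDctnBad)

#' M-error and delta-M-error of a scan pair
#'
#' Computes bad-voxel statistics and the composite index
#' \code{M_error = badFraction/100 * mean|dCTN|_bad} for both arms, each
#' against its own arm's control baseline, and their difference
#' \code{deltaMError = M_error(non-MAR) - M_error(MAR)} (higher means
#' greater improvement from MAR).
#'
#' @param pair a \linkS4class{ScanPair}.
#' @param baseline a \linkS4class{BaselineReference} or fixed HU value.
#' @param annulus an \linkS4class{AnnulusSpec}.
#' @param thresholdHU classification threshold (default 40 HU).
#' @param slices slice indices analyzed (default: all).
#' @return An \linkS4class{MErrorResult}.
#' @export
deltaMError <- function(pair, baseline, annulus = annulusSpec(),
                        thresholdHU = 40, slices = NULL) {
  stopifnot(is(pair, "ScanPair"))
  arms <- c("nonMAR", "MAR")
  get1 <- function(arm) badVoxelStats(armVolume(pair, arm), baseline, annulus,
                                      arm, thresholdHU, slices)
  st <- lapply(stats::setNames(arms, arms), get1)
  pull <- function(f) vapply(st, `[[`, numeric(1), f)
  m <- vapply(st, mErrorIndex, numeric(1))
  new("MErrorResult", badFractionPct = pull("badFractionPct"),
      badFractionSD = pull("badFractionSD"),
      meanAbsDctnBad = pull("meanAbsDctnBad"), mError = m,
      deltaMError = unname(m["nonMAR"] - m["MAR"]),
      thresholdHU = thresholdHU, nSlices = st[[1L]]$nSlices)
}

#' Accumulated histogram of annular CT-number deviations
#'
#' Deviations of annulus voxels from the expected solid-water value are
#' pooled across the analyzed slices and binned at \code{binWidth} HU with
#' edges aligned to multiples of the bin width; the cumulative fraction at
#' each right edge is the fraction of voxels with deviation at or below
#' it. Signed deviations are the default (negative/positive tails showing
#' under-/overestimation); \code{signed = FALSE} bins |deviation| instead.
#'
#' @param x an \linkS4class{ImageVolume} or \linkS4class{ScanPair} (for a
#'   pair, both arms are returned).
#' @param baseline a \linkS4class{BaselineReference} or fixed HU value.
#' @param annulus an \linkS4class{AnnulusSpec}.
#' @param binWidth HU, positive (default 5).
#' @param signed logical (default TRUE).
#' @param slices slice indices analyzed (default: all).
#' @param arm baseline arm for a single volume.
#' @return A \linkS4class{DeltaCTNHistogram}, or a named list of two for a
#'   pair.
#' @export
cumulativeHist <- function(x, baseline, annulus = annulusSpec(), binWidth = 5,
                           signed = TRUE, slices = NULL,
                           arm = c("nonMAR", "MAR")) {
  if (binWidth <= 0) stop("binWidth must be positive")
  if (is(x, "ScanPair")) {
    arms <- c("nonMAR", "MAR")
    return(lapply(stats::setNames(arms, arms), function(a)
      cumulativeHist(armVolume(x, a), baseline, annulus, binWidth, signed,
                     slices, arm = a)))
  }
  stopifnot(is(x, "ImageVolume"))
  arm <- match.arg(arm)
  if (is.null(slices)) slices <- seq_len(nSlices(x))
  d <- unlist(.annulusDeltas(x, .baselineHU(baseline, arm), annulus, slices),
              use.names = FALSE)
  if (length(d) == 0L) stop("empty annulus: nothing to bin")
  if (!signed) d <- abs(d)
  edges <- seq(binWidth * floor(min(d) / binWidth),
               binWidth * ceiling(max(d) / binWidth), by = binWidth)
  frac <- vapply(edges, function(e) mean(d <= e), numeric(1))
  frac[length(frac)] <- 1  # guard against fp wobble at the final edge
  new("DeltaCTNHistogram", binEdges = edges, cumulativeFraction = frac,
      signedMode = signed, binWidth = binWidth)
}
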