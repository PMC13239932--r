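# Delta-CTN difference maps with percentile display clipping.

#' Difference map of a scan pair
#'
#' Element-wise CTN(non-MAR) - CTN(MAR) on one axial slice. Positive
#' values mark voxels the MAR correction lowered; the map of the control
#' pair is identically zero when MAR is a no-op.
#'
#' @param pair a validated \linkS4class{ScanPair}.
#' @param sliceIndex axial slice, 1-based.
#' @return A \linkS4class{DiffMap} (display range unset until
#'   \code{\link{clipPercentiles}}).
#' @export
deltaMap <- function(pair, sliceIndex) {
  stopifnot(is(pair, "ScanPair"))
  if (sliceIndex < 1L || sliceIndex > nSlices(pair@nonMAR))
    stop("slice index ", sliceIndex, " out of range 1..",
         nSlices(pair@nonMAR))
  new("DiffMap", delta = pair@nonMAR@voxels[, , sliceIndex] -
        pair@mar@voxels[, , sliceIndex])
}

#' Clip the display range of a difference map
#'
#' Sets the display range to the (lo, hi) percentiles of the stored delta
#' distribution, suppressing isolated noise spikes from the colour scale.
#' Percentiles use linear interpolation between order statistics
#' (\code{stats::quantile} type 7). Stored delta values are never altered.
#' A degenerate (constant) map gets a range widened to +/- 1 HU around the
#' constant, with a warning.
#'
#' @param map a \linkS4class{DiffMap}.
#' @param lo,hi percentiles in [0, 100], lo < hi (defaults 3 and 97).
#' @return the map with \code{displayRange} set.
#' @examples
#' m <- new("DiffMap", delta = matrix(1:100, 10, 10))
#' displayRange(clipPercentiles(m))  # c(3.97, 97.03)
#' @export
clipPercentiles <- function(map, lo = 3, hi = 97) {
  stopifnot(is(map, "DiffMap"))
  if (!(lo >= 0 && hi <= 100 && lo < hi))
    stop("need 0 <= lo < hi <= 100")
  rng <- unname(stats::quantile(map@delta, c(lo, hi) / 100, type = 7))
  if (rng[1L] == rng[2L]) {
    warning("degenerate delta distribution; widening display range to +/- 1 HU")
    rng <- rng + c(-1, 1)
  }
  initialize(map, clipLoPct = lo, clipHiPct = hi, displayRange = rng)
}
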