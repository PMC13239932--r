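# Circular CT-number profiles and mean absolute deviation from the
# solid-water baseline.
#
# Streaks radiate in all directions from a metal insert, so a line profile
# sees bright or dark streaks depending on where it is drawn; a circle of
# fixed radius samples them all. The deviation metric is the mean of
# per-sample absolute deviations (never the absolute deviation of the
# mean), so bright and dark streaks cannot cancel.

#' Sample a circular profile
#'
#' CT numbers on the circle of radius \code{radiusMM} about \code{center},
#' by bilinear interpolation at \code{nAngles} uniformly spaced angles over
#' [0, 360). Angle 0 points along the +column axis and angles advance
#' counter-clockwise (towards +row).
#'
#' @param slice2d numeric matrix of CT numbers.
#' @param center \code{c(row, col)}, 1-based voxel coordinates (fractional
#'   allowed).
#' @param radiusMM circle radius, mm; the circle must lie fully inside the
#'   slice.
#' @param nAngles samples per circle.
#' @param spacing mm/voxel.
#' @return numeric vector of length \code{nAngles}.
#' @examples
#' m <- matrix(100, 64, 64)
#' unique(sampleCircle(m, c(32.5, 32.5), 10, 36, 1))
#' @export
sampleCircle <- function(slice2d, center, radiusMM, nAngles, spacing) {
  rVox <- radiusMM / spacing
  if (center[1L] - rVox < 1 || center[1L] + rVox > nrow(slice2d) ||
      center[2L] - rVox < 1 || center[2L] + rVox > ncol(slice2d))
    stop("circle of radius ", radiusMM, " mm exits the image bounds")
  theta <- 2 * pi * (seq_len(nAngles) - 1L) / nAngles
  .bilinear(slice2d, center[1L] + rVox * sin(theta),
            center[2L] + rVox * cos(theta))
}

#' Locate the insert centre on a slice
#'
#' The centroid of the 50\%-of-max metal mask when metal is present in the
#' channel ROI; otherwise (e.g. the solid-water control) the centroid of
#' the phantom body disk.
#'
#' @param slice2d numeric matrix of CT numbers.
#' @param spacing mm/voxel.
#' @param roiRadiusMM channel ROI radius for metal segmentation (mm).
#' @return \code{c(row, col)}, 1-based.
#' @export
findInsertCenter <- function(slice2d, spacing, roiRadiusMM = 14) {
  body <- .bodyCentroid(slice2d)
  mask <- tryCatch(segmentMetalMask(slice2d, body, roiRadiusMM, spacing),
                   error = function(e) NULL)
  if (is.null(mask)) body else .maskCentroid(mask)
}

#' Select the analysis slices
#'
#' The \code{n} consecutive slices centred on the slice whose metal mask
#' (voxels at or above \code{metalHuThreshold}) has maximal area; ties take
#' the lower index. When no slice contains metal (solid-water control) the
#' window is centred on the mid-slice. The window is shifted, never
#' shortened, at volume boundaries.
#'
#' @param volume an \linkS4class{ImageVolume} with at least \code{n} slices.
#' @param n number of consecutive slices (default 5).
#' @param metalHuThreshold HU defining the metal mask.
#' @return integer vector of \code{n} slice indices.
#' @export
selectCentralSlices <- function(volume, n = 5L, metalHuThreshold = 2500) {
  ns <- nSlices(volume)
  if (ns < n)
    stop("volume has ", ns, " slices; ", n, " requested")
  areas <- apply(volume@voxels >= metalHuThreshold, 3L, sum)
  centre <- if (any(areas > 0)) which.max(areas) else floor((ns + 1) / 2)
  start <- centre - floor((n - 1) / 2)
  start <- min(max(start, 1L), ns - n + 1L)
  seq.int(start, length.out = n)
}

#' Extract circular profiles from a volume
#'
#' Samples all configured radii on the selected slices, locating the
#' sampling centre per slice with \code{\link{findInsertCenter}}.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param config a \linkS4class{RadialConfig}.
#' @param slices slice indices; default
#'   \code{selectCentralSlices(volume, config@nSlices)}.
#' @param center optional fixed \code{c(row, col)} centre overriding the
#'   per-slice search.
#' @return A \linkS4class{CircularProfileSet}.
#' @export
extractProfiles <- function(volume, config = radialConfig(), slices = NULL,
                            center = NULL) {
  if (is.null(slices))
    slices <- selectCentralSlices(volume, config@nSlices)
  vals <- array(NA_real_, c(config@nAngles, length(config@radii),
                            length(slices)))
  ctrs <- matrix(NA_real_, length(slices), 2L)
  for (si in seq_along(slices)) {
    sl <- volume@voxels[, , slices[si]]
    ctr <- if (is.null(center))
      findInsertCenter(sl, volume@pixelSpacing) else center
    ctrs[si, ] <- ctr
    for (ri in seq_along(config@radii))
      vals[, ri, si] <- sampleCircle(sl, ctr, config@radii[ri],
                                     config@nAngles, volume@pixelSpacing)
  }
  theta <- 2 * pi * (seq_len(config@nAngles) - 1L) / config@nAngles
  new("CircularProfileSet", values = vals, radii = config@radii,
      angles = theta, sliceIndices = as.integer(slices), center = ctrs)
}

#' Compute the solid-water baseline
#'
#' Per-radius circular-profile means, the global profile mean, and the
#' annular (donut-mask) mean of the solid-water control, computed
#' independently for the non-MAR and MAR arms.
#'
#' @param control the control \linkS4class{ScanPair} (solid-water insert).
#' @param config a \linkS4class{RadialConfig}.
#' @param annulus an \linkS4class{AnnulusSpec}.
#' @param annulusSlices slices entering the annular mean (default: all).
#' @return A \linkS4class{BaselineReference}.
#' @export
computeBaseline <- function(control, config = radialConfig(),
                            annulus = annulusSpec(), annulusSlices = NULL) {
  stopifnot(is(control, "ScanPair"))
  if (control@material@name != "solid_water")
    stop("baseline control must be the solid_water insert, got ",
         control@material@name)
  arms <- c("nonMAR", "MAR")
  prm <- matrix(NA_real_, length(config@radii), 2L,
                dimnames = list(NULL, arms))
  glob <- ann <- stats::setNames(numeric(2L), arms)
  for (arm in arms) {
    vol <- armVolume(control, arm)
    prof <- extractProfiles(vol, config)
    prm[, arm] <- apply(prof@values, 2L, mean)
    glob[arm] <- mean(prof@values)
    sl <- if (is.null(annulusSlices)) seq_len(nSlices(vol)) else annulusSlices
    annVals <- c()
    for (s in sl) {
      slice <- vol@voxels[, , s]
      ctr <- findInsertCenter(slice, vol@pixelSpacing)
      mask <- annularMask(dim(slice), annulus, vol@pixelSpacing, ctr)
      annVals <- c(annVals, slice[mask])
    }
    ann[arm] <- mean(annVals)
  }
  new("BaselineReference", radii = config@radii, perRadiusMean = prm,
      globalMean = glob, annulusMean = ann,
      source = paste0(control@scannerLabel, "/solid_water"),
      spacing = control@nonMAR@pixelSpacing)
}

#' Mean absolute CT-number deviation on circular profiles
#'
#' For each arm and radius: the mean over slices and angles of
#' |CTN - baseline|, where the baseline is the control's per-radius
#' profile mean of the matching arm (or the single global control mean
#' with \code{baselineMode = "global"}).
#'
#' @param pair a \linkS4class{ScanPair} from the same scan set as the
#'   baseline.
#' @param baseline a \linkS4class{BaselineReference}.
#' @param config a \linkS4class{RadialConfig}; radii must match the
#'   baseline's.
#' @param baselineMode "per-radius" (default) or "global".
#' @return data.frame with columns scanner, material, arm, radius_mm,
#'   mean_abs_dctn_hu.
#' @export
circularDeviation <- function(pair, baseline, config = radialConfig(),
                              baselineMode = c("per-radius", "global")) {
  stopifnot(is(pair, "ScanPair"), is(baseline, "BaselineReference"))
  baselineMode <- match.arg(baselineMode)
  if (!isTRUE(all.equal(pair@nonMAR@pixelSpacing, baseline@spacing)))
    stop("pixel spacing mismatch between pair (", pair@nonMAR@pixelSpacing,
         " mm) and baseline source (", baseline@spacing, " mm)")
  if (!isTRUE(all.equal(config@radii, baseline@radii)))
    stop("configured radii do not match the baseline's radii")
  rows <- list()
  for (arm in c("nonMAR", "MAR")) {
    prof <- extractProfiles(armVolume(pair, arm), config)
    for (ri in seq_along(config@radii)) {
      ref <- if (baselineMode == "per-radius")
        baseline@perRadiusMean[ri, arm] else baseline@globalMean[arm]
      rows[[length(rows) + 1L]] <- data.frame(
        scanner = pair@scannerLabel, material = pair@material@name,
        arm = arm, radius_mm = config@radii[ri],
        mean_abs_dctn_hu = mean(abs(prof@values[, ri, ] - ref)))
    }
  }
  do.call(rbind, rows)
}

#' Unwrap circular profiles into a 2-D image
#'
#' Rectangular view of a \linkS4class{CircularProfileSet} for display:
#' rows are angles; columns are radii (single slice), slices (single
#' radius), or radius-major radius/slice combinations. Values are copied,
#' never resampled.
#'
#' @param profileSet a \linkS4class{CircularProfileSet}.
#' @return numeric matrix \code{[angle, radius-or-slice]} with descriptive
#'   column names.
#' @export
unwrapProfiles <- function(profileSet) {
  v <- profileSet@values
  d <- dim(v)
  if (d[3L] == 1L) {
    out <- v[, , 1L, drop = TRUE]
    out <- matrix(out, d[1L], d[2L])
    colnames(out) <- sprintf("r%.2fmm", profileSet@radii)
  } else if (d[2L] == 1L) {
    out <- matrix(v[, 1L, ], d[1L], d[3L])
    colnames(out) <- sprintf("slice%d", profileSet@sliceIndices)
  } else {
    out <- matrix(aperm(v, c(1L, 3L, 2L)), d[1L], d[2L] * d[3L])
    colnames(out) <- as.vector(outer(profileSet@sliceIndices,
                                     profileSet@radii,
                                     function(s, r) sprintf("r%.2fmm_slice%d", r, s)))
  }
  out
}
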