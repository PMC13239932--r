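# Portable volume container (NIfTI, float64) and scan-pair assembly.

#' Save / load an ImageVolume in the portable container
#'
#' The portable container is a single-file NIfTI volume with float64 data,
#' giving a lossless round-trip of voxel values and of the mm spacing held
#' in its header (in-plane spacing and slice thickness as pixdim). The
#' array is written with NIfTI axis order (x = column, y = row, z = slice).
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param path file path, conventionally ending in \code{.nii} or
#'   \code{.nii.gz}.
#' @return \code{saveVolume}: invisibly, \code{path}. \code{loadVolume}:
#'   an \linkS4class{ImageVolume}.
#' @examples
#' vol <- imageVolume(array(stats::rnorm(4 * 64 * 64), c(64, 64, 4)),
#'                    pixelSpacing = 0.5, sliceThickness = 2)
#' p <- tempfile(fileext = ".nii")
#' saveVolume(vol, p)
#' identical(voxels(loadVolume(p)), voxels(vol))
#' @export
saveVolume <- function(volume, path) {
  stopifnot(is(volume, "ImageVolume"))
  arr <- aperm(volume@voxels, c(2L, 1L, 3L))
  attr(arr, "pixdim") <- c(volume@pixelSpacing, volume@pixelSpacing,
                           volume@sliceThickness)
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname saveVolume
#' @export
loadVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot parse volume file ", path,
                                           ": ", conditionMessage(e)))
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stop("volume file lacks valid geometry metadata (pixdim): ", path)
  if (abs(pd[1L] - pd[2L]) > 1e-6)
    stop("anisotropic in-plane spacing is not supported: ", pd[1L], " x ",
         pd[2L], " mm")
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(arr)), " dimensions")
  imageVolume(aperm(arr, c(2L, 1L, 3L)), pixelSpacing = pd[1L],
              sliceThickness = pd[3L])
}

#' Assemble a geometry-matched scan pair
#'
#' Validates that the non-MAR and MAR reconstructions share grid shape,
#' pixel spacing and slice thickness, then packages them for paired
#' comparison.
#'
#' @param nonMAR,mar \linkS4class{ImageVolume}s of the same acquisition
#'   reconstructed without and with MAR.
#' @param material \linkS4class{MaterialSpec} of the insert core.
#' @param scannerLabel free-text label.
#' @return A \linkS4class{ScanPair}.
#' @export
makeScanPair <- function(nonMAR, mar,
                         material = defaultMaterials()$solid_water,
                         scannerLabel = "unspecified") {
  stopifnot(is(nonMAR, "ImageVolume"), is(mar, "ImageVolume"))
  if (!identical(dim(nonMAR@voxels), dim(mar@voxels)))
    stop("grid shape mismatch: non-MAR ",
         paste(dim(nonMAR@voxels), collapse = "x"), " vs MAR ",
         paste(dim(mar@voxels), collapse = "x"))
  if (!isTRUE(all.equal(nonMAR@pixelSpacing, mar@pixelSpacing)))
    stop("pixelSpacing mismatch: ", nonMAR@pixelSpacing, " vs ",
         mar@pixelSpacing, " mm")
  if (!isTRUE(all.equal(nonMAR@sliceThickness, mar@sliceThickness)))
    stop("sliceThickness mismatch: ", nonMAR@sliceThickness, " vs ",
         mar@sliceThickness, " mm")
  new("ScanPair", nonMAR = nonMAR, mar = mar, scannerLabel = scannerLabel,
      material = material)
}

#' Assemble a ScanSet from pairs
#'
#' @param pairs named list of \linkS4class{ScanPair}s, one per insert
#'   material.
#' @param control name of the solid-water control entry.
#' @param seedLog optional named integer vector of simulator seeds.
#' @return A \linkS4class{ScanSet}.
#' @export
scanSet <- function(pairs, control = "solid_water",
                    seedLog = integer()) {
  new("ScanSet", pairs = pairs, control = control,
      seedLog = as.integer(seedLog))
}
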