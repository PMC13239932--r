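# Parallel-beam projection and filtered back-projection.
#
# The forward projector and backprojector are compiled (src/projection.cpp);
# the ramp filter is applied here in the Fourier domain using the discrete
# Ram-Lak convolution kernel, which avoids the DC bias of sampling |f|
# directly.

#' @useDynLib MARbench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Projection angles (radians) uniformly covering [0, pi).
.projAngles <- function(nAngles) seq(0, pi, length.out = nAngles + 1L)[-(nAngles + 1L)]

#' Parallel-beam forward projection of one slice
#'
#' Line integrals of a 2-D map over \code{nAngles} directions covering
#' 180 degrees; the detector array has one element per image column at the
#' pixel pitch, centred on the image centre. Values are integrals in units
#' of the map times mm.
#'
#' @param slice2d numeric matrix (e.g. linear attenuation, 1/mm).
#' @param nAngles number of projection angles.
#' @param spacing pixel pitch, mm.
#' @return sinogram matrix \code{[detector, angle]}.
#' @export
forwardProject <- function(slice2d, nAngles, spacing) {
  stopifnot(is.matrix(slice2d), nAngles >= 1, spacing > 0)
  cppForwardProject(slice2d, .projAngles(nAngles), spacing,
                    max(dim(slice2d)), spacing)
}

# Ramp-filter a sinogram column-wise (discrete Ram-Lak kernel, FFT
# convolution with zero padding). Returns the filtered sinogram scaled by
# the detector pitch, ready for backprojection.
.rampFilter <- function(sino, spacing) {
  nDet <- nrow(sino)
  m <- 2L^ceiling(log2(2L * nDet))
  h <- numeric(m)
  h[1L] <- 1 / (4 * spacing^2)
  lags <- seq(1L, m / 2L, by = 2L)  # odd lags carry the kernel tails
  h[1L + lags] <- -1 / (pi * lags * spacing)^2
  h[m + 1L - lags] <- -1 / (pi * lags * spacing)^2
  H <- Re(stats::fft(h))
  pad <- rbind(sino, matrix(0, m - nDet, ncol(sino)))
  filt <- Re(stats::mvfft(stats::mvfft(pad) * H, inverse = TRUE)) / m
  filt[seq_len(nDet), , drop = FALSE] * spacing
}

#' Filtered back-projection of a sinogram
#'
#' Reconstructs a square map from a parallel-beam sinogram produced by
#' \code{\link{forwardProject}} (or compatible geometry) using Ram-Lak
#' filtering and linear-interpolation backprojection.
#'
#' @param sino sinogram matrix \code{[detector, angle]}.
#' @param gridSize output image side, voxels.
#' @param spacing pixel pitch, mm.
#' @return reconstructed matrix \code{[gridSize, gridSize]} in the units of
#'   the projected map (e.g. 1/mm).
#' @export
filteredBackProject <- function(sino, gridSize, spacing) {
  stopifnot(is.matrix(sino), gridSize >= 2, spacing > 0)
  q <- .rampFilter(sino, spacing)
  cppBackProject(q, .projAngles(ncol(sino)), gridSize, gridSize, spacing)
}
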