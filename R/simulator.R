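# Synthetic phantom CT simulator: digital phantom rasterization,
# polychromatic parallel-beam acquisition with Poisson noise and photon
# starvation, and a reference sinogram-inpainting MAR.

#' Rasterize the digital phantom
#'
#' Builds the concentric-disk phantom (resin body, solid-water housing
#' channel, metal core) on the simulation grid: per-energy linear
#' attenuation maps of one axial slice (the phantom is axially uniform)
#' plus a ground-truth HU volume assigning every voxel its material's
#' nominal CT number (-1000 HU outside the body). Region membership is
#' decided at voxel centres.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param config a \linkS4class{SimConfig}; the body must fit on the grid.
#' @return A \linkS4class{DigitalPhantom}.
#' @examples
#' ph <- buildDigitalPhantom(phantomSpec(), simConfig(gridSize = 128,
#'                                                    pixelSpacing = 1))
#' range(voxels(truthVolume(ph)))
#' @export
buildDigitalPhantom <- function(spec, config) {
  g <- config@gridSize
  fov <- g * config@pixelSpacing
  if (spec@bodyDiameter > fov)
    stop("phantom body (", spec@bodyDiameter, " mm) does not fit on the ",
         fov, " mm grid")
  ctr <- c((g + 1) / 2, (g + 1) / 2)
  d2 <- .distSq(g, g, ctr, config@pixelSpacing)
  region <- matrix("air", g, g)
  region[d2 <= (spec@bodyDiameter / 2)^2] <- "body"
  region[d2 <= (spec@channelDiameter / 2)^2] <- "housing"
  region[d2 <= (spec@coreDiameter / 2)^2] <- "core"
  mats <- list(air = defaultMaterials()$air, body = spec@bodyMaterial,
               housing = spec@housingMaterial, core = spec@coreMaterial)
  pick <- function(field) {
    v <- vapply(mats, function(m) slot(m, field), numeric(1))
    matrix(v[region], g, g)
  }
  truthSlice <- pick("nominalHU")
  truth <- imageVolume(array(truthSlice, c(g, g, config@nSlices)),
                       pixelSpacing = config@pixelSpacing,
                       sliceThickness = config@sliceThickness,
                       originCenter = ctr)
  new("DigitalPhantom", muLow = pick("muLow"), muHigh = pick("muHigh"),
      truthHU = truth, spec = spec, config = config)
}

#' @rdname accessors
#' @export
setGeneric("truthVolume", function(object) standardGeneric("truthVolume"))
#' @rdname accessors
#' @export
setMethod("truthVolume", "DigitalPhantom", function(object) object@truthHU)

# Effective water attenuation (1/mm) at the configured spectrum: the
# reference coefficient of the attenuation-to-HU mapping.
.muReference <- function(config, referenceMaterial) {
  w <- config@spectrumWeights
  w[1L] * referenceMaterial@muLow + w[2L] * referenceMaterial@muHigh
}

# One noisy effective-attenuation sinogram from the two monochromatic ones.
.detectSinogram <- function(pLow, pHigh, config) {
  w <- config@spectrumWeights
  intensity <- w[1L] * exp(-pLow) + w[2L] * exp(-pHigh)
  if (is.finite(config@photonsPerRay)) {
    counts <- matrix(stats::rpois(length(intensity),
                                  config@photonsPerRay * intensity),
                     nrow(intensity), ncol(intensity))
    counts <- pmax(counts, config@photonFloor)
    -log(counts / config@photonsPerRay)
  } else {
    # noiseless: the count floor still applies (photon starvation)
    -log(pmax(intensity, config@photonFloor / 1e12))
  }
}

.reconstructHU <- function(pEff, config, muRef) {
  mu <- filteredBackProject(pEff, config@gridSize, config@pixelSpacing)
  1000 * (mu - muRef) / muRef
}

#' Simulate a CT scan of a digital phantom
#'
#' Per slice: parallel-beam line integrals of the two attenuation maps at
#' \code{nAngles} over 180 degrees; polychromatic detected intensity
#' \code{I = wLow exp(-pLow) + wHigh exp(-pHigh)}; Poisson counts with mean
#' \code{photonsPerRay * I}, clamped below at \code{photonFloor} (photon
#' starvation); log transform; Ram-Lak filtered back-projection; and
#' attenuation-to-HU mapping against the spectrum-weighted water
#' coefficient. Slices share the phantom but receive independent noise;
#' the result is deterministic given \code{noiseSeed} (per-slice seeds are
#' \code{noiseSeed + slice}).
#'
#' @param phantom a \linkS4class{DigitalPhantom}.
#' @param config a \linkS4class{SimConfig} (grid must match the phantom's).
#' @param referenceMaterial water-equivalent \linkS4class{MaterialSpec}
#'   defining 0 HU (default solid water).
#' @return An \linkS4class{ImageVolume} of reconstructed CT numbers.
#' @export
simulateScan <- function(phantom, config = phantom@config,
                         referenceMaterial = defaultMaterials()$solid_water) {
  stopifnot(is(phantom, "DigitalPhantom"))
  if (!all(dim(phantom@muLow) == config@gridSize))
    stop("phantom grid does not match config gridSize")
  if (!is.infinite(config@photonsPerRay) && config@photonsPerRay <= 0)
    stop("photonsPerRay must be positive")
  muRef <- .muReference(config, referenceMaterial)
  pLow <- forwardProject(phantom@muLow, config@nAngles, config@pixelSpacing)
  pHigh <- forwardProject(phantom@muHigh, config@nAngles, config@pixelSpacing)
  g <- config@gridSize
  vox <- array(0, c(g, g, config@nSlices))
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  for (s in seq_len(config@nSlices)) {
    set.seed(config@noiseSeed + s)
    pEff <- .detectSinogram(pLow, pHigh, config)
    vox[, , s] <- .reconstructHU(pEff, config, muRef)
  }
  imageVolume(vox, pixelSpacing = config@pixelSpacing,
              sliceThickness = config@sliceThickness,
              originCenter = c((g + 1) / 2, (g + 1) / 2))
}

# Linear interpolation across the metal-trace intervals of one projection
# column. `trace` is logical; boundary samples just outside each run anchor
# the interpolation (nearest available value at sinogram edges).
.inpaintColumn <- function(p, trace) {
  r <- rle(trace)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(p)
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    if (a == 1L && b == n) {
      p[] <- 0
    } else if (a == 1L) {
      p[a:b] <- p[b + 1L]
    } else if (b == n) {
      p[a:b] <- p[a - 1L]
    } else {
      p[a:b] <- stats::approx(c(a - 1L, b + 1L), p[c(a - 1L, b + 1L)],
                              xout = a:b)$y
    }
  }
  p
}

#' Reference sinogram-inpainting MAR
#'
#' A generic linear-interpolation MAR serving as the package's reference
#' correction: voxels at or above \code{metalHuThreshold} form the metal
#' mask; its forward projection defines the metal trace; each projection
#' column's trace interval is replaced by linear interpolation between its
#' boundary samples; the inpainted sinogram is reconstructed; and the
#' original metal voxels are re-inserted unchanged. When the volume holds
#' no metal voxels the input is returned unchanged with a warning.
#'
#' @param volume an \linkS4class{ImageVolume} on the simulation grid.
#' @param config the \linkS4class{SimConfig} (projection geometry and
#'   metal threshold).
#' @param referenceMaterial water-equivalent reference for the HU mapping.
#' @return An \linkS4class{ImageVolume}.
#' @export
applyReferenceMAR <- function(volume, config,
                              referenceMaterial = defaultMaterials()$solid_water) {
  stopifnot(is(volume, "ImageVolume"))
  vox <- volume@voxels
  metal <- vox >= config@metalHuThreshold
  if (!any(metal)) {
    warning("no metal voxels at or above ", config@metalHuThreshold,
            " HU; returning input unchanged")
    return(volume)
  }
  muRef <- .muReference(config, referenceMaterial)
  g <- dim(vox)[1L]
  out <- vox
  for (s in seq_len(dim(vox)[3L])) {
    mu <- muRef * (1 + vox[, , s] / 1000)
    mu[mu < 0] <- 0
    sino <- forwardProject(mu, config@nAngles, config@pixelSpacing)
    maskProj <- forwardProject(matrix(as.numeric(metal[, , s]), g, g),
                               config@nAngles, config@pixelSpacing)
    trace <- maskProj > 1e-9
    for (a in seq_len(ncol(sino)))
      if (any(trace[, a])) sino[, a] <- .inpaintColumn(sino[, a], trace[, a])
    hu <- 1000 * (filteredBackProject(sino, g, config@pixelSpacing) - muRef) / muRef
    hu[metal[, , s]] <- vox[, , s][metal[, , s]]
    out[, , s] <- hu
  }
  imageVolume(out, pixelSpacing = volume@pixelSpacing,
              sliceThickness = volume@sliceThickness,
              originCenter = volume@originCenter)
}

#' Simulate the full benchmark scan set
#'
#' For each requested insert material: builds the phantom, simulates the
#' non-MAR scan, applies the reference MAR, and packages the two as a
#' \linkS4class{ScanPair}. All materials share the grid and acquisition
#' settings; the per-material seed is \code{noiseSeed + 1000 * index} and
#' is recorded in the returned set's seed log. The solid-water control must
#' be among the materials (the reference MAR's no-metal warning is expected
#' and muffled for it).
#'
#' @param config a \linkS4class{SimConfig}.
#' @param materials character vector of material names from
#'   \code{\link{defaultMaterials}} (must include \code{"solid_water"}), or
#'   a named list of \linkS4class{MaterialSpec}s.
#' @param scannerLabel label stored on each pair.
#' @return A \linkS4class{ScanSet} with the solid-water pair flagged as
#'   control.
#' @examples
#' \donttest{
#' set <- makeScanSet(simConfig(gridSize = 128, pixelSpacing = 1,
#'                              nSlices = 2, nAngles = 90))
#' set
#' }
#' @export
makeScanSet <- function(config,
                        materials = c("solid_water", "aluminum", "titanium",
                                      "stainless_steel"),
                        scannerLabel = "simulator") {
  if (is.character(materials)) {
    tab <- defaultMaterials()
    unknown <- setdiff(materials, names(tab))
    if (length(unknown))
      stop("unknown materials: ", paste(unknown, collapse = ", "))
    materials <- tab[materials]
  }
  if (!"solid_water" %in% names(materials))
    stop("materials must include the solid_water control")
  pairs <- list()
  seedLog <- integer()
  for (i in seq_along(materials)) {
    mat <- materials[[i]]
    seed <- config@noiseSeed + 1000L * i
    cfg <- initialize(config, noiseSeed = seed)
    phantom <- buildDigitalPhantom(phantomSpec(coreMaterial = mat), cfg)
    nonMAR <- simulateScan(phantom, cfg)
    mar <- withCallingHandlers(
      applyReferenceMAR(nonMAR, cfg),
      warning = function(w) {
        if (grepl("no metal voxels", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    pairs[[names(materials)[i]]] <- makeScanPair(nonMAR, mar, material = mat,
                                                 scannerLabel = scannerLabel)
    seedLog[names(materials)[i]] <- seed
  }
  scanSet(pairs, control = "solid_water", seedLog = seedLog)
}
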