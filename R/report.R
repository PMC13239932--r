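# Aggregation of all metrics into report tables, images and a manifest.

.writeCsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

.divergingPalette <- function(n = 255)
  grDevices::hcl.colors(n, "Blue-Red 3")

.pngImage <- function(path, m, zlim, main) {
  grDevices::png(path, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  mClip <- pmin(pmax(m, zlim[1L]), zlim[2L])
  graphics::image(t(mClip)[, nrow(mClip):1], col = .divergingPalette(),
                  zlim = zlim, axes = FALSE, main = main, useRaster = TRUE)
}

#' Render the full benchmark report
#'
#' Computes every metric of the suite for one \linkS4class{ScanSet} and
#' writes: per-set CSV tables (circular-profile deviations; diameter
#' accuracy; bad-voxel/M-error suite; cumulative histograms), a difference
#' map and an unwrapped-profile image per insert, and a JSON manifest
#' (configuration, seeds, versions) for reproducibility. CSV output is
#' byte-identical across reruns of the same set.
#'
#' @param set a \linkS4class{ScanSet} (at least the control pair).
#' @param outputDir writable output directory (created if missing).
#' @param config a \linkS4class{RadialConfig}; default adapts nSlices to
#'   the volumes.
#' @param annulus an \linkS4class{AnnulusSpec}.
#' @param thresholdHU bad-voxel threshold (default 40).
#' @param binWidth histogram bin width, HU (default 5).
#' @param histSigned signed (TRUE, default) or absolute histogram mode.
#' @param sharedScale optional fixed \code{c(lo, hi)} HU display range
#'   applied to every difference map (the consistent cross-system colour
#'   scale); per-map percentile clipping when NULL.
#' @param clip percentiles for per-map display clipping (default 3/97).
#' @return Invisibly, a named list of written file paths.
#' @export
renderReport <- function(set, outputDir, config = NULL,
                         annulus = annulusSpec(), thresholdHU = 40,
                         binWidth = 5, histSigned = TRUE, sharedScale = NULL,
                         clip = c(3, 97)) {
  stopifnot(is(set, "ScanSet"))
  if (length(set@pairs) == 0L) stop("empty ScanSet")
  ok <- dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outputDir)) stop("cannot create output directory ", outputDir)
  if (file.access(outputDir, 2L) != 0L) stop("unwritable directory ", outputDir)
  ctl <- controlPair(set)
  if (is.null(config)) {
    ns <- min(5L, nSlices(ctl@nonMAR))
    config <- radialConfig(nSlices = ns)
  }
  baseline <- computeBaseline(ctl, config, annulus)

  files <- list()
  radial <- do.call(rbind, lapply(set@pairs, circularDeviation,
                                  baseline = baseline, config = config))
  rownames(radial) <- NULL
  files$radial <- .writeCsv(radial, outputDir, "radial_deviations.csv")

  diam <- list(); merr <- list(); hist <- list()
  for (nm in names(set@pairs)) {
    pair <- set@pairs[[nm]]
    isControl <- nm == set@control
    if (!isControl) {
      dr <- diameterReport(pair, nSlicesAnalyzed = config@nSlices)
      diam[[nm]] <- data.frame(
        material = nm, calculated_diameter_mm = dr@meanDiameter,
        diameter_error_mm = dr@diameterErrorMM,
        diameter_error_sd = dr@diameterErrorSD,
        percent_error = dr@percentError, percent_error_sd = dr@percentErrorSD)
    }
    me <- deltaMError(pair, baseline, annulus, thresholdHU)
    merr[[nm]] <- data.frame(
      material = nm, n_slices = me@nSlices,
      bad_pct_nonMAR = me@badFractionPct["nonMAR"],
      bad_sd_nonMAR = me@badFractionSD["nonMAR"],
      bad_pct_MAR = me@badFractionPct["MAR"],
      bad_sd_MAR = me@badFractionSD["MAR"],
      m_error_nonMAR = me@mError["nonMAR"], m_error_MAR = me@mError["MAR"],
      delta_m_error = me@deltaMError)
    h <- cumulativeHist(pair, baseline, annulus, binWidth, histSigned)
    for (arm in names(h))
      hist[[paste(nm, arm)]] <- data.frame(
        material = nm, arm = arm, edge_hu = h[[arm]]@binEdges,
        cumulative_fraction = h[[arm]]@cumulativeFraction)

    mid <- selectCentralSlices(armVolume(pair, "nonMAR"), 1L)
    dm <- deltaMap(pair, mid)
    dm <- withCallingHandlers(clipPercentiles(dm, clip[1L], clip[2L]),
                              warning = function(w) invokeRestart("muffleWarning"))
    zlim <- if (is.null(sharedScale)) dm@displayRange else sharedScale
    f1 <- file.path(outputDir, sprintf("diffmap_%s.png", nm))
    .pngImage(f1, dm@delta, zlim, sprintf("dCTN map: %s", nm))
    prof <- extractProfiles(armVolume(pair, "MAR"), config)
    uw <- unwrapProfiles(prof)
    f2 <- file.path(outputDir, sprintf("profiles_%s.png", nm))
    grDevices::png(f2, width = 640, height = 480)
    graphics::image(seq_len(nrow(uw)), seq_len(ncol(uw)), uw,
                    col = grDevices::hcl.colors(255, "Viridis"),
                    xlab = "angle sample", ylab = "radius x slice",
                    main = sprintf("unwrapped profiles: %s", nm))
    grDevices::dev.off()
    files[[paste0("img_", nm)]] <- c(f1, f2)
  }
  files$diameter <- .writeCsv(do.call(rbind, diam), outputDir,
                              "diameter_accuracy.csv")
  files$merror <- .writeCsv(do.call(rbind, merr), outputDir, "merror.csv")
  files$hist <- .writeCsv(do.call(rbind, hist), outputDir, "histograms.csv")

  manifest <- list(
    package = "MARbench",
    version = as.character(utils::packageVersion("MARbench")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    control = set@control,
    materials = names(set@pairs),
    seed_log = as.list(set@seedLog),
    radii_mm = config@radii,
    n_profile_angles = config@nAngles,
    n_slices_analyzed = config@nSlices,
    annulus_mm = c(annulus@innerRadius, annulus@outerRadius),
    threshold_hu = thresholdHU,
    histogram = list(bin_width_hu = binWidth, signed = histSigned),
    clip_percentiles = clip,
    shared_scale = sharedScale
  )
  files$manifest <- file.path(outputDir, "manifest.json")
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(files)
}
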