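# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Small seeded scan set exercising the full pipeline at modest cost:
# 128 mm field of view at 1 mm pixels, 3 slices, 120 views.
smallScanSet <- function() {
  if (is.null(.fixtures$set)) {
    cfg <- simConfig(gridSize = 128L, pixelSpacing = 1, nSlices = 3L,
                     nAngles = 120L, noiseSeed = 42L)
    .fixtures$cfg <- cfg
    .fixtures$set <- makeScanSet(cfg, c("solid_water", "titanium",
                                        "stainless_steel"))
  }
  .fixtures$set
}

smallConfig <- function() {
  invisible(smallScanSet())
  .fixtures$cfg
}

smallBaseline <- function() {
  if (is.null(.fixtures$baseline))
    .fixtures$baseline <- computeBaseline(controlPair(smallScanSet()),
                                          radialConfig(nSlices = 3L))
  .fixtures$baseline
}

# Constant-valued scan pair (both arms), handy for degenerate-input checks.
constantPair <- function(huNonMAR = 90, huMAR = huNonMAR, dims = c(96, 96, 3),
                         spacing = 1, thickness = 2,
                         material = defaultMaterials()$solid_water) {
  mk <- function(hu) imageVolume(array(hu, dims), spacing, thickness)
  makeScanPair(mk(huNonMAR), mk(huMAR), material = material,
               scannerLabel = "synthetic")
}

# Rasterized disk mask: voxel centres within radiusMM of the grid centre.
diskMask <- function(n, radiusMM, spacing) {
  ctr <- (n + 1) / 2
  d2 <- outer(((seq_len(n) - ctr) * spacing)^2,
              ((seq_len(n) - ctr) * spacing)^2, `+`)
  d2 <= radiusMM^2
}
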