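test_that("digital phantom rasterizes the stated geometry", {
  cfg <- simConfig(gridSize = 256L, pixelSpacing = 0.5, nSlices = 1L)
  ph <- buildDigitalPhantom(phantomSpec(coreMaterial = defaultMaterials()$titanium),
                            cfg)
  truth <- voxels(truthVolume(ph))[, , 1]

  # core mask area vs analytic pi * (12.7/2)^2 = 126.68 mm^2
  coreArea <- sum(truth == 8000) * 0.5^2
  expect_lt(abs(coreArea - pi * 6.35^2) / (pi * 6.35^2), 0.02)
  # concentric ordering: housing ring is solid water, body is resin, outside air
  expect_setequal(unique(as.vector(truth)), c(-1000, 0, 90, 8000))

  # control phantom truth holds nothing above soft-tissue range
  phc <- buildDigitalPhantom(phantomSpec(), cfg)
  expect_lt(max(voxels(truthVolume(phc))), 200)

  # all-air phantom has identically zero attenuation
  air <- defaultMaterials()$air
  pha <- buildDigitalPhantom(phantomSpec(coreMaterial = air,
                                         bodyMaterial = air,
                                         housingMaterial = air), cfg)
  expect_true(all(pha@muLow == 0) && all(pha@muHigh == 0))

  # body larger than the grid is rejected
  expect_error(buildDigitalPhantom(phantomSpec(),
                                   simConfig(gridSize = 128L,
                                             pixelSpacing = 0.5)),
               "does not fit")
})

test_that("noise-free monochromatic reconstruction matches truth within 15 HU", {
  w <- defaultMaterials()$solid_water
  wmono <- materialSpec("water_mono", 1.0, w@muHigh, w@muHigh, 0)
  # 360 views: adequate angular sampling for the 128-wide grid
  cfg <- simConfig(gridSize = 128L, pixelSpacing = 1, nSlices = 1L,
                   nAngles = 360L, spectrumWeights = c(1, 0),
                   photonsPerRay = Inf)
  ph <- buildDigitalPhantom(phantomSpec(coreMaterial = wmono,
                                        bodyMaterial = wmono,
                                        housingMaterial = wmono), cfg)
  vol <- simulateScan(ph, cfg, referenceMaterial = wmono)
  v <- voxels(vol)[, , 1]
  interior <- diskMask(128, 0.8 * 119 / 2, 1)
  expect_lt(max(abs(v[interior] - 0)), 15)
})

test_that("a uniform air scan reconstructs to -1000 HU everywhere", {
  air <- defaultMaterials()$air
  cfg <- simConfig(gridSize = 128L, pixelSpacing = 1, nSlices = 1L,
                   nAngles = 120L)
  ph <- buildDigitalPhantom(phantomSpec(coreMaterial = air, bodyMaterial = air,
                                        housingMaterial = air), cfg)
  v <- voxels(simulateScan(ph, cfg))
  expect_lt(max(abs(v + 1000)), 10)
})

test_that("simulation is deterministic given the seed", {
  cfg <- simConfig(gridSize = 96L, pixelSpacing = 1.25, nSlices = 2L,
                   nAngles = 96L, noiseSeed = 11L)
  ph <- buildDigitalPhantom(phantomSpec(), cfg)
  v1 <- simulateScan(ph, cfg)
  v2 <- simulateScan(ph, cfg)
  expect_identical(voxels(v1), voxels(v2))
  # different seed changes the noise
  cfg2 <- simConfig(gridSize = 96L, pixelSpacing = 1.25, nSlices = 2L,
                    nAngles = 96L, noiseSeed = 12L)
  expect_false(identical(voxels(v1), voxels(simulateScan(ph, cfg2))))
})

test_that("beam-hardening bias near the core grows with core attenuation", {
  cfg <- simConfig(gridSize = 128L, pixelSpacing = 1, nSlices = 1L,
                   nAngles = 180L, photonsPerRay = Inf)
  ring <- diskMask(128, 20, 1) & !diskMask(128, 12.7, 1)
  ctl <- voxels(simulateScan(buildDigitalPhantom(phantomSpec(), cfg), cfg))[, , 1]
  bias <- vapply(c("aluminum", "titanium", "stainless_steel"), function(m) {
    ph <- buildDigitalPhantom(phantomSpec(coreMaterial = defaultMaterials()[[m]]),
                              cfg)
    v <- voxels(simulateScan(ph, cfg))[, , 1]
    mean(v[ring]) - mean(ctl[ring])
  }, numeric(1))
  expect_true(all(abs(bias) > 0))
  expect_true(abs(bias[["aluminum"]]) < abs(bias[["titanium"]]))
  expect_true(abs(bias[["titanium"]]) < abs(bias[["stainless_steel"]]))
})

test_that("reference MAR is a warning no-op without metal and preserves metal voxels", {
  cfg <- smallConfig()
  ctl <- controlPair(smallScanSet())
  expect_warning(out <- applyReferenceMAR(armVolume(ctl, "nonMAR"), cfg),
                 "no metal")
  expect_identical(voxels(out), voxels(armVolume(ctl, "nonMAR")))

  steel <- scanPairs(smallScanSet())$stainless_steel
  nm <- voxels(armVolume(steel, "nonMAR"))
  mm <- voxels(armVolume(steel, "MAR"))
  metal <- nm >= cfg@metalHuThreshold
  expect_gt(sum(metal), 0)
  expect_identical(nm[metal], mm[metal])
})

test_that("reference MAR does not worsen the composite index for the densest insert", {
  set <- smallScanSet()
  bl <- smallBaseline()
  steel <- scanPairs(set)$stainless_steel
  res <- deltaMError(steel, bl)
  expect_lte(res@mError[["MAR"]], res@mError[["nonMAR"]])
})

test_that("scan sets are complete, control-flagged, and bitwise reproducible", {
  set <- smallScanSet()
  expect_s4_class(set, "ScanSet")
  expect_length(scanPairs(set), 3L)
  expect_identical(insertMaterial(controlPair(set))@name, "solid_water")
  expect_error(makeScanSet(smallConfig(), c("titanium")), "solid_water")

  set2 <- makeScanSet(smallConfig(), c("solid_water", "titanium",
                                       "stainless_steel"))
  for (nm in names(scanPairs(set)))
    for (arm in c("nonMAR", "MAR"))
      expect_identical(voxels(armVolume(scanPairs(set)[[nm]], arm)),
                       voxels(armVolume(scanPairs(set2)[[nm]], arm)))
})
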