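test_that("sampleCircle reproduces constant and linear fields exactly", {
  m <- matrix(100, 64, 64)
  expect_equal(sampleCircle(m, c(32.5, 32.5), 10, 36, 1), rep(100, 36))

  # f(row, col) = col: samples must equal c_col + r cos(theta)
  lin <- matrix(rep(seq_len(64), each = 64), 64, 64)  # value = column index
  ctr <- c(32.5, 32.5); r <- 12
  got <- sampleCircle(lin, ctr, r, 90, 1)
  theta <- 2 * pi * (0:89) / 90
  expect_equal(got, ctr[2] + r * cos(theta), tolerance = 1e-6)

  expect_error(sampleCircle(m, c(32.5, 32.5), 40, 36, 1), "bounds")
})

test_that("rotating the slice by 90 degrees permutes the profile circularly", {
  set.seed(3)
  n <- 65  # odd: exact centre voxel
  base <- matrix(stats::rnorm(n * n), n, n)
  # smooth it a little so bilinear sampling is well-behaved
  sm <- (base + base[c(1, 1:(n - 1)), ] + base[, c(1, 1:(n - 1))]) / 3
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  rot <- t(sm)[, n:1]  # 90-degree rotation about the centre
  p1 <- sampleCircle(sm, ctr, 20, 72, 1)
  p2 <- sampleCircle(rot, ctr, 20, 72, 1)
  shift <- 72 / 4  # rotated samples lag the originals by a quarter turn
  expect_lt(max(abs(p2 - p1[(seq_len(72) - 1 - shift) %% 72 + 1])), 1e-9)
  expect_lt(abs(mean(abs(p1)) - mean(abs(p2))), 1e-9)
})

test_that("central slice selection follows the metal area with stated tie-breaks", {
  vox <- array(0, c(64, 64, 10))
  vox[30:34, 30:34, 6] <- 3000          # maximal metal area at slice 6
  vox[31:33, 31:33, 3] <- 3000
  vol <- imageVolume(vox, 1, 1)
  expect_identical(selectCentralSlices(vol, 5), 4:8)
  expect_identical(selectCentralSlices(vol, 10), 1:10)
  expect_error(selectCentralSlices(vol, 11), "slices")

  # tie between slices 5 and 7: the lower index wins
  vox2 <- array(0, c(64, 64, 10))
  vox2[30:33, 30:33, 5] <- 3000
  vox2[30:33, 30:33, 7] <- 3000
  expect_identical(selectCentralSlices(imageVolume(vox2, 1, 1), 5), 3:7)

  # no metal at all: window centred on the mid-slice
  expect_identical(selectCentralSlices(imageVolume(array(0, c(64, 64, 10)), 1, 1), 5),
                   3:7)
  # window shifted, not shortened, at the boundary
  vox3 <- array(0, c(64, 64, 10))
  vox3[30:33, 30:33, 1] <- 3000
  expect_identical(selectCentralSlices(imageVolume(vox3, 1, 1), 5), 1:5)
})

test_that("baselines are per-radius, per-arm, and reproduce symmetric fields", {
  ctl <- constantPair(90, 80)
  bl <- computeBaseline(ctl, radialConfig(radii = c(10, 20), nSlices = 3L),
                        annulusSpec(10, 30))
  expect_equal(unname(bl@perRadiusMean[, "nonMAR"]), c(90, 90))
  expect_equal(unname(bl@perRadiusMean[, "MAR"]), c(80, 80))
  expect_equal(unname(bl@annulusMean), c(90, 80))

  # centre-symmetric linear gradient: circle means equal the centre value
  n <- 96
  grad <- matrix(rep(seq_len(n), each = n), n, n)  # value = column index
  pair <- makeScanPair(imageVolume(array(grad, c(n, n, 3)), 1, 1),
                       imageVolume(array(grad, c(n, n, 3)), 1, 1))
  bl2 <- computeBaseline(pair, radialConfig(radii = c(10, 20), nSlices = 3L),
                         annulusSpec(10, 30))
  expect_equal(unname(bl2@perRadiusMean[, "nonMAR"]), rep((n + 1) / 2, 2),
               tolerance = 1e-9)

  # control must be solid water
  ti <- constantPair(0, material = defaultMaterials()$titanium)
  expect_error(computeBaseline(ti, radialConfig(nSlices = 3L)), "solid_water")
})

test_that("circular deviation is zero on a constant control and obeys the triangle inequality", {
  ctl <- constantPair(90)
  rc <- radialConfig(radii = c(10, 20, 30), nSlices = 3L)
  bl <- computeBaseline(ctl, rc, annulusSpec(10, 40))
  dev <- circularDeviation(ctl, bl, rc)
  expect_equal(dev$mean_abs_dctn_hu, rep(0, 6))

  # mean |dCTN| >= |mean dCTN| on arbitrary fields
  set.seed(5)
  vox <- array(stats::rnorm(96 * 96 * 3, sd = 50), c(96, 96, 3))
  noisy <- makeScanPair(imageVolume(vox + 90, 1, 1),
                        imageVolume(vox / 2 + 90, 1, 1))
  for (r in c(10, 20, 30)) {
    prof <- extractProfiles(armVolume(noisy, "nonMAR"),
                            radialConfig(radii = r, nSlices = 3L))
    ref <- bl@perRadiusMean[match(r, c(10, 20, 30)), "nonMAR"]
    expect_gte(mean(abs(prof@values - ref)), abs(mean(prof@values - ref)))
  }

  # geometry mismatch against the baseline source is refused
  shrunk <- constantPair(90, dims = c(96, 96, 3), spacing = 0.5)
  expect_error(circularDeviation(shrunk, bl, rc), "spacing")
})

test_that("unwrapped profiles are reshaped copies of the samples", {
  set.seed(9)
  vol <- imageVolume(array(stats::rnorm(96 * 96, sd = 20) + 50, c(96, 96, 1)),
                     1, 1)
  prof <- extractProfiles(vol, radialConfig(radii = c(10, 20, 30),
                                            nAngles = 360L, nSlices = 1L))
  uw <- unwrapProfiles(prof)
  expect_identical(dim(uw), c(360L, 3L))
  expect_identical(as.numeric(uw), as.numeric(prof@values))

  # constant input stays constant, multi-slice keeps every sample
  cvol <- imageVolume(array(7, c(96, 96, 4)), 1, 1)
  cprof <- extractProfiles(cvol, radialConfig(radii = c(10, 20),
                                              nAngles = 45L, nSlices = 4L))
  cuw <- unwrapProfiles(cprof)
  expect_identical(dim(cuw), c(45L, 8L))
  expect_true(all(abs(cuw - 7) < 1e-12))
})

test_that("artifact deviations concentrate near the metal in the non-MAR arm", {
  set <- smallScanSet()
  bl <- computeBaseline(controlPair(set), radialConfig(nSlices = 3L))
  dev <- circularDeviation(scanPairs(set)$stainless_steel, bl,
                           radialConfig(nSlices = 3L))
  nm <- dev[dev$arm == "nonMAR", ]
  expect_gte(nm$mean_abs_dctn_hu[nm$radius_mm == 12.7],
             nm$mean_abs_dctn_hu[nm$radius_mm == 38.0])
})
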