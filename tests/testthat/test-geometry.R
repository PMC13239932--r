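test_that("50%-of-max segmentation recovers a two-level disk and guards against no metal", {
  n <- 96
  disk <- diskMask(n, 10, 1)
  sl <- matrix(0, n, n); sl[disk] <- 3000
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  mask <- segmentMetalMask(sl, ctr, roiRadiusMM = 14, spacing = 1)
  expect_identical(mask, disk)  # threshold 1500 selects exactly the disk

  # streak satellite outside the main component is discarded
  sl2 <- sl; sl2[5 + ctr[1], 12 + ctr[2]] <- 2800
  mask2 <- segmentMetalMask(sl2, ctr, roiRadiusMM = 14, spacing = 1)
  expect_identical(mask2, disk)

  expect_error(segmentMetalMask(matrix(90, n, n), ctr, 14, 1), "no metal")
})

test_that("segmentation boundary tracks the half-maximum of a rim ramp", {
  # radial plateau at 3000 HU to r0, linear ramp to 0 at r1: the half-max
  # crossing sits at (r0 + r1) / 2
  n <- 128; sp <- 0.25
  ctr <- (n + 1) / 2
  r <- sqrt(outer(((seq_len(n) - ctr) * sp)^2, ((seq_len(n) - ctr) * sp)^2, `+`))
  r0 <- 4; r1 <- 8
  sl <- matrix(3000 * pmin(pmax((r1 - r) / (r1 - r0), 0), 1), n, n)
  mask <- segmentMetalMask(sl, c(ctr, ctr), roiRadiusMM = 14, spacing = sp)
  dHalf <- 2 * (r0 + r1) / 2
  expect_lt(abs(estimateDiameter(mask, sp) - dHalf), 2 * sp)
})

test_that("area-equivalent diameter follows its closed form and scaling law", {
  expect_equal(estimateDiameter(matrix(TRUE, 1, 1), 0.5), 2 * sqrt(0.25 / pi))
  expect_error(estimateDiameter(matrix(FALSE, 4, 4), 0.5), "empty")

  m1 <- matrix(FALSE, 20, 20); m1[1:5, 1:5] <- TRUE          # N = 25
  m2 <- matrix(FALSE, 20, 20); m2[1:10, 1:10] <- TRUE        # 4N
  expect_equal(estimateDiameter(m2, 1) / estimateDiameter(m1, 1), 2)

  # translation and 90-degree rotation leave the estimate unchanged
  shifted <- matrix(FALSE, 20, 20); shifted[11:15, 14:18] <- TRUE
  expect_equal(estimateDiameter(shifted, 1), estimateDiameter(m1, 1))
  expect_equal(estimateDiameter(t(m1), 1), estimateDiameter(m1, 1))
})

test_that("a rasterized 12.7 mm disk is recovered within one voxel, with grid convergence", {
  sp <- 0.25
  mask <- diskMask(192, 6.35, sp)
  expect_lt(abs(estimateDiameter(mask, sp) - 12.7), sp)
  # refining the grid 2x moves the estimate by less than one coarse voxel
  fine <- diskMask(384, 6.35, sp / 2)
  expect_lt(abs(estimateDiameter(fine, sp / 2) - estimateDiameter(mask, sp)), sp)
})

test_that("diameter aggregation follows the slice-wise absolute-error convention", {
  res <- summarizeDiameters(rep(12.7, 5))
  expect_equal(res@diameterErrorMM, 0)
  expect_equal(res@diameterErrorSD, 0)
  expect_equal(res@percentError, 0)

  res2 <- summarizeDiameters(c(12.5, 12.9, 12.7))
  expect_equal(res2@meanDiameter, 12.7)
  expect_equal(res2@diameterErrorMM, mean(c(0.2, 0.2, 0)))
  # Jensen: |mean - true| <= mean |error|
  set.seed(13)
  for (i in 1:20) {
    d <- 12.7 + stats::rnorm(5, sd = 0.5)
    r <- summarizeDiameters(d)
    expect_lte(abs(r@meanDiameter - 12.7), r@diameterErrorMM + 1e-12)
  }
})

test_that("diameterReport segments per slice and flags failures", {
  n <- 128; sp <- 0.25
  disk <- diskMask(n, 6.35, sp)
  sl <- matrix(0, n, n); sl[disk] <- 3000
  vox <- array(rep(sl, 5), c(n, n, 5))
  vol <- imageVolume(vox, sp, 1)
  res <- diameterReport(vol)
  expect_lt(abs(res@meanDiameter - 12.7), sp)
  expect_length(res@failedSlices, 0)

  vox[, , 2] <- 0  # no metal on slice 2
  # make slice 3 the area maximum so the window still covers slice 2
  expect_warning(res2 <- diameterReport(imageVolume(vox, sp, 1)),
                 "segmentation failed")
  expect_length(res2@failedSlices, 1)
  expect_lt(abs(res2@meanDiameter - 12.7), sp)
})
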