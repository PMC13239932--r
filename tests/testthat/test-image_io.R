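test_that("DICOM series round-trips voxels and geometry, invariant to file names", {
  set.seed(101)
  vox <- array(sample(-1024:3000, 48 * 48 * 4, TRUE), c(48, 48, 4))
  vol <- imageVolume(vox, pixelSpacing = 0.5, sliceThickness = 2)
  d <- withr::local_tempdir()
  writeDicomSeries(vol, d)
  got <- loadDicomSeries(d)
  # slope 1 / integer storage: exact within the 0.5 HU quantization
  expect_lt(max(abs(voxels(got) - voxels(vol))), 0.5 + 1e-12)
  expect_equal(pixelSpacing(got), 0.5)
  expect_equal(sliceThickness(got), 2)

  # shuffled, uninformative file names: position-based sort restores order
  d2 <- withr::local_tempdir()
  fs <- list.files(d, full.names = TRUE)
  perm <- rev(seq_along(fs))
  file.copy(fs, file.path(d2, sprintf("scan_%s.dcm", letters[perm])))
  expect_identical(voxels(loadDicomSeries(d2)), voxels(got))
})

test_that("DICOM ingest rejects mixed series and truncated files", {
  vol <- imageVolume(array(0, c(32, 32, 2)), 1, 1)
  d <- withr::local_tempdir()
  writeDicomSeries(vol, d, seriesUID = "1.2.3.1")
  writeDicomSeries(imageVolume(array(0, c(32, 32, 1)), 1, 1),
                   d, seriesUID = "1.2.3.2")
  expect_error(loadDicomSeries(d), "mixed series")

  d3 <- withr::local_tempdir()
  writeDicomSeries(vol, d3)
  f <- list.files(d3, full.names = TRUE)[1]
  writeBin(readBin(f, "raw", 400), f)       # chop the pixel data
  file.remove(list.files(d3, full.names = TRUE)[-1])
  expect_error(loadDicomSeries(d3), "truncated|lacks image pixel")
})

test_that("HU values below -1024 are clamped on ingest", {
  vol <- imageVolume(array(c(-5000, 0, 100), c(1, 3, 1)), 1, 1)
  expect_equal(min(voxels(vol)), -1024)
  expect_equal(voxels(vol)[1, 2:3, 1], c(0, 100))
})

test_that("portable volume container round-trips losslessly", {
  set.seed(7)
  vol <- imageVolume(array(stats::rnorm(4 * 40 * 40), c(40, 40, 4)),
                     pixelSpacing = 0.5, sliceThickness = 2.5)
  p <- withr::local_tempfile(fileext = ".nii")
  saveVolume(vol, p)
  got <- loadVolume(p)
  expect_identical(as.numeric(voxels(got)), as.numeric(voxels(vol)))
  expect_equal(pixelSpacing(got), 0.5)
  expect_equal(sliceThickness(got), 2.5)

  bad <- withr::local_tempfile(fileext = ".nii")
  writeBin(as.raw(seq_len(64)), bad)
  expect_error(suppressWarnings(loadVolume(bad)), "parse|geometry")
})

test_that("makeScanPair validates geometry and names the offending field", {
  a <- imageVolume(array(0, c(32, 32, 2)), 1, 2)
  b <- imageVolume(array(1, c(32, 32, 2)), 1, 3)
  expect_error(makeScanPair(a, b), "sliceThickness")
  c1 <- imageVolume(array(0, c(32, 32, 3)), 1, 2)
  expect_error(makeScanPair(a, c1), "shape")
  d1 <- imageVolume(array(0, c(32, 32, 2)), 0.5, 2)
  expect_error(makeScanPair(a, d1), "pixelSpacing")

  # identity pair is valid and its difference map is identically zero
  p <- makeScanPair(a, a)
  expect_true(all(deltaValues(deltaMap(p, 1)) == 0))
})
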