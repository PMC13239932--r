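test_that("the donut mask matches its analytic area with closed boundaries", {
  spec <- annulusSpec()  # 15 / 45 mm
  n <- 200; sp <- 0.5
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  mask <- annularMask(c(n, n), spec, sp, ctr)
  area <- sum(mask) * sp^2
  expect_lt(abs(area - pi * (45^2 - 15^2)) / (pi * (45^2 - 15^2)), 0.01)

  # a voxel centre exactly at the inner radius is included
  m1 <- annularMask(c(101, 101), annulusSpec(15, 45), 1, c(51, 51))
  expect_true(m1[51, 51 + 15])
  expect_true(m1[51, 51 + 45])   # and at the outer radius
  expect_false(m1[51, 51 + 14])

  expect_error(annulusSpec(45, 15), "inner")
  expect_error(annularMask(c(64, 64), spec, 1, c(32, 32)), "extent")
})

test_that("bad-voxel statistics match hand enumeration with a strict 40 HU boundary", {
  toy <- c(0, 10, 39, 40, -40, 41, -41, 100, -100)
  s <- badVoxelSummary(list(toy), thresholdHU = 40)
  expect_equal(s$badFractionPct, 100 * 4 / 9)
  expect_equal(s$meanAbsDctnBad, mean(c(41, 41, 100, 100)))  # 70.5
  expect_equal(s$nBad, 4)

  # raising the threshold can only shrink the bad set
  s80 <- badVoxelSummary(list(toy), thresholdHU = 80)
  expect_equal(s80$badFractionPct, 100 * 2 / 9)
  set.seed(21)
  d <- stats::rnorm(500, sd = 50)
  fr <- vapply(seq(0, 120, by = 10), function(th)
    badVoxelSummary(list(d), th)$badFractionPct, numeric(1))
  expect_true(all(diff(fr) <= 0))

  # all-baseline annulus: every statistic is zero
  z <- badVoxelSummary(list(rep(0, 50), rep(0, 50)))
  expect_equal(c(z$badFractionPct, z$badFractionSD, z$meanAbsDctnBad),
               c(0, 0, 0))
})

test_that("the M-error index is the exact product identity", {
  expect_equal(mErrorIndex(2.0, 50), 1.0)
  expect_equal(mErrorIndex(0, 0), 0)
  toy <- badVoxelSummary(list(c(0, 10, 39, 40, -40, 41, -41, 100, -100)))
  expect_equal(mErrorIndex(toy), 4 / 9 * 70.5)

  set.seed(31)
  for (i in 1:25) {
    st <- list(badFractionPct = stats::runif(1, 0, 100),
               meanAbsDctnBad = stats::runif(1, 40, 400))
    expect_equal(mErrorIndex(st),
                 st$badFractionPct / 100 * st$meanAbsDctnBad,
                 tolerance = 1e-12)
  }
})

test_that("volume-level bad-voxel stats agree exactly with a brute-force loop", {
  set.seed(17)
  n <- 32L
  spec <- annulusSpec(3, 10)
  vox <- array(stats::rnorm(n * n * 3, mean = 0, sd = 35), c(n, n, 3))
  # salt in exact-boundary deviations: 40 must not be bad, 40 + eps must be
  vox[5, 5, 1] <- 40; vox[6, 6, 1] <- -40
  vox[7, 7, 1] <- 40.0001; vox[8, 8, 1] <- -40.0001
  vol <- imageVolume(vox, 1, 1)
  got <- badVoxelStats(vol, baseline = 0, annulus = spec)

  # independent voxel-by-voxel loop
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  nBad <- 0L; nTot <- 0L; absSum <- 0; perSlice <- numeric(3)
  for (s in 1:3) {
    badS <- 0L; totS <- 0L
    for (i in 1:n) for (j in 1:n) {
      d <- sqrt(((i - ctr[1]))^2 + ((j - ctr[2]))^2)
      if (d >= 3 && d <= 10) {
        totS <- totS + 1L
        dev <- vox[i, j, s] - 0
        if (abs(dev) > 40) {
          badS <- badS + 1L
          absSum <- absSum + abs(dev)
        }
      }
    }
    nBad <- nBad + badS; nTot <- nTot + totS
    perSlice[s] <- 100 * badS / totS
  }
  expect_identical(got$nVoxels, nTot)
  expect_identical(got$nBad, nBad)
  expect_equal(got$badFractionPct, 100 * nBad / nTot, tolerance = 1e-15)
  expect_equal(got$meanAbsDctnBad, absSum / nBad, tolerance = 1e-15)
  expect_equal(got$badFractionSD, stats::sd(perSlice), tolerance = 1e-12)
})

test_that("delta-M-error is zero for an identity MAR and positive when MAR cleans up", {
  set.seed(23)
  n <- 64
  vox <- array(stats::rnorm(n * n * 2, sd = 60), c(n, n, 2))
  vol <- imageVolume(vox, 1, 1)
  idPair <- makeScanPair(vol, vol)
  res <- deltaMError(idPair, baseline = 0, annulus = annulusSpec(5, 20))
  expect_identical(res@deltaMError, 0)
  expect_gt(res@mError[["nonMAR"]], 0)

  clean <- imageVolume(vox / 10, 1, 1)
  res2 <- deltaMError(makeScanPair(vol, clean), baseline = 0,
                      annulus = annulusSpec(5, 20))
  expect_gt(res2@deltaMError, 0)
})

test_that("cumulative histograms count hand-enumerable inputs and normalize to 1", {
  n <- 11
  vals <- c(-10, -5, 0, 5, 10)
  ctr <- 6
  spec <- annulusSpec(3, 3.5)
  ring <- which(annularMask(c(n, n), spec, 1, c(ctr, ctr)), arr.ind = TRUE)
  expect_gte(nrow(ring), 5)
  sl <- matrix(0, n, n)
  assigned <- vals[(seq_len(nrow(ring)) - 1) %% 5 + 1]
  for (k in seq_len(nrow(ring))) sl[ring[k, 1], ring[k, 2]] <- assigned[k]
  h <- cumulativeHist(imageVolume(array(sl, c(n, n, 1)), 1, 1),
                      baseline = 0, annulus = spec)
  # hand count of the assigned multiset at the 0 HU edge
  expect_equal(h@cumulativeFraction[h@binEdges == 0], mean(assigned <= 0))
  expect_equal(h@cumulativeFraction[h@binEdges == -5], mean(assigned <= -5))
  expect_equal(h@cumulativeFraction[length(h@cumulativeFraction)], 1.0)
  expect_true(all(diff(h@cumulativeFraction) >= 0))
})

test_that("cumulative histograms step once for constant input and respect modes", {
  n <- 64
  vol <- imageVolume(array(90, c(n, n, 1)), 1, 1)
  h <- cumulativeHist(vol, baseline = 87, annulus = annulusSpec(5, 20))
  expect_equal(h@cumulativeFraction[length(h@cumulativeFraction)], 1)
  expect_true(all(h@cumulativeFraction %in% c(0, 1)))  # a single step
  expect_true(all(h@binEdges %% 5 == 0))               # aligned edges

  set.seed(41)
  vox <- array(stats::rnorm(n * n, sd = 30), c(n, n, 1))
  volr <- imageVolume(vox, 1, 1)
  hs <- cumulativeHist(volr, 0, annulusSpec(5, 20), signed = TRUE)
  ha <- cumulativeHist(volr, 0, annulusSpec(5, 20), signed = FALSE)
  expect_gte(min(ha@binEdges), 0)
  expect_lt(min(hs@binEdges), 0)

  # empirical median consistent with the direct median within one bin
  d <- vox[annularMask(c(n, n), annulusSpec(5, 20), 1, c(32.5, 32.5))]
  medEdge <- hs@binEdges[which(hs@cumulativeFraction >= 0.5)[1]]
  expect_lte(abs(medEdge - stats::median(d)), 5)

  expect_error(cumulativeHist(volr, 0, annulusSpec(5, 20), binWidth = 0),
               "positive")
})
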