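# Phantom generation and forward/raw-scan simulation.

test_that("phantom generator is deterministic and follows the Poisson density law", {
  spec0 <- PhantomSpec("beads", dims = c(24, 24, 5), voxel = c(0.5, 0.5, 0.5),
                       beadDensity = 0, seed = 1L)
  expect_true(all(generatePhantom(spec0)@data == 0))
  # expected count 100 in the volume: density = 100 / (24*24*5*0.125)
  vUm3 <- 24 * 24 * 5 * 0.125
  spec <- PhantomSpec("beads", dims = c(24, 24, 5), voxel = c(0.5, 0.5, 0.5),
                      beadRadius = 0.6, beadDensity = 100 / vUm3, seed = 7L)
  v1 <- generatePhantom(spec)
  expect_lt(abs(attr(v1@data, "nBeads") - 100), 3 * sqrt(100))
  v2 <- generatePhantom(spec)
  expect_identical(v1@data, v2@data)
  expect_warning(generatePhantom(
    PhantomSpec("beads", dims = c(8, 8, 3), beadRadius = 0.1,
                voxel = c(0.5, 0.5, 0.5), beadDensity = 1e-3)), "single voxel")
})

test_that("composite phantom stacks beads, slab background and neurites", {
  spec <- PhantomSpec("composite", dims = c(20, 20, 5), voxel = c(0.5, 0.5, 0.5),
                      beadRadius = 0.6, beadDensity = 2e-3, slabThickness = 2,
                      slabDensity = 5e-3, nNeurites = 2L, offset = 1.5, seed = 2L)
  v <- generatePhantom(spec)
  expect_true(all(v@data >= 1.5))
  expect_gt(sum(v@data > 1.5), 0)
})

test_that("forward projection is the PSF for a delta and is linear", {
  psf <- testPsf()
  f0 <- which(abs(psf@fineCoords) < 1e-9)
  vg <- pointVolume(psf, f0, f0, which(testZ == 0))
  mv <- forwardViews(vg, psf)
  expect_lt(max(abs(mv@views - aperm(psf@hp[, , , , which(testZ == 0)],
                                     c(1, 2, 3, 4)))), 1e-6)
  vgA <- pointVolume(psf, 6, 9, 1, value = 2)
  vgB <- pointVolume(psf, 11, 4, 3, value = 0.7)
  both <- vgA; both@data <- vgA@data + vgB@data
  mvSum <- forwardViews(vgA, psf)@views + forwardViews(vgB, psf)@views
  expect_lt(max(abs(forwardViews(both, psf)@views - mvSum)), 1e-6)
  # dense (FFT) and sparse paths agree
  expect_lt(max(abs(forwardViews(both, psf, sparseLimit = 0L)@views -
                    forwardViews(both, psf)@views)), 1e-9)
})

test_that("confocal views collect fewer slab photons, progressively with thickness", {
  psf <- slabPsf()
  au <- airyUnit(psf@config, "full")
  mod <- applyConfocal(psf, ConfocalConfig(slitWidth = 4 * au))
  ratio <- vapply(c(20, 40, 80), function(thk) {
    vg <- slabVolume(psf, thk)
    sum(forwardViews(vg, mod)@views) / sum(forwardViews(vg, psf)@views)
  }, numeric(1))
  expect_true(all(ratio < 1))
  expect_true(all(diff(ratio) < 0))
})

test_that("sLFM raw scan realigns back to the forward views exactly", {
  psf <- testPsf()
  vg <- pointVolume(psf, 8, 8, which(testZ == 0))
  seq <- simulateRawScan(vg, psf, mode = "sLFM")
  expect_equal(dim(seq@frames)[3], psf@config@scanSteps^2)
  rv <- pixelRealign(seq, psf@config)
  mv <- forwardViews(vg, psf)
  expect_lt(max(abs(rv@views - mv@views)), 1e-12)
})

test_that("rolling-shutter sweep reproduces the triangle-modulated PSF model", {
  # the derivation chain sweep -> sensor modulation -> realigned triangle
  # weight, executed as an internal oracle (exact-offset modulation)
  psf <- testPsf()
  vg <- pointVolume(psf, 8, 8, which(testZ == 0))
  conf <- ConfocalConfig(slitWidth = 40)
  seq <- simulateRawScan(vg, psf, conf, mode = "csLFM", sweepSteps = 64L)
  rv <- pixelRealign(seq, psf@config)
  pred <- forwardViews(vg, applyConfocal(psf, conf, exactOffset = TRUE))
  mask <- viewMask(psf@config)
  for (vi in 1:5) for (ui in 1:5) {
    if (!mask[vi, ui]) next
    a <- sum(rv@views[, , vi, ui]); b <- sum(pred@views[, , vi, ui])
    expect_lt(abs(a - b) / b, 0.02)
  }
})

test_that("a deeply defocused point is strongly rejected by a tight slit", {
  psf <- slabPsf()
  au <- airyUnit(psf@config, "full")
  mod <- applyConfocal(psf, ConfocalConfig(slitWidth = 2 * au))
  vg <- pointVolume(psf, 20, 20, which(slabZ == 32))
  frac <- sum(forwardViews(vg, mod)@views) / sum(forwardViews(vg, psf)@views)
  expect_lt(frac, 0.20)
  expect_equal(frac, 0.145, tolerance = 0.15)  # regression anchor
})

test_that("undersampled sweeps are flagged", {
  psf <- testPsf()
  vg <- pointVolume(psf, 8, 8, which(testZ == 0))
  expect_warning(simulateRawScan(vg, psf, ConfocalConfig(slitWidth = 8),
                                 mode = "csLFM", sweepSteps = 4L),
                 "undersampled")
})

test_that("noise model: seeded, unbiased, vanishing at high photon counts", {
  img <- matrix(50, 8, 8)
  n1 <- addNoise(img, photonScale = 1, seed = 11L)
  expect_identical(n1, addNoise(img, photonScale = 1, seed = 11L))
  expect_error(addNoise(matrix(-1, 2, 2)), "negative")
  # law of large numbers: at 1e6 photons relative deviation < 1%
  big <- addNoise(matrix(1e6, 4, 4), photonScale = 1, readNoiseE = 1.6, seed = 3L)
  expect_lt(max(abs(big - 1e6)) / 1e6, 0.01)
  # Monte-Carlo mean of 1000 realizations close to the clean image
  acc <- 0
  for (k in seq_len(1000)) acc <- acc + addNoise(img, seed = k)
  m <- acc / 1000
  se <- sqrt((50 + 1.6^2) / 1000)
  expect_lt(max(abs(m - 50)), 3 * se * 4)  # 64 cells; allow the family max
})

test_that("cLFM frame extraction partitions the sequence", {
  psf <- testPsf()
  vg <- pointVolume(psf, 8, 8, which(testZ == 0))
  seq <- simulateRawScan(vg, psf, mode = "sLFM")
  total <- 0
  for (k in seq_len(dim(seq@frames)[3])) {
    fr <- extractClfmFrame(seq, k)
    expect_equal(fr@s, 1L)
    expect_identical(fr@frames[, , 1], seq@frames[, , k])
    total <- total + sum(fr@frames)
  }
  expect_equal(total, sum(seq@frames))
  expect_error(extractClfmFrame(seq, 99L), "out of range")
  # unscanned realignment is s-fold coarser
  rv1 <- pixelRealign(extractClfmFrame(seq, 1L))
  rvS <- pixelRealign(seq)
  expect_equal(dim(rvS@views)[1], psf@config@scanSteps * dim(rv1@views)[1])
})
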