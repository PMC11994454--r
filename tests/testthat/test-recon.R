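# Pixel realignment of measurements, cLFM upsampling, iterative tomography
# and digital adaptive optics.

test_that("measurement realignment conserves energy and matches a naive oracle", {
  psf <- testPsf()
  cfg <- psf@config
  set.seed(5)
  vg <- pointVolume(psf, 7, 9, which(testZ == 0))
  seq <- simulateRawScan(vg, psf, mode = "sLFM")
  rv <- pixelRealign(seq, cfg)
  expect_lt(abs(sum(rv@views) - sum(seq@frames)) / sum(seq@frames), 1e-6)
  s <- cfg@scanSteps; nV <- cfg@nViews
  nLens <- dim(seq@frames)[1] %/% nV
  lc <- (nLens + 1L) %/% 2L
  mMin <- s * (1L - lc) - (s - 1L)
  naive <- array(0, dim(rv@views))
  for (l in seq_len(nLens)) for (k in 0:(s - 1L))
    for (l2 in seq_len(nLens)) for (k2 in 0:(s - 1L)) {
      fy <- s * (l - lc) - k - mMin + 1L
      fx <- s * (l2 - lc) - k2 - mMin + 1L
      for (vi in seq_len(nV)) for (ui in seq_len(nV))
        naive[fy, fx, vi, ui] <-
          seq@frames[(l - 1L) * nV + vi, (l2 - 1L) * nV + ui, k * s + k2 + 1L]
    }
  expect_identical(rv@views, naive)
  expect_equal(dim(rv@views)[1], s * nLens)
  expect_error(pixelRealign(new("RawScanSequence",
                                frames = seq@frames[, , 1:3], s = 3L,
                                mode = "sLFM", config = cfg, confocal = NULL,
                                sweepSteps = 1L)))
})

test_that("cLFM cubic upsampling reproduces constants and the Lagrange oracle", {
  psf <- testPsf()
  cfg1 <- psf@config; cfg1@scanSteps <- 1L
  nLens <- 9L
  const <- new("MultiViewStack",
               views = array(2.5, c(nLens, nLens, 5, 5)),
               fineCoords = (seq_len(nLens) - (nLens + 1) / 2) * cfg1@mlaPitch,
               config = cfg1, mode = "sLFM", provenance = list())
  up <- clfmUpsample(const, 3L)
  expect_lt(max(abs(up@views - 2.5)), 1e-9)
  # grid matches the s = 3 scanned stack exactly
  ri <- cslfm:::realignIndex(nLens, 3L)
  expect_equal(up@fineCoords, ri$m * cfg1@mlaPitch / 3)
  # interior samples match an independent polynomial-fit cubic
  set.seed(8)
  rnd <- const
  rnd@views <- array(runif(nLens^2 * 25), c(nLens, nLens, 5, 5))
  upr <- clfmUpsample(rnd, 3L)
  coarse <- rnd@fineCoords
  for (probe in list(c(14, 16, 2, 3), c(10, 20, 4, 4))) {
    xf <- upr@fineCoords[probe[1]]; yf <- upr@fineCoords[probe[2]]
    i1 <- max(which(coarse <= xf)); j1 <- max(which(coarse <= yf))
    ii <- (i1 - 1):(i1 + 2); jj <- (j1 - 1):(j1 + 2)
    patch <- rnd@views[ii, jj, probe[3], probe[4]]
    lag <- function(x, xs, ys) sum(vapply(seq_len(4), function(a)
      ys[a] * prod((x - xs[-a]) / (xs[a] - xs[-a])), numeric(1)))
    colv <- vapply(seq_len(4), function(j) lag(xf, coarse[ii], patch[, j]), numeric(1))
    oracle <- lag(yf, coarse[jj], colv)
    expect_equal(upr@views[probe[1], probe[2], probe[3], probe[4]], oracle,
                 tolerance = 1e-6)
  }
  expect_error(clfmUpsample(const, 0L), ">= 1")
})

test_that("RL with a single delta view converges to the measurement", {
  cfg <- OpticalConfig(na = 0.5, magObjective = 20, refrIndex = 1.33,
                       mlaPitch = 20, mlaFocal = 400, pixelSize = 20,
                       nViews = 1L, scanSteps = 1L)
  nF <- 9L
  hp <- array(0, c(nF, nF, 1, 1, 1)); hp[5, 5, 1, 1, 1] <- 1
  psf <- new("SpatialAngularPSF", hp = hp,
             fineCoords = (seq_len(nF) - 5) * 20, depths = 0,
             config = cfg, modulated = FALSE, slitWidth = NA_real_)
  set.seed(9)
  meas <- matrix(runif(nF^2, 0.5, 2), nF, nF)
  views <- new("MultiViewStack", views = array(meas, c(nF, nF, 1, 1)),
               fineCoords = psf@fineCoords, config = cfg, mode = "sLFM",
               provenance = list())
  rec <- iterativeTomography(views, psf, nIter = 10L, depths = 0)
  expect_lt(max(abs(rec@volume@data[, , 1] - meas)) / max(meas), 1e-3)
})

test_that("bead round trip localizes within one voxel under both modes", {
  psf <- testPsf()
  vg <- pointVolume(psf, 9, 7, which(testZ == 0))
  recS <- reconstructPipeline(forwardViews(vg, psf), psf, nIter = 15L)
  amS <- which(recS@volume@data == max(recS@volume@data), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(amS - c(9, 7, which(testZ == 0)))), 1)
  mod <- applyConfocal(psf, ConfocalConfig(slitWidth = 40))
  recC <- reconstructPipeline(forwardViews(vg, mod), mod, nIter = 15L)
  amC <- which(recC@volume@data == max(recC@volume@data), arr.ind = TRUE)[1, ]
  expect_equal(amS, amC)
  expect_true(all(recS@volume@data >= 0))
  # fidelity is non-increasing within numerical jitter
  expect_true(all(diff(recS@fidelity) <= 1e-3 * abs(recS@fidelity[1])))
})

test_that("modelling the confocal PSF removes out-of-focus reconstruction energy", {
  # a defocused bead acquired through the slit: ignoring the modulation in
  # the reconstruction model misassigns most of its energy to other planes
  psf <- testPsf()
  mod <- applyConfocal(psf, ConfocalConfig(slitWidth = 25))
  izB <- which(testZ == 0.5)
  vg <- pointVolume(psf, 8, 8, izB)
  views <- forwardViews(vg, mod)   # csLFM acquisition
  recM <- iterativeTomography(views, mod, nIter = 15L)
  expect_warning(recU <- iterativeTomography(views, psf, nIter = 15L),
                 "unmodulated")
  offFrac <- function(rec) {
    e <- apply(rec@volume@data, 3, sum)
    1 - e[izB] / sum(e)
  }
  expect_lt(offFrac(recM), offFrac(recU))
  expect_lt(offFrac(recM), 0.1)
})

test_that("zero iterations return the initialization and parameters are logged", {
  psf <- testPsf()
  vg <- pointVolume(psf, 8, 8, which(testZ == 0))
  views <- forwardViews(vg, psf)
  rec0 <- iterativeTomography(views, psf, nIter = 0L)
  expect_equal(length(unique(as.vector(rec0@volume@data))), 1L)  # uniform init
  recB <- iterativeTomography(views, psf, nIter = 0L, init = "backprojection")
  expect_gt(var(as.vector(recB@volume@data)), 0)
  res <- reconstructPipeline(views, psf, nIter = 1L)
  expect_match(res@psfInfo$provenance, "ws_um")
})

test_that("DAO: null case, imposed tilt recovery, and shift equivariance", {
  psf <- testPsf9()
  cfg <- psf@config
  st <- fineStep(cfg)
  nF <- length(psf@fineCoords)
  set.seed(3)
  vol <- array(0, c(nF, nF, 3))
  for (i in 1:10) vol[sample(8:20, 1), sample(8:20, 1), sample(1:3, 1)] <-
    runif(1, 0.5, 1)
  vg <- VolumeGrid(vol, c(st, st, 0.5), zCoords = testZ)
  mv <- forwardViews(vg, psf)
  # null case: a single estimation pass isolates the estimator itself
  sm0 <- daoEstimate(mv, psf, nOuter = 1L)
  expect_lt(max(abs(c(sm0@dy, sm0@dx))) / st, 0.1)
  expect_equal(sm0@dy[3, 3], 0)
  # pupil-tilt ramp recovery at package defaults
  fs2 <- cslfm:::fourierShift2
  alpha <- 0.7; c0 <- 3L
  sh <- mv
  for (vi in 1:5) for (ui in 1:5)
    sh@views[, , vi, ui] <- pmax(fs2(mv@views[, , vi, ui], alpha * (vi - c0), 0), 0)
  sm <- daoEstimate(sh, psf)
  imp <- alpha * ((1:5) - c0) * st
  off <- c(1, 2, 4, 5)
  expect_lt(max(abs(sm@dy[off, 3] - imp[off]) / abs(imp[off])), 0.10)
  # equivariance: a common shift of all views leaves the relative map intact
  sh2 <- sh
  for (vi in 1:5) for (ui in 1:5)
    sh2@views[, , vi, ui] <- pmax(fs2(sh@views[, , vi, ui], 0.8, 0.5), 0)
  sm2 <- daoEstimate(sh2, psf)
  expect_lt(max(abs(sm2@dy - sm@dy), abs(sm2@dx - sm@dx)) / st, 0.15)
  # featureless views produce zero shifts with a warning
  flat <- mv; flat@views[] <- 1
  expect_warning(smF <- daoEstimate(flat, psf), "featureless")
  expect_true(all(smF@dy == 0))
})

test_that("DAO-corrected reconstruction outperforms the uncorrected one", {
  psf <- testPsf9()
  st <- fineStep(psf@config)
  nF <- length(psf@fineCoords)
  set.seed(4)
  vol <- array(0, c(nF, nF, 3))
  for (i in 1:8) vol[sample(9:19, 1), sample(9:19, 1), 2] <- runif(1, 0.5, 1)
  vg <- VolumeGrid(vol, c(st, st, 0.5), zCoords = testZ)
  mv <- forwardViews(vg, psf)
  fs2 <- cslfm:::fourierShift2
  ab <- mv
  for (vi in 1:5) for (ui in 1:5)
    ab@views[, , vi, ui] <- pmax(fs2(mv@views[, , vi, ui],
                                     0.6 * (vi - 3), 0.4 * (ui - 3)), 0)
  plainR <- reconstructPipeline(ab, psf, nIter = 15L)
  daoR <- reconstructPipeline(ab, psf, dao = TRUE, nIter = 15L)
  ref <- vg@data / max(vg@data)
  score <- function(r) snr(ref, r@volume@data / max(r@volume@data))
  expect_gt(score(daoR), score(plainR))
  expect_true(daoR@psfInfo$dao)
})
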