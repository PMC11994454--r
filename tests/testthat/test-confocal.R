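# Confocal modulation model and slit-design calculators.

test_that("triangle weight follows the printed definition", {
  expect_equal(triWeight(0, 5), 1)
  expect_equal(triWeight(5, 5), 0)
  expect_equal(triWeight(2.5, 5), 0.5)
  expect_equal(triWeight(-2.5, 5), 0.5)
  expect_error(triWeight(1, 0), "positive")
})

test_that("general slit/shutter weight matches brute-force sweep integration", {
  # oracle: rectangle-rule integration of the sweep integral at step ws/2000
  sweepOracle <- function(ybar, ws, hr) {
    step <- ws / 2000
    c <- seq(-(ws + hr), ws + hr, by = step)
    val <- vapply(ybar, function(y)
      sum((abs(c) <= ws / 2) * (abs(y - c) <= hr / 2)) * step, numeric(1))
    val / min(ws, hr)
  }
  ws <- 7; y <- seq(-1.2 * ws, 1.2 * ws, length.out = 200)
  expect_lt(max(abs(confocalWeight(y, ws, ws) - triWeight(y, ws))), 1e-12)
  expect_lt(max(abs(confocalWeight(y, ws, ws) - sweepOracle(y, ws, ws))), 2e-3)
  # unequal windows: trapezoid with plateau; inside-plateau point is 1
  expect_equal(confocalWeight(7 / 4, 2 * 7, 7), 1)
  expect_lt(max(abs(confocalWeight(y, 2 * ws, ws) - sweepOracle(y, 2 * ws, ws))), 2e-3)
  expect_equal(confocalWeight(0, 3, 9, M = 63), 1)
})

test_that("confocal modulation: identity limit, double-modulation guard, view ordering", {
  psf <- testPsf()
  wide <- applyConfocal(psf, ConfocalConfig(slitWidth = Inf))
  expect_identical(wide@hp, psf@hp)     # tri -> 1 exactly over any support
  expect_true(wide@modulated)
  expect_error(applyConfocal(wide, ConfocalConfig(slitWidth = 10)), "double")
  big <- applyConfocal(psf, ConfocalConfig(slitWidth = 1e6))
  expect_lt(max(abs(big@hp - psf@hp)) / max(psf@hp), 1e-3)
  # modulation never increases energy
  mod <- applyConfocal(psf, ConfocalConfig(slitWidth = 20))
  expect_true(all(mod@hp <= psf@hp + 1e-15))
})

test_that("oblique views lose more energy than paraxial views under modulation", {
  psf <- bgPsf()
  cfg <- psf@config
  au <- airyUnit(cfg, "full")
  mod <- applyConfocal(psf, ConfocalConfig(slitWidth = 11 * au))
  c0 <- centralViewIndex(cfg)
  izf <- which(bgZ == 0); izd <- which(bgZ == 45)
  retained <- function(p, vi, iz) sum(p@hp[, , vi, c0, iz])
  # in-focus central view keeps nearly all photons at 11 AU
  expect_gte(retained(mod, c0, izf) / retained(psf, c0, izf), 0.9)
  # at depth, the most oblique view is attenuated more than the central one
  rOb <- retained(mod, cfg@nViews, izd) / retained(psf, cfg@nViews, izd)
  rCe <- retained(mod, c0, izd) / retained(psf, c0, izd)
  expect_lt(rOb, rCe)
})

test_that("Airy units reproduce both instruments' slit sizings", {
  inv <- invertedOptics(); up <- uprightOptics()
  expect_equal(airyUnit(inv, "full"), 28.8, tolerance = 0.002)
  expect_equal(round(325 / airyUnit(inv, "full")), 11)
  expect_equal(airyUnit(up, "full"), 25.0, tolerance = 0.002)
  expect_equal(round(650 / airyUnit(up, "full")), 26)
  # linear in wavelength
  inv2 <- inv; inv2@wavelength <- 2 * inv@wavelength
  expect_equal(airyUnit(inv2, "full"), 2 * airyUnit(inv, "full"))
  # sub-aperture AU scales with the view count under pupil segmentation
  expect_equal(airyUnit(inv, "sub"), airyUnit(inv, "full") * inv@nViews)
})

test_that("normalized energy map: unit limit, monotone decay, slit-axis anisotropy", {
  psf <- bgPsf()
  cfg <- psf@config
  c0 <- centralViewIndex(cfg)
  em0 <- normalizedEnergyMap(psf, ConfocalConfig(slitWidth = Inf))
  expect_equal(em0@ebar[which(bgZ == 0), c0, c0], 1, tolerance = 1e-6)
  au <- airyUnit(cfg, "full")
  em <- normalizedEnergyMap(psf, ConfocalConfig(slitWidth = 2 * au))
  mask <- viewMask(cfg)
  # strict decay in |pz| for every in-pupil view on the coverage-scale grid
  for (vi in seq_len(cfg@nViews)) for (ui in seq_len(cfg@nViews)) {
    if (!mask[vi, ui]) next
    expect_true(all(diff(em@ebar[, vi, ui]) < 0),
                info = sprintf("view v=%d u=%d", vi - c0, ui - c0))
  }
  expect_lte(max(em@ebar), 1 + 1e-6)
  # suppression acts along the scan axis v: decay with |v| exceeds decay
  # with |u| at depth (the "elongated along u" iso-contour anisotropy)
  izd <- which(bgZ == 30)
  expect_gt(em@ebar[izd, c0, c0 + 2L], em@ebar[izd, c0 + 2L, c0])
})

test_that("photon efficiency has the correct limits and grows with slit size", {
  psf <- testPsf()
  wide <- applyConfocal(psf, ConfocalConfig(slitWidth = Inf))
  expect_equal(photonEfficiency(psf, wide, c(-0.5, 0.5)), 1)
  au <- airyUnit(psf@config, "full")
  eff <- vapply(c(1, 3, 5, 11, 20), function(a) {
    m <- applyConfocal(psf, ConfocalConfig(slitWidth = a * au))
    photonEfficiency(psf, m, c(-0.5, 0.5))
  }, numeric(1))
  expect_true(all(diff(eff) >= 0))
  expect_error(photonEfficiency(psf, wide, c(-10, 10)), "depth list")
})

test_that("axial coverage: unmodulated profile envelopes the modulated ones", {
  psf <- slabPsf()
  au <- airyUnit(psf@config, "full")
  p0 <- axialCoverageProfile(psf)
  p11 <- axialCoverageProfile(applyConfocal(psf, ConfocalConfig(slitWidth = 11 * au)))
  p1 <- axialCoverageProfile(applyConfocal(psf, ConfocalConfig(slitWidth = 1 * au)))
  expect_true(all(p0$profile$energy >= p11$profile$energy - 1e-12))
  expect_true(all(p11$profile$energy >= p1$profile$energy - 1e-12))
  # the tight slit collapses the coverage fastest
  expect_lte(p1$halfEnergyWidth, p11$halfEnergyWidth)
  # defocus symmetry of the profile
  e <- p0$profile$energy
  expect_lt(max(abs(e - rev(e))) / max(e), 0.02)
})

test_that("design report carries the sensor geometry and round-trips through JSON", {
  inv <- invertedOptics(); up <- uprightOptics()
  expect_equal(pixelsPerLens(inv), 13L)
  expect_equal(pixelsPerLens(up), 21L)
  # the reduced test PSF support legitimately trips the truncation monitor
  rep <- suppressWarnings(designReport(inv, ConfocalConfig(slitWidth = 325),
                                       psf = testPsf(), zWindow = c(-0.5, 0.5)))
  expect_equal(rep$px_per_lens, 13L)
  expect_equal(rep$slit_au, 325 / airyUnit(inv, "full"))
  f <- tempfile(fileext = ".json")
  rep$energy_map <- NULL  # data frames flatten in JSON; scalar fields suffice
  jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$au_full_um, rep$au_full_um)
  expect_equal(back$photon_efficiency, rep$photon_efficiency)
})
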