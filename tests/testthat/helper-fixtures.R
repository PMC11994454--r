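# Shared fixtures, computed once per test run and cached. The "test"
# instrument is a 5x5-view scale model whose fine grid resolves the
# diffraction limit; the "background" instrument is a low-magnification
# 20x/0.5 water config whose defocused PSFs stay within a desk-scale
# microlens support, used for slit-design/background experiments.

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, force(expr), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

testOptics <- function() {
  readOpticsConfig(system.file("extdata/optics_test.yaml", package = "cslfm"))
}

invertedOptics <- function() {
  readOpticsConfig(system.file("extdata/optics_inverted.yaml", package = "cslfm"))
}

uprightOptics <- function() {
  readOpticsConfig(system.file("extdata/optics_upright.yaml", package = "cslfm"))
}

backgroundOptics <- function() {
  OpticalConfig(na = 0.5, magObjective = 20, magRelay = 1, wavelength = 525,
                refrIndex = 1.33, mlaPitch = 100, mlaFocal = 2000,
                pixelSize = 20, nViews = 5L, scanSteps = 3L)
}

testZ <- c(-0.5, 0, 0.5)

testPsf <- function() memo("testPsf", {
  computePsf(testOptics(), testZ, nLens = 5L, osf = 3L)
})

testPsf9 <- function() memo("testPsf9", {
  computePsf(testOptics(), testZ, nLens = 9L, osf = 3L)
})

bgZ <- c(0, 15, 30, 45)

bgPsf <- function() memo("bgPsf", {
  computePsf(backgroundOptics(), bgZ, nLens = 13L, osf = 9L)
})

slabZ <- seq(-40, 40, by = 8)

slabPsf <- function() memo("slabPsf", {
  computePsf(backgroundOptics(), slabZ, nLens = 13L, osf = 9L)
})

# point-source volume on the fine grid of a PSF
pointVolume <- function(psf, iy, ix, iz, value = 1, dz = NULL) {
  nF <- length(psf@fineCoords)
  cfg <- psf@config
  st <- cfg@mlaPitch / (cfg@scanSteps * magnification(cfg))
  if (is.null(dz)) dz <- if (length(psf@depths) > 1) min(diff(sort(psf@depths))) else 1
  v <- array(0, c(nF, nF, length(psf@depths)))
  v[iy, ix, iz] <- value
  VolumeGrid(v, c(st, st, dz), zCoords = psf@depths)
}

# nested bead-over-slab volumes: thicker slabs contain the thinner slabs'
# emitters plus deeper ones (same seed), so suppression comparisons are not
# confounded by independent sampling
slabVolume <- function(psf, thicknessUm, seed = 42L, density = 2e-3,
                       beadValue = 2000, emitterValue = 50) {
  nF <- length(psf@fineCoords)
  cfg <- psf@config
  st <- cfg@mlaPitch / (cfg@scanSteps * magnification(cfg))
  z <- psf@depths
  dz <- min(diff(sort(z)))
  v <- array(0, c(nF, nF, length(z)))
  v[(nF + 1) %/% 2, (nF + 1) %/% 2, which(z == 0)] <- beadValue
  zMax <- max(abs(z))
  full <- which(abs(z) <= zMax)
  nE <- round(density * (nF * st)^2 * 2 * zMax)
  set.seed(seed)
  iy <- sample(nF, nE, TRUE); ix <- sample(nF, nE, TRUE)
  zi <- sample(full, nE, TRUE)
  keep <- abs(z[zi]) <= thicknessUm / 2
  for (i in which(keep)) v[iy[i], ix[i], zi[i]] <- v[iy[i], ix[i], zi[i]] + emitterValue
  VolumeGrid(v, c(st, st, dz), zCoords = z)
}

centralViewIndex <- function(config) (config@nViews + 1L) / 2L
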