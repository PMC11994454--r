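# Forward acquisition model: linear view-space imaging (Eq.-7-style PSF
# convolution per depth), the explicit raw-sensor rolling-shutter sweep
# (moving illumination line + synchronized shutter window, integrated over
# the exposure), shot/read noise, and cLFM frame extraction.

# match volume depths into the PSF depth list; error on mismatch
matchDepths <- function(volZ, psfZ) {
  idx <- vapply(volZ, function(z) {
    j <- which(abs(psfZ - z) < 1e-6)
    if (!length(j)) stop(sprintf("volume depth %g um is not in the PSF depth list", z))
    j[1]
  }, integer(1))
  idx
}

#' Forward-project a volume into angular views
#'
#' Linear, laterally shift-invariant imaging on the fine grid: each view is
#' the depth-sum of the volume slices convolved with the matching
#' spatial-angular PSF kernels. A modulated PSF yields csLFM views, an
#' unmodulated one sLFM views.
#'
#' @param volume a \code{VolumeGrid}; lateral voxel size must equal the PSF
#'   fine step and depths must be a subset of the PSF depth list.
#' @param psf a \code{SpatialAngularPSF}.
#' @param sparseLimit use direct sparse accumulation instead of FFT
#'   convolution when the volume has at most this many nonzero voxels.
#' @return a \code{MultiViewStack} with the volume's lateral dimensions.
#' @export
forwardViews <- function(volume, psf, sparseLimit = 64L) {
  stopifnot(is(volume, "VolumeGrid"), is(psf, "SpatialAngularPSF"))
  cfg <- psf@config
  stepObj <- cfg@mlaPitch / (cfg@scanSteps * magnification(cfg))
  if (max(abs(volume@voxel[1:2] - stepObj)) > 1e-6)
    stop(sprintf("lateral voxel size must equal the PSF fine step (%g um)", stepObj))
  zIdx <- matchDepths(volume@zCoords, psf@depths)
  d <- dim(volume@data)
  nV <- cfg@nViews
  f0 <- which(abs(psf@fineCoords) < 1e-9)
  views <- array(0, c(d[1], d[2], nV, nV))
  nz <- which(volume@data != 0)
  if (length(nz) <= sparseLimit) {
    ijk <- arrayInd(nz, d)
    nF <- length(psf@fineCoords)
    for (q in seq_along(nz)) {
      iy <- ijk[q, 1]; ix <- ijk[q, 2]; val <- volume@data[nz[q]]
      zi <- zIdx[ijk[q, 3]]
      ry <- iy + seq_len(nF) - f0; rx <- ix + seq_len(nF) - f0
      oky <- ry >= 1 & ry <= d[1]; okx <- rx >= 1 & rx <= d[2]
      ker <- psf@hp[oky, okx, , , zi, drop = FALSE]
      dim(ker) <- dim(ker)[1:4]
      old <- views[ry[oky], rx[okx], , , drop = FALSE]
      dim(old) <- dim(ker)
      views[ry[oky], rx[okx], , ] <- old + val * ker
    }
  } else {
    for (vi in seq_len(nV)) for (ui in seq_len(nV)) {
      acc <- matrix(0, d[1], d[2])
      for (iz in seq_len(d[3])) {
        sl <- volume@data[, , iz]
        if (!any(sl != 0)) next
        acc <- acc + fftConv2Same(sl, psf@hp[, , vi, ui, zIdx[iz]], center = c(f0, f0))
      }
      views[, , vi, ui] <- acc
    }
  }
  views[views < 0] <- 0   # FFT round-off
  new("MultiViewStack", views = views, fineCoords = psf@fineCoords,
      config = cfg, mode = if (psf@modulated) "csLFM" else "sLFM",
      provenance = list(noise = FALSE,
                        ws_um = if (psf@modulated) psf@slitWidth else NA_real_))
}

# inverse realignment: place view samples back on the sensor for one phase
deRealignFrame <- function(views, config, nLens, ky, kx) {
  nV <- config@nViews; s <- config@scanSteps
  ri <- realignIndex(nLens, s)
  G <- nLens * nV
  frame <- matrix(0, G, G)
  fy <- match(seq_len(nLens), ri$l[ri$k == ky])  # fine index per lens at phase ky
  fyIdx <- which(ri$k == ky)[fy]
  fxIdx <- which(ri$k == kx)[match(seq_len(nLens), ri$l[ri$k == kx])]
  for (vi in seq_len(nV)) for (ui in seq_len(nV)) {
    frame[(seq_len(nLens) - 1L) * nV + vi, (seq_len(nLens) - 1L) * nV + ui] <-
      views[fyIdx, fxIdx, vi, ui]
  }
  frame
}

#' Simulate a raw rolling-shutter scan sequence
#'
#' Explicit acquisition model: for each scan phase a full sensor frame is
#' integrated while the illumination line (a top-hat of width
#' \code{slitWidth/M} in object y, uniform in z over the illumination axial
#' extent) sweeps the field and the rolling-shutter window of height
#' \code{shutterHeight} tracks its conjugate position, masking all other
#' sensor rows (csLFM mode). sLFM mode applies neither strip nor mask and
#' returns the unswept full-frame images.
#'
#' @param volume a \code{VolumeGrid} whose lateral size equals the PSF fine
#'   grid.
#' @param psf the unmodulated \code{SpatialAngularPSF} of the instrument.
#' @param confocal a \code{ConfocalConfig} (required for csLFM mode).
#' @param mode "sLFM" or "csLFM".
#' @param sweepSteps illumination-line positions integrated per frame
#'   (midpoint rule over the sweep; edges of strip and shutter are
#'   antialiased by fractional row coverage).
#' @return a \code{RawScanSequence}.
#' @export
simulateRawScan <- function(volume, psf, confocal = NULL,
                            mode = c("sLFM", "csLFM"), sweepSteps = 64L) {
  mode <- match.arg(mode)
  stopifnot(is(psf, "SpatialAngularPSF"))
  if (psf@modulated)
    stop("supply the unmodulated PSF; the sweep itself applies the confocal modulation")
  cfg <- psf@config
  s <- cfg@scanSteps; nV <- cfg@nViews
  nF <- length(psf@fineCoords)
  d <- dim(volume@data)
  if (d[1] != nF || d[2] != nF)
    stop("volume lateral size must match the PSF fine grid (", nF, " samples)")
  nLens <- nF %/% s
  M <- magnification(cfg)
  G <- nLens * nV
  frames <- array(0, c(G, G, s * s))
  if (mode == "sLFM") {
    views <- forwardViews(volume, psf)
    for (ky in 0:(s - 1L)) for (kx in 0:(s - 1L))
      frames[, , ky * s + kx + 1L] <- deRealignFrame(views@views, cfg, nLens, ky, kx)
    return(new("RawScanSequence", frames = frames, s = s, mode = mode,
               config = cfg, confocal = NULL, sweepSteps = 1L))
  }
  if (is.null(confocal)) stop("csLFM mode requires a ConfocalConfig")
  ws <- confocal@slitWidth; hr <- confocal@shutterHeight
  rowH <- cfg@mlaPitch / nV                 # sensor row height at the MLA plane
  pixC <- (seq_len(G) - (G + 1) / 2) * rowH # sensor row centres, MLA um
  volRowC <- psf@fineCoords                 # voxel row centres, MLA um
  rowW <- cfg@mlaPitch / s                  # voxel row extent, MLA um
  span <- range(c(pixC, volRowC))
  lo <- span[1] - (ws + hr) / 2; hi <- span[2] + (ws + hr) / 2
  dC <- (hi - lo) / sweepSteps
  if (dC > hr / 4)
    warning(sprintf("sweep step %.3g um exceeds a quarter shutter height; undersampled sweep", dC))
  centres <- lo + (seq_len(sweepSteps) - 0.5) * dC
  zOK <- abs(volume@zCoords) <= confocal@illumAxialExtent / 2 + 1e-9
  overlapFrac <- function(x, halfA, c0, halfB)  # |[x +- halfA] ^ [c0 +- halfB]| / (2 halfA)
    pmax(0, pmin(x + halfA, c0 + halfB) - pmax(x - halfA, c0 - halfB)) / (2 * halfA)
  for (j in seq_len(sweepSteps)) {
    cj <- centres[j]
    wy <- overlapFrac(volRowC, rowW / 2, cj, ws / 2)
    if (!any(wy > 0)) next
    wvol <- volume@data * wy                 # recycles over first (y) dim
    if (!all(zOK)) wvol[, , !zOK] <- 0
    if (!any(wvol != 0)) next
    vj <- forwardViews(VolumeGrid(wvol, volume@voxel, volume@zCoords), psf)
    for (ky in 0:(s - 1L)) for (kx in 0:(s - 1L)) {
      # the shutter tracks the illumination line's image, which carries the
      # scan-phase drift of the image plane; shift the window accordingly
      maskRow <- overlapFrac(pixC, rowH / 2, cj + ky * cfg@mlaPitch / s, hr / 2)
      fr <- deRealignFrame(vj@views, cfg, nLens, ky, kx)
      frames[, , ky * s + kx + 1L] <- frames[, , ky * s + kx + 1L] +
        maskRow * fr * dC / min(ws, hr)
    }
  }
  new("RawScanSequence", frames = frames, s = s, mode = mode, config = cfg,
      confocal = confocal, sweepSteps = as.integer(sweepSteps))
}

#' Add photon and read noise to a measurement
#'
#' Poisson shot noise at \code{photonScale} photons per intensity unit plus
#' zero-mean Gaussian read noise, seeded and deterministic. Values are
#' clamped at zero after read noise so downstream nonnegativity contracts
#' hold.
#'
#' @param x a \code{RawScanSequence}, \code{MultiViewStack} or numeric array.
#' @param photonScale photons per intensity unit (larger = less shot noise).
#' @param readNoiseE read-noise standard deviation, electrons (1 e- = 1
#'   photon at unit gain).
#' @param seed integer seed.
#' @return object of the same class with noisy values.
#' @export
addNoise <- function(x, photonScale = 1, readNoiseE = 1.6, seed = 1L) {
  noisify <- function(a) {
    if (min(a) < 0) stop("negative input intensity")
    n <- length(a)
    out <- withSeed(seed, {
      v <- rpois(n, as.vector(a) * photonScale) +
        rnorm(n, sd = readNoiseE)
      v / photonScale
    })
    out[out < 0] <- 0
    array(out, dim(a))
  }
  if (is(x, "RawScanSequence")) {
    x@frames <- noisify(x@frames); return(x)
  }
  if (is(x, "MultiViewStack")) {
    x@views <- noisify(x@views); x@provenance$noise <- TRUE; return(x)
  }
  noisify(x)
}

#' Extract a single-position cLFM frame from a scan sequence
#'
#' Returns the one scan position's sensor frame as an unscanned (s = 1)
#' sequence for cLFM-style processing.
#'
#' @param seq a \code{RawScanSequence}.
#' @param phaseIndex frame index in 1..s^2.
#' @return a \code{RawScanSequence} with a single frame; the scan phase it
#'   came from is recorded in the mode string metadata via attribute
#'   \code{phaseOrigin}.
#' @export
extractClfmFrame <- function(seq, phaseIndex = 1L) {
  stopifnot(is(seq, "RawScanSequence"))
  if (phaseIndex < 1L || phaseIndex > dim(seq@frames)[3])
    stop("phase index out of range")
  cfg <- seq@config
  cfg1 <- cfg; cfg1@scanSteps <- 1L
  out <- new("RawScanSequence",
             frames = seq@frames[, , phaseIndex, drop = FALSE], s = 1L,
             mode = seq@mode, config = cfg1, confocal = seq@confocal,
             sweepSteps = seq@sweepSteps)
  attr(out@frames, "phaseOrigin") <- as.integer(phaseIndex)
  out
}
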