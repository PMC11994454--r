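# Reconstruction: pixel realignment of measurements, cLFM cubic upsampling,
# multi-view Richardson-Lucy iterative tomography and simplified digital
# adaptive optics (per-view rigid disparity correction).

#' Pixel-realign a raw scan sequence into angular views
#'
#' The same lossless permutation as the PSF realignment, applied to
#' measurements: pixel offset within a microlens becomes the view index and
#' (microlens, scan phase) interleave into the fine spatial grid. Energy is
#' conserved exactly.
#'
#' @param seq a \code{RawScanSequence} holding the complete scan lattice.
#' @param config the matching \code{OpticalConfig}.
#' @return a \code{MultiViewStack}.
#' @export
pixelRealign <- function(seq, config = seq@config) {
  stopifnot(is(seq, "RawScanSequence"))
  s <- seq@s
  d <- dim(seq@frames)
  if (d[3] != s * s) stop("incomplete scan lattice")
  nV <- config@nViews
  if (d[1] %% nV != 0L) stop("sensor rows not a multiple of nViews")
  nLens <- d[1] %/% nV
  ri <- realignIndex(nLens, s)
  nF <- nLens * s
  views <- array(0, c(nF, nF, nV, nV))
  for (ky in 0:(s - 1L)) for (kx in 0:(s - 1L)) {
    fy <- which(ri$k == ky); fx <- which(ri$k == kx)
    X <- seq@frames[, , ky * s + kx + 1L]
    for (vi in seq_len(nV)) for (ui in seq_len(nV))
      views[fy, fx, vi, ui] <- X[(ri$l[fy] - 1L) * nV + vi, (ri$l[fx] - 1L) * nV + ui]
  }
  fine <- ri$m * config@mlaPitch / s
  new("MultiViewStack", views = views, fineCoords = fine, config = config,
      mode = seq@mode, provenance = list(noise = NA, realigned = TRUE))
}

#' Cubic upsampling of unscanned (cLFM) views to the fine grid
#'
#' Separable 4-point (Lagrange) cubic interpolation of single-phase views
#' from the microlens-pitch grid onto the fine pitch/s grid of a scanned
#' stack.
#'
#' @param views a \code{MultiViewStack} from a single-phase (s = 1) sequence.
#' @param factor target scan factor s (>= 1).
#' @return a \code{MultiViewStack} on the fine grid.
#' @export
clfmUpsample <- function(views, factor) {
  stopifnot(is(views, "MultiViewStack"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("upsampling factor must be >= 1")
  if (factor == 1L) return(views)
  cfg <- views@config
  coarse <- views@fineCoords
  nLens <- length(coarse)
  ri <- realignIndex(nLens, factor)
  fine <- ri$m * cfg@mlaPitch / factor
  # positions of fine samples in units of the coarse sample index
  at <- (fine - coarse[1]) / (coarse[2] - coarse[1]) + 1
  d <- dim(views@views)
  nF <- length(fine)
  out <- array(0, c(nF, nF, d[3], d[4]))
  for (vi in seq_len(d[3])) for (ui in seq_len(d[4])) {
    tmp <- matrix(0, nF, d[2])
    for (j in seq_len(d[2])) tmp[, j] <- lagrangeCubic1(views@views[, j, vi, ui], at)
    full <- matrix(0, nF, nF)
    for (i in seq_len(nF)) full[i, ] <- lagrangeCubic1(tmp[i, ], at)
    full[full < 0] <- 0
    out[, , vi, ui] <- full
  }
  cfgUp <- cfg; cfgUp@scanSteps <- factor
  prov <- views@provenance; prov$upsampled <- factor
  new("MultiViewStack", views = out, fineCoords = fine, config = cfgUp,
      mode = views@mode, provenance = prov)
}

# shift PSF kernels per view by the ShiftMap (object um -> fine samples)
shiftPsf <- function(psf, shifts) {
  cfg <- psf@config
  stepObj <- cfg@mlaPitch / (cfg@scanSteps * magnification(cfg))
  hp <- psf@hp
  nV <- cfg@nViews
  for (vi in seq_len(nV)) for (ui in seq_len(nV)) {
    dy <- shifts@dy[vi, ui] / stepObj
    dx <- shifts@dx[vi, ui] / stepObj
    if (abs(dy) < 1e-9 && abs(dx) < 1e-9) next
    for (iz in seq_along(psf@depths)) {
      k <- fourierShift2(hp[, , vi, ui, iz], dy, dx)
      k[k < 0] <- 0
      hp[, , vi, ui, iz] <- k
    }
  }
  psf@hp <- hp
  psf
}

#' Multi-view Richardson-Lucy iterative tomography
#'
#' Multiplicative update with the spatial-angular PSF as the projection
#' model: \code{vol <- vol * [sum_v BP_v(meas_v / (FP_v(vol) + eps))] /
#' [sum_v BP_v(1)]}, where FP/BP are per-view, per-depth FFT convolutions
#' with the (optionally shift-corrected) PSF kernels. Nonnegativity is
#' preserved by construction; the Poisson data fidelity is logged per
#' iteration. Views outside the pupil disk are skipped.
#'
#' @param views a \code{MultiViewStack}.
#' @param psf a \code{SpatialAngularPSF}; using an unmodulated PSF on csLFM
#'   data is permitted but flagged with a warning (out-of-focus artifacts).
#' @param nIter iterations; 0 returns the initialization.
#' @param shifts optional \code{ShiftMap} for digital adaptive optics; the
#'   PSF kernels (not the measurements) are shifted to keep the forward
#'   model consistent.
#' @param depths reconstruction depth list; defaults to the PSF depth list.
#' @param init "constant" (uniform positive) or "backprojection".
#' @param epsFactor RL ratio guard, relative to the measurement maximum.
#' @return a \code{ReconResult}.
#' @export
iterativeTomography <- function(views, psf, nIter = 30L, shifts = NULL,
                                depths = psf@depths,
                                init = c("constant", "backprojection"),
                                epsFactor = 1e-9) {
  stopifnot(is(views, "MultiViewStack"), is(psf, "SpatialAngularPSF"))
  init <- match.arg(init)
  cfg <- psf@config
  if (identical(views@mode, "csLFM") && !psf@modulated)
    warning("reconstructing csLFM data with an unmodulated PSF; expect out-of-focus artifacts")
  zIdx <- matchDepths(depths, psf@depths)
  if (!is.null(shifts)) psf <- shiftPsf(psf, shifts)
  d <- dim(views@views)
  nV <- cfg@nViews
  mask <- viewMask(cfg)
  f0 <- which(abs(psf@fineCoords) < 1e-9)
  cen <- c(f0, f0)
  nz <- length(zIdx)
  eps <- epsFactor * max(views@views)
  stepObj <- cfg@mlaPitch / (cfg@scanSteps * magnification(cfg))
  vxl <- c(stepObj, stepObj, if (nz > 1) min(diff(sort(depths))) else stepObj)
  useView <- which(mask & apply(psf@hp, c(3, 4), sum)[, , drop = FALSE] > 0, arr.ind = TRUE)
  # denominator: sum over views of BP(1)
  ones <- matrix(1, d[1], d[2])
  den <- array(0, c(d[1], d[2], nz))
  for (r in seq_len(nrow(useView))) {
    vi <- useView[r, 1]; ui <- useView[r, 2]
    for (iz in seq_len(nz))
      den[, , iz] <- den[, , iz] +
        fftCorr2Same(ones, psf@hp[, , vi, ui, zIdx[iz]], center = cen)
  }
  den[den < 1e-12] <- 1e-12
  vol <- if (init == "constant") {
    array(max(mean(views@views), 1e-6), c(d[1], d[2], nz))
  } else {
    bp <- array(0, c(d[1], d[2], nz))
    for (r in seq_len(nrow(useView))) {
      vi <- useView[r, 1]; ui <- useView[r, 2]
      for (iz in seq_len(nz))
        bp[, , iz] <- bp[, , iz] +
          fftCorr2Same(views@views[, , vi, ui], psf@hp[, , vi, ui, zIdx[iz]], center = cen)
    }
    bp / den
  }
  fid <- numeric(0)
  forwardV <- function(vol, vi, ui) {
    acc <- matrix(0, d[1], d[2])
    for (iz in seq_len(nz))
      acc <- acc + fftConv2Same(vol[, , iz], psf@hp[, , vi, ui, zIdx[iz]], center = cen)
    acc
  }
  for (it in seq_len(nIter)) {
    num <- array(0, c(d[1], d[2], nz))
    fidIt <- 0
    for (r in seq_len(nrow(useView))) {
      vi <- useView[r, 1]; ui <- useView[r, 2]
      fwd <- forwardV(vol, vi, ui)
      fwd[fwd < 0] <- 0
      m <- views@views[, , vi, ui]
      fidIt <- fidIt + sum(fwd - m * log(fwd + eps))
      ratio <- m / (fwd + eps)
      for (iz in seq_len(nz))
        num[, , iz] <- num[, , iz] +
          fftCorr2Same(ratio, psf@hp[, , vi, ui, zIdx[iz]], center = cen)
    }
    vol <- vol * num / den
    vol[vol < 0] <- 0
    fid <- c(fid, fidIt)
  }
  psfInfo <- list(modulated = psf@modulated,
                  ws_um = if (psf@modulated) psf@slitWidth else NA_real_,
                  n_views = nV, n_iter = as.integer(nIter))
  new("ReconResult",
      volume = VolumeGrid(vol, vxl, zCoords = depths),
      iterations = as.integer(nIter), fidelity = fid,
      shifts = shifts, psfInfo = psfInfo)
}

#' Estimate per-view disparity shifts (simplified digital adaptive optics)
#'
#' Runs a short unshifted reconstruction, forward-projects it per view, and
#' measures the residual displacement of each measured view against its
#' prediction by subpixel phase correlation. Because the prediction carries
#' the PSF's intrinsic parallax, the estimate isolates the aberration-like
#' extra disparity. Estimates are taken relative to the central view (whose
#' shift is zero by definition) and clamped at \code{maxShift}.
#'
#' @param views a \code{MultiViewStack}.
#' @param psf the matching \code{SpatialAngularPSF}.
#' @param nIter iterations of the internal reference reconstruction.
#' @param nOuter outer estimate-correct-re-estimate cycles (the usual
#'   adaptive-optics loop); 2 is enough for tilts within the clamp.
#' @param maxShift clamp for shift magnitudes, object um.
#' @param refine add a correlation-parabola subpixel refinement stage (off
#'   by default; whitened phase correlation is more robust to the residual
#'   blur of the internal reference).
#' @param varThreshold views with variance below this fraction of the
#'   maximum view variance are treated as featureless (zero shift, warning).
#' @return a \code{ShiftMap} (dy, dx in object um).
#' @export
daoEstimate <- function(views, psf, nIter = 20L, nOuter = 2L, maxShift = 2,
                        varThreshold = 1e-6, refine = FALSE) {
  stopifnot(is(views, "MultiViewStack"), is(psf, "SpatialAngularPSF"))
  cfg <- psf@config
  nV <- cfg@nViews
  c0 <- (nV + 1L) / 2L
  stepObj <- cfg@mlaPitch / (cfg@scanSteps * magnification(cfg))
  mask <- viewMask(cfg)
  vvar <- apply(views@views, c(3, 4), function(m) var(as.vector(m)))
  if (max(vvar) <= 0 || all(vvar[mask] < varThreshold * max(vvar))) {
    warning("views are featureless; returning zero shifts")
    z <- matrix(0, nV, nV)
    return(new("ShiftMap", dy = z, dx = z, maxShift = maxShift))
  }
  # Outer adaptive-optics loop: estimate, correct the PSF, re-reconstruct,
  # re-estimate the residual. The windowed correlation underestimates large
  # displacements by a roughly multiplicative factor, so accumulating
  # residual corrections converges to the true shift (geometric series),
  # whereas a single pass stops ~10% short for pitch-scale tilts.
  total <- list(dy = matrix(0, nV, nV), dx = matrix(0, nV, nV))
  psf0 <- psf
  for (outer in seq_len(nOuter)) {
  rec <- iterativeTomography(views, psf, nIter = nIter)
  d <- dim(views@views)
  # Hann window against wrap-around bias in the Fourier correlation
  hann <- outer(0.5 - 0.5 * cos(2 * pi * (seq_len(d[1]) - 1) / (d[1] - 1)),
                0.5 - 0.5 * cos(2 * pi * (seq_len(d[2]) - 1) / (d[2] - 1)))
  f0 <- which(abs(psf@fineCoords) < 1e-9); cen <- c(f0, f0)
  zIdx <- matchDepths(rec@volume@zCoords, psf@depths)
  dy <- matrix(0, nV, nV); dx <- matrix(0, nV, nV)
  for (vi in seq_len(nV)) for (ui in seq_len(nV)) {
    if (!mask[vi, ui]) next
    if (vvar[vi, ui] < varThreshold * max(vvar)) next
    pred <- matrix(0, d[1], d[2])
    for (iz in seq_along(zIdx))
      pred <- pred + fftConv2Same(rec@volume@data[, , iz],
                                  psf@hp[, , vi, ui, zIdx[iz]], center = cen)
    if (sum(pred) <= 0) next
    meas <- views@views[, , vi, ui] * hann
    sh <- phaseCorrShift(meas, pred * hann)
    # optional: refine each axis by a parabola on the normalized correlation
    # of the fractionally shifted prediction
    ncc <- function(s) {
      p <- fourierShift2(pred, s[1], s[2]) * hann
      sum(meas * p) / sqrt(sum(p * p))
    }
    if (refine) for (ax in 1:2) {
      st3 <- c(-0.5, 0, 0.5)
      v3 <- vapply(st3, function(o) {
        s <- sh; s[ax] <- s[ax] + o; ncc(s)
      }, numeric(1))
      dn <- v3[1] - 2 * v3[2] + v3[3]
      if (is.finite(dn) && abs(dn) > .Machine$double.eps)
        sh[ax] <- sh[ax] + 0.25 * (v3[1] - v3[3]) / dn
    }
    dy[vi, ui] <- sh[1] * stepObj
    dx[vi, ui] <- sh[2] * stepObj
  }
  # relative to the central view; accumulate the residual and clamp
  dy <- dy - dy[c0, c0]; dx <- dx - dx[c0, c0]
  dy[!mask] <- 0; dx[!mask] <- 0
  total$dy <- pmin(pmax(total$dy + dy, -maxShift), maxShift)
  total$dx <- pmin(pmax(total$dx + dx, -maxShift), maxShift)
  if (outer < nOuter)
    psf <- shiftPsf(psf0, new("ShiftMap", dy = total$dy, dx = total$dx,
                              maxShift = maxShift))
  }
  new("ShiftMap", dy = total$dy, dx = total$dx, maxShift = maxShift)
}

#' Full reconstruction pipeline
#'
#' Realign (when given a raw sequence), optionally estimate digital
#' adaptive-optics shifts, then run iterative tomography. All resolved
#' parameters are logged in the result's \code{psfInfo}.
#'
#' @param x a \code{RawScanSequence} or \code{MultiViewStack}.
#' @param psf a \code{SpatialAngularPSF}.
#' @param dao run \code{daoEstimate} and use the shifts.
#' @param nIter RL iterations.
#' @param ... forwarded to \code{iterativeTomography}.
#' @return a \code{ReconResult}.
#' @export
reconstructPipeline <- function(x, psf, dao = FALSE, nIter = 30L, ...) {
  views <- if (is(x, "RawScanSequence")) pixelRealign(x, psf@config) else x
  shifts <- if (dao) daoEstimate(views, psf) else NULL
  res <- iterativeTomography(views, psf, nIter = nIter, shifts = shifts, ...)
  res@psfInfo$dao <- dao
  res@psfInfo$provenance <- sprintf("psf[modulated=%s,ws_um=%s] nIter=%d dao=%s",
                                    psf@modulated,
                                    format(if (psf@modulated) psf@slitWidth else NA),
                                    nIter, dao)
  res
}
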