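# Wave-optics core: scalar Debye field at the native image plane, microlens
# sampling to the sensor, and pixel realignment into the spatial-angular
# domain.
#
# The scalar Debye integral of an aplanatic objective (apodization sqrt(cos))
# gives the amplitude of an isotropic point emitter at the native image
# plane; lateral image coordinates are object coordinates scaled by the total
# magnification M, defocus is expressed in object micrometres. Each microlens
# applies its aperture window and the Fourier-transforming propagation over
# one microlens focal length; the squared modulus is integrated over sensor
# pixels. Realignment is the lossless reindexing of (microlens, pixel, scan
# phase) into (view, fine spatial position).

# Radial Debye amplitude table: rows = radius, cols = depth.
debyeRadial <- function(config, depths, rMaxObj, thetaNodes = 256L) {
  lam <- config@wavelength * 1e-3            # um
  n <- config@refrIndex
  k <- 2 * pi / lam
  alpha <- asin(config@na / n)
  theta <- seq(0, alpha, length.out = thetaNodes + 1L)
  w <- simpsonWeights(thetaNodes, theta[2] - theta[1])
  apod <- sqrt(cos(theta)) * sin(theta)
  dr <- lam / (20 * config@na)
  r <- seq(0, rMaxObj + dr, by = dr)
  J <- besselJ(outer(r, k * n * sin(theta)), 0)      # [nr, ntheta]
  U <- matrix(0 + 0i, length(r), length(depths))
  for (iz in seq_along(depths)) {
    ph <- exp(1i * k * n * depths[iz] * cos(theta))
    U[, iz] <- J %*% (w * apod * ph)
  }
  list(r = r, U = U)
}

#' Scalar Debye field at the native image plane
#'
#' Evaluates the amplitude point-spread function of an aplanatic objective
#' for a list of defocus depths, sampled at the microlens plane on a grid
#' commensurate with the microlens/pixel lattice (plus one pitch of margin so
#' scan phases become integer-sample shifts).
#'
#' @param config an \code{OpticalConfig}.
#' @param depths defocus depths in object micrometres.
#' @param nLens lateral support in microlens pitches (odd).
#' @param osf grid samples per sensor pixel (odd); the grid step is
#'   \code{mlaPitch/(nViews*osf)} at the MLA plane and must satisfy the
#'   Nyquist bound \code{lambda*M/(4*NA)}.
#' @param thetaNodes Simpson nodes over the aperture angle.
#' @return a \code{NativeField}.
#' @export
computeNativeField <- function(config, depths, nLens = 5L, osf = 3L,
                               thetaNodes = 256L) {
  stopifnot(is(config, "OpticalConfig"))
  validObject(config)
  nLens <- as.integer(nLens); osf <- as.integer(osf)
  if (nLens %% 2L != 1L || osf %% 2L != 1L)
    stop("nLens and osf must be odd")
  M <- magnification(config)
  P <- config@nViews * osf
  h <- config@mlaPitch / P
  nyq <- config@wavelength * 1e-3 * M / (4 * config@na)
  if (h > nyq + 1e-9)
    stop(sprintf(paste("native grid step %.4g um is coarser than the Nyquist",
                       "bound %.4g um; increase osf"), h, nyq))
  N <- nLens * P
  main <- (seq_len(N) - (N + 1) / 2) * h
  ext <- c(main[1] - (P:1) * h, main)        # one pitch margin, low side
  rGrid <- sqrt(outer(ext^2, ext^2, "+")) / M
  tab <- debyeRadial(config, depths, max(rGrid), thetaNodes)
  field <- array(0 + 0i, c(length(ext), length(ext), length(depths)))
  for (iz in seq_along(depths)) {
    re <- approx(tab$r, Re(tab$U[, iz]), xout = rGrid, rule = 2)$y
    im <- approx(tab$r, Im(tab$U[, iz]), xout = rGrid, rule = 2)$y
    field[, , iz] <- complex(real = re, imaginary = im)
  }
  new("NativeField", field = field, yCoords = ext, xCoords = ext, step = h,
      depths = depths, config = config, nLens = nLens, osf = osf)
}

#' Sensor-plane light-field PSF
#'
#' Propagates a \code{NativeField} through the microlens array to the sensor:
#' per microlens, the field is windowed by the lens aperture, Fourier
#' transformed over one microlens focal length, squared, and integrated over
#' sensor pixels. One pattern is produced per scan phase (emitter position
#' modulo one pitch on the s x s scan lattice). The output is normalized so
#' the in-focus pattern sums to one.
#'
#' @param field a \code{NativeField}.
#' @param config the matching \code{OpticalConfig}.
#' @return a \code{SensorPSF}.
#' @export
computeSensorPsf <- function(field, config = field@config) {
  stopifnot(is(field, "NativeField"))
  nV <- config@nViews; osf <- field@osf; nLens <- field@nLens
  s <- config@scanSteps
  if (nLens < 3L)
    stop("field must cover at least 3 microlens pitches per direction")
  P <- nV * osf
  if (P %% s != 0L)
    stop("scan-phase lattice not commensurate with the view/pixel grid: ",
         sprintf("nViews*osf = %d is not divisible by s = %d", P, s))
  shiftSamp <- P %/% s
  N <- nLens * P
  margin <- P
  lam <- config@wavelength * 1e-3
  n <- config@refrIndex
  h <- field@step
  xm <- (seq_len(P) - (P + 1) / 2) * h       # within-lens coords = subsample coords
  E <- exp(-1i * (2 * pi * n / (lam * config@mlaFocal)) * outer(xm, xm)) * h
  nz <- length(field@depths)
  G <- nLens * nV
  hs <- array(0, c(G, G, s, s, nz))
  binIdx <- rep(seq_len(nV), each = osf)
  for (iz in seq_len(nz)) {
    for (ky in 0:(s - 1L)) for (kx in 0:(s - 1L)) {
      # emitter displaced by +delta: sample U(x - delta) = shift window down
      rows <- margin + seq_len(N) - ky * shiftSamp
      cols <- margin + seq_len(N) - kx * shiftSamp
      W <- field@field[rows, cols, iz]
      for (ly in seq_len(nLens)) {
        Ry <- E %*% W[(ly - 1L) * P + seq_len(P), ]
        for (lx in seq_len(nLens)) {
          S <- Ry[, (lx - 1L) * P + seq_len(P)] %*% t(E)
          I <- Mod(S)^2
          # integrate over sensor pixels (mean over osf x osf subsamples)
          Ib <- rowsum(I, binIdx) ; Ib <- t(rowsum(t(Ib), binIdx)) / osf^2
          hs[(ly - 1L) * nV + seq_len(nV), (lx - 1L) * nV + seq_len(nV),
             ky + 1L, kx + 1L, iz] <- Ib
        }
      }
    }
  }
  izRef <- which.min(abs(field@depths))
  norm <- sum(hs[, , 1L, 1L, izRef])
  hs <- hs / norm
  pix <- (seq_len(G) - (G + 1) / 2) * config@mlaPitch / nV
  new("SensorPSF", hs = hs, pixCoords = pix, depths = field@depths,
      config = config, nLens = nLens)
}

# Fine-grid bookkeeping shared by PSF and measurement realignment.
# Fine position m = s*(l - lc) - k, k = 0..s-1 the scan phase, l the lens.
realignIndex <- function(nLens, s) {
  lc <- (nLens + 1L) %/% 2L
  mMin <- s * (1L - lc) - (s - 1L)
  m <- mMin + seq_len(nLens * s) - 1L
  k <- (-m) %% s
  l <- lc + (m + k) %/% s
  list(m = m, k = k, l = l, lc = lc)
}

#' Pixel realignment of a sensor PSF into the spatial-angular domain
#'
#' Pure permutation ("dimension exchange"): the pixel offset within each
#' microlens becomes the view index (u, v) and microlens centre minus
#' magnified emitter position, interleaved with the scan phases, becomes the
#' fine spatial coordinate (xbar, ybar). No interpolation; energy is
#' conserved exactly.
#'
#' @param sensorPsf a \code{SensorPSF} holding all s x s scan phases.
#' @param config the matching \code{OpticalConfig}.
#' @return an unmodulated \code{SpatialAngularPSF}.
#' @export
realignPsf <- function(sensorPsf, config = sensorPsf@config) {
  stopifnot(is(sensorPsf, "SensorPSF"))
  s <- config@scanSteps
  d <- dim(sensorPsf@hs)
  if (d[3] != s || d[4] != s)
    stop("sensor PSF does not hold the complete ", s, " x ", s, " scan lattice")
  nV <- config@nViews
  nLens <- sensorPsf@nLens
  nz <- d[5]
  ri <- realignIndex(nLens, s)
  nF <- nLens * s
  hp <- array(0, c(nF, nF, nV, nV, nz))
  for (iz in seq_len(nz)) for (ky in 0:(s - 1L)) for (kx in 0:(s - 1L)) {
    fy <- which(ri$k == ky); fx <- which(ri$k == kx)
    X <- sensorPsf@hs[, , ky + 1L, kx + 1L, iz]
    for (vi in seq_len(nV)) for (ui in seq_len(nV)) {
      hp[fy, fx, vi, ui, iz] <-
        X[(ri$l[fy] - 1L) * nV + vi, (ri$l[fx] - 1L) * nV + ui]
    }
  }
  fine <- ri$m * config@mlaPitch / s
  new("SpatialAngularPSF", hp = hp, fineCoords = fine,
      depths = sensorPsf@depths, config = config, modulated = FALSE,
      slitWidth = NA_real_)
}

# brute-force realignment oracle lives in the test suite, not here

#' Convenience wrapper: build the spatial-angular PSF from a configuration
#'
#' Runs \code{computeNativeField}, \code{computeSensorPsf} and
#' \code{realignPsf} in sequence.
#'
#' @inheritParams computeNativeField
#' @return an unmodulated \code{SpatialAngularPSF}.
#' @export
computePsf <- function(config, depths, nLens = 5L, osf = 3L,
                       thetaNodes = 256L) {
  nf <- computeNativeField(config, depths, nLens = nLens, osf = osf,
                           thetaNodes = thetaNodes)
  realignPsf(computeSensorPsf(nf, config), config)
}
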