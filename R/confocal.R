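# Line-confocal modulation model and slit-design calculators.
#
# The synchronized sweep of an illumination line of width ws (at the
# conjugate image plane) with a rolling-shutter window of height hr acts, for
# each sensor row, as the convolution of two rect windows in the scan
# coordinate. With ws = hr (the conjugate slit/shutter condition) that
# convolution is the unit triangle tri(ybar/ws); in general it is a
# trapezoid. Applied to the spatial-angular PSF this multiplies each (ybar)
# row by the weight, uniformly along xbar.

#' Triangle confocal weight
#'
#' \code{tri(ybar/ws) = max(0, 1 - |ybar/ws|)}, the modulation profile when
#' the slit width equals the rolling-shutter height.
#'
#' @param ybar spatial-angular coordinate(s), um at the conjugate image plane.
#' @param ws slit width, um.
#' @export
triWeight <- function(ybar, ws) {
  if (ws <= 0) stop("slit width must be positive")
  pmax(0, 1 - abs(ybar / ws))
}

#' General slit/shutter confocal weight
#'
#' Numeric evaluation of the sweep integral for unequal slit width and
#' shutter height: the convolution of rect(.*M/ws) and rect(./hr) in sensor
#' coordinates, peak-normalized to 1. Reduces to \code{triWeight} when
#' \code{ws == hr}; otherwise a trapezoid with plateau half-width
#' \code{|ws - hr|/2} and base half-width \code{(ws + hr)/2}.
#'
#' @param ybar sensor-referred offset(s), um at the conjugate image plane.
#' @param ws slit width, um. @param hr shutter height, um.
#' @param M total magnification (the weight itself is magnification-free
#'   once both windows are referred to the image plane; M only scales the
#'   internal integration variable).
#' @export
confocalWeight <- function(ybar, ws, hr = ws, M = 1) {
  if (ws <= 0 || hr <= 0 || M <= 0) stop("ws, hr and M must be positive")
  # overlap length of two rects of widths ws and hr at centre offset ybar,
  # normalized by the peak overlap min(ws, hr)
  lo <- pmax(-ws / 2, ybar - hr / 2)
  hi <- pmin(ws / 2, ybar + hr / 2)
  pmax(0, hi - lo) / min(ws, hr)
}

#' Apply the confocal modulation to a spatial-angular PSF
#'
#' Multiplies hp by \code{tri(ybar/ws)} (default mode, the |v| << ws
#' simplification) or by \code{tri((ybar + v_um)/ws)} (\code{exactOffset}
#' mode, keeping the view's sensor-row offset v expressed in image-plane
#' micrometres). The modulation is uniform along xbar.
#'
#' @param psf an unmodulated \code{SpatialAngularPSF}.
#' @param confocal a \code{ConfocalConfig} (its \code{slitWidth} is used).
#' @param exactOffset keep the per-view row offset instead of neglecting it.
#' @return a modulated \code{SpatialAngularPSF}.
#' @export
applyConfocal <- function(psf, confocal, exactOffset = FALSE) {
  stopifnot(is(psf, "SpatialAngularPSF"), is(confocal, "ConfocalConfig"))
  if (psf@modulated)
    stop("PSF is already confocal-modulated; refusing double modulation")
  ws <- confocal@slitWidth
  cfg <- psf@config
  nV <- cfg@nViews
  c0 <- (nV + 1L) / 2L
  hp <- psf@hp
  for (vi in seq_len(nV)) {
    vUm <- if (exactOffset) (vi - c0) * cfg@mlaPitch / nV else 0
    w <- triWeight(psf@fineCoords + vUm, ws)
    hp[, , vi, , ] <- hp[, , vi, , , drop = FALSE] * w
  }
  new("SpatialAngularPSF", hp = hp, fineCoords = psf@fineCoords,
      depths = psf@depths, config = cfg, modulated = TRUE, slitWidth = ws)
}

#' Airy unit at the conjugate image plane
#'
#' \code{1.22 * lambda * M / NA} for the whole objective aperture
#' (\code{mode = "full"}), or with the sub-aperture NA after pupil
#' segmentation by the MLA (\code{mode = "sub"}), taking one microlens pitch
#' to subtend 1/nViews of the pupil diameter (\code{NA_sub = NA * kappa /
#' nViews}, kappa = 1 by default).
#'
#' @param config an \code{OpticalConfig}.
#' @param mode "full" or "sub".
#' @param kappa pupil-segmentation scale factor for the sub-aperture NA.
#' @return Airy-unit diameter in micrometres at the conjugate image plane.
#' @export
airyUnit <- function(config, mode = c("full", "sub"), kappa = 1) {
  mode <- match.arg(mode)
  lam <- config@wavelength * 1e-3
  M <- magnification(config)
  naEff <- switch(mode, full = config@na,
                  sub = config@na * kappa / config@nViews)
  1.22 * lam * M / naEff
}

#' Logical mask of views inside the pupil disk
#'
#' The MLA segments the objective pupil into nViews x nViews sub-apertures;
#' views whose centre lies outside the pupil disk carry only diffraction
#' leakage and are excluded from energy analyses and reconstruction weighting
#' (the standard sLFM view subset).
#'
#' @param config an \code{OpticalConfig}.
#' @param radius inclusion radius in view-index units; default inscribes the
#'   pupil with half a view of tolerance.
#' @return logical matrix [v, u].
#' @export
viewMask <- function(config, radius = (config@nViews - 1) / 2 + 0.5) {
  c0 <- (config@nViews - 1) / 2
  idx <- seq_len(config@nViews) - 1 - c0
  outer(idx, idx, function(v, u) sqrt(u^2 + v^2) <= radius)
}

#' Normalized per-view PSF energies under confocal modulation
#'
#' For each view u = (u, v) the reference energy E0(u) is the in-focus
#' unmodulated PSF energy; the normalized energy Ebar'(pz, u, ws) is the
#' modulated energy at each depth divided by E0(u). Ebar' quantifies the
#' background suppression: it decays with |pz|, faster for larger |v|.
#'
#' @param psf an unmodulated \code{SpatialAngularPSF}.
#' @param confocal a \code{ConfocalConfig}.
#' @param exactOffset passed to \code{applyConfocal}.
#' @param truncationWarn warn if the in-focus PSF support appears truncated
#'   (border energy above this fraction of the total).
#' @return an \code{EnergyMap}.
#' @export
normalizedEnergyMap <- function(psf, confocal, exactOffset = FALSE,
                                truncationWarn = 0.01) {
  stopifnot(is(psf, "SpatialAngularPSF"))
  if (psf@modulated) stop("supply the unmodulated PSF")
  d <- dim(psf@hp)
  nz <- d[5]; nV <- d[3]
  izRef <- which.min(abs(psf@depths))
  e0 <- apply(psf@hp[, , , , izRef, drop = FALSE], c(3, 4), sum)
  border <- sum(psf@hp[c(1, d[1]), , , , izRef]) + sum(psf@hp[, c(1, d[2]), , , izRef])
  if (border > truncationWarn * sum(psf@hp[, , , , izRef]))
    warning("PSF support appears truncated: >", 100 * truncationWarn,
            "% of in-focus energy on the border")
  mod <- applyConfocal(psf, confocal, exactOffset = exactOffset)
  ebar <- array(0, c(nz, nV, nV))
  for (iz in seq_len(nz))
    ebar[iz, , ] <- apply(mod@hp[, , , , iz, drop = FALSE], c(3, 4), sum) / e0
  new("EnergyMap", ebar = ebar, e0 = e0, depths = psf@depths,
      slitWidth = confocal@slitWidth)
}

#' Photon efficiency of the confocal modulation
#'
#' Ratio of total collected energy with and without the confocal modulation
#' for emitters uniformly distributed over a depth window (the "same fixed
#' cell within the DOF" scenario).
#'
#' @param psfUnmod,psfMod unmodulated and modulated \code{SpatialAngularPSF}
#'   on identical grids.
#' @param zWindow depth window c(zmin, zmax), um; must lie within the PSF
#'   depth list.
#' @return fraction in [0, 1].
#' @export
photonEfficiency <- function(psfUnmod, psfMod, zWindow = c(-2, 2)) {
  stopifnot(is(psfUnmod, "SpatialAngularPSF"), is(psfMod, "SpatialAngularPSF"))
  if (!isTRUE(all.equal(psfUnmod@depths, psfMod@depths)) ||
      !isTRUE(all.equal(psfUnmod@fineCoords, psfMod@fineCoords)))
    stop("PSFs must share identical depth and spatial grids")
  inWin <- psfUnmod@depths >= zWindow[1] - 1e-9 & psfUnmod@depths <= zWindow[2] + 1e-9
  if (!any(inWin)) stop("z window lies outside the PSF depth list")
  if (zWindow[1] < min(psfUnmod@depths) - 1e-9 ||
      zWindow[2] > max(psfUnmod@depths) + 1e-9)
    stop("z window extends beyond the PSF depth list")
  eU <- sum(psfUnmod@hp[, , , , inWin])
  eM <- sum(psfMod@hp[, , , , inWin])
  eM / eU
}

#' Axial coverage profile of a PSF
#'
#' Per-depth total energy, plus an operational half-energy depth-of-field
#' summary: the depth range over which the energy stays above a threshold
#' fraction (default 50%) of the in-focus value, measured by linear
#' interpolation between depth samples.
#'
#' @param psf a \code{SpatialAngularPSF} (modulated or not).
#' @param threshold energy fraction defining the coverage width.
#' @return list with \code{profile} (data.frame pz, energy) and
#'   \code{halfEnergyWidth} (um; Inf when the profile never falls below the
#'   threshold inside the sampled range).
#' @export
axialCoverageProfile <- function(psf, threshold = 0.5) {
  stopifnot(is(psf, "SpatialAngularPSF"))
  e <- apply(psf@hp, 5, sum)
  pz <- psf@depths
  o <- order(pz); pz <- pz[o]; e <- e[o]
  izRef <- which.min(abs(pz))
  level <- threshold * e[izRef]
  crossing <- function(idx) {   # walk outwards from focus until below level
    for (i in idx) if (e[i] < level) {
      j <- if (i < izRef) i + 1L else i - 1L
      return(pz[j] + (pz[i] - pz[j]) * (e[j] - level) / (e[j] - e[i]))
    }
    NA_real_
  }
  lo <- if (izRef > 1) crossing((izRef - 1):1) else NA_real_
  hi <- if (izRef < length(pz)) crossing((izRef + 1):length(pz)) else NA_real_
  width <- if (is.na(lo) || is.na(hi)) Inf else hi - lo
  list(profile = data.frame(pz = pz, energy = e), halfEnergyWidth = width)
}

#' Confocality design report
#'
#' Collects the slit-design quantities for an instrument configuration:
#' Airy units, slit size in AU, pixels per microlens, photon efficiency over
#' a depth window, half-energy axial coverage and the normalized-energy
#' decay curves.
#'
#' @param optical an \code{OpticalConfig}.
#' @param confocal a \code{ConfocalConfig}.
#' @param psf optional precomputed unmodulated \code{SpatialAngularPSF}; when
#'   NULL the energy-based entries are computed from a PSF built with the
#'   given sampling parameters.
#' @param depths,nLens,osf PSF sampling used when \code{psf} is NULL.
#' @param zWindow photon-efficiency depth window, um.
#' @return a list (JSON-serializable) with keys \code{au_full_um},
#'   \code{au_sub_um}, \code{slit_au}, \code{px_per_lens},
#'   \code{photon_efficiency}, \code{axial_halfenergy_um} and
#'   \code{energy_map} (per-depth central-view Ebar').
#' @export
designReport <- function(optical, confocal, psf = NULL,
                         depths = seq(-7.5, 7.5, by = 0.5), nLens = 5L,
                         osf = 3L, zWindow = c(-2, 2)) {
  auF <- airyUnit(optical, "full")
  auS <- airyUnit(optical, "sub")
  rep <- list(
    au_full_um = auF,
    au_sub_um = auS,
    slit_au = confocal@slitWidth / auF,
    px_per_lens = pixelsPerLens(optical)
  )
  if (is.null(psf)) psf <- computePsf(optical, depths, nLens = nLens, osf = osf)
  mod <- applyConfocal(psf, confocal)
  rep$photon_efficiency <- photonEfficiency(psf, mod, zWindow)
  rep$axial_halfenergy_um <- axialCoverageProfile(mod)$halfEnergyWidth
  em <- normalizedEnergyMap(psf, confocal)
  c0 <- (dim(em@ebar)[2] + 1L) / 2L
  rep$energy_map <- data.frame(pz = em@depths, ebar_central = em@ebar[, c0, c0])
  rep
}
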