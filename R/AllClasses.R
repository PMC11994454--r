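# S4 containers for the csLFM computational stack.
#
# Coordinate conventions used throughout:
#   * object space in micrometres, z = 0 at the native focal plane,
#     positive z toward the objective;
#   * "MLA-plane" micrometres are conjugate-image-plane coordinates at the
#     microlens array, i.e. object micrometres times the total magnification
#     M = magObjective * magRelay. The relay between MLA and camera is folded
#     in by expressing the sensor pixel at the MLA plane as mlaPitch/nViews;
#   * ybar is the camera-row / illumination-scan direction; view indices
#     (u, v) are integers centred at 0, v along ybar;
#   * arrays are column-major with the y (row) axis first.

#' Optical configuration of a (confocal) scanning light-field microscope
#'
#' Instrument geometry of objective, microlens array (MLA) and camera. The
#' relay between the MLA and the sensor is implied by the constraint that one
#' microlens covers exactly \code{nViews} camera pixels, so the sensor pixel
#' referred to the MLA plane is \code{mlaPitch/nViews}.
#'
#' @slot na objective numerical aperture.
#' @slot magObjective objective magnification.
#' @slot magRelay relay magnification between native image plane and MLA.
#' @slot wavelength emission wavelength in nm.
#' @slot refrIndex immersion refractive index.
#' @slot mlaPitch microlens pitch in micrometres.
#' @slot mlaFocal microlens focal length in micrometres.
#' @slot pixelSize physical sensor pixel in micrometres.
#' @slot nViews angular resolution per axis (odd).
#' @slot scanSteps scan lattice size s (s x s phases over one pitch; s = 1
#'   reproduces unscanned cLFM sampling).
#' @export
setClass("OpticalConfig", representation(
  na = "numeric", magObjective = "numeric", magRelay = "numeric",
  wavelength = "numeric", refrIndex = "numeric",
  mlaPitch = "numeric", mlaFocal = "numeric", pixelSize = "numeric",
  nViews = "integer", scanSteps = "integer"
))

setValidity("OpticalConfig", function(object) {
  msg <- character(0)
  if (object@na <= 0) msg <- c(msg, "na must be positive")
  if (object@na > object@refrIndex)
    msg <- c(msg, "na cannot exceed the immersion refractive index")
  if (object@magObjective * object@magRelay <= 0)
    msg <- c(msg, "total magnification must be positive")
  if (object@nViews %% 2L != 1L) msg <- c(msg, "nViews must be odd")
  if (object@scanSteps < 1L) msg <- c(msg, "scanSteps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn OpticalConfig constructor.
#' @param na,magObjective,magRelay,wavelength,refrIndex,mlaPitch,mlaFocal,pixelSize,nViews,scanSteps
#'   see slots.
#' @export
OpticalConfig <- function(na, magObjective, magRelay = 1, wavelength = 525,
                          refrIndex = 1.515, mlaPitch = 100, mlaFocal = 2100,
                          pixelSize = 6.5, nViews = 13L, scanSteps = 3L) {
  new("OpticalConfig", na = na, magObjective = magObjective,
      magRelay = magRelay, wavelength = wavelength, refrIndex = refrIndex,
      mlaPitch = mlaPitch, mlaFocal = mlaFocal, pixelSize = pixelSize,
      nViews = as.integer(nViews), scanSteps = as.integer(scanSteps))
}

#' Total magnification of the system
#' @param config an \code{OpticalConfig}.
#' @export
magnification <- function(config) config@magObjective * config@magRelay

#' Relay magnification between MLA and sensor implied by the pixel fit
#' @inheritParams magnification
#' @export
sensorRelay <- function(config) config@nViews * config@pixelSize / config@mlaPitch

#' Camera pixels covered by one microlens
#' @inheritParams magnification
#' @export
pixelsPerLens <- function(config)
  as.integer(round(config@mlaPitch * sensorRelay(config) / config@pixelSize))

#' Fine spatial-grid step after s-step scanning, object-referred micrometres
#' @inheritParams magnification
#' @export
fineStep <- function(config) config@mlaPitch / (config@scanSteps * magnification(config))

setMethod("show", "OpticalConfig", function(object) {
  cat(sprintf("OpticalConfig: NA %.2f, M %.1fx (%.0fx obj x %.3g relay), lambda %g nm\n",
              object@na, magnification(object), object@magObjective,
              object@magRelay, object@wavelength))
  cat(sprintf("  MLA pitch %g um (f %g um), %d x %d views, pixel %g um, scan %d x %d\n",
              object@mlaPitch, object@mlaFocal, object@nViews, object@nViews,
              object@pixelSize, object@scanSteps, object@scanSteps))
})

#' Line-confocal illumination / rolling-shutter configuration
#'
#' @slot slitWidth illumination slit width at the conjugate image plane, um.
#' @slot shutterHeight rolling-shutter active window height at the sensor,
#'   expressed at the conjugate image plane, um.
#' @slot illumAxialExtent axial range (object um) over which the elongated
#'   illumination sheet is treated as uniform.
#' @export
setClass("ConfocalConfig", representation(
  slitWidth = "numeric", shutterHeight = "numeric", illumAxialExtent = "numeric"
))

setValidity("ConfocalConfig", function(object) {
  msg <- character(0)
  if (object@slitWidth <= 0) msg <- c(msg, "slitWidth must be positive")
  if (object@shutterHeight <= 0) msg <- c(msg, "shutterHeight must be positive")
  if (object@illumAxialExtent <= 0) msg <- c(msg, "illumAxialExtent must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn ConfocalConfig constructor; by design the slit width defaults
#'   to the rolling-shutter height (the conjugate slit/shutter condition).
#' @param slitWidth,shutterHeight,illumAxialExtent see slots.
#' @export
ConfocalConfig <- function(slitWidth, shutterHeight = slitWidth,
                           illumAxialExtent = 15) {
  new("ConfocalConfig", slitWidth = slitWidth, shutterHeight = shutterHeight,
      illumAxialExtent = illumAxialExtent)
}

setMethod("show", "ConfocalConfig", function(object) {
  cat(sprintf("ConfocalConfig: slit %g um, shutter %g um, illumination extent %g um (axial)\n",
              object@slitWidth, object@shutterHeight, object@illumAxialExtent))
})

#' Complex scalar field at the native image plane
#'
#' Debye field of an isotropic point emitter, sampled at the MLA plane for a
#' list of defocus depths. The grid is commensurate with the microlens /
#' pixel lattice and carries one extra pitch of margin on the low side so
#' scan phases are integer-sample shifts.
#'
#' @slot field complex array [y, x, z].
#' @slot yCoords,xCoords sample coordinates, MLA-plane um.
#' @slot step grid step, MLA-plane um.
#' @slot depths defocus list, object um.
#' @slot config the generating \code{OpticalConfig}.
#' @slot nLens lateral support in microlens pitches.
#' @slot osf samples per sensor pixel.
#' @export
setClass("NativeField", representation(
  field = "array", yCoords = "numeric", xCoords = "numeric", step = "numeric",
  depths = "numeric", config = "OpticalConfig", nLens = "integer",
  osf = "integer"
))

setValidity("NativeField", function(object) {
  cfg <- object@config
  nyq <- cfg@wavelength * 1e-3 * magnification(cfg) / (4 * cfg@na)
  if (object@step > nyq + 1e-9)
    return(sprintf("grid step %.3g um coarser than Nyquist bound %.3g um", object@step, nyq))
  if (!all(is.finite(Mod(object@field)))) return("field contains non-finite values")
  TRUE
})

setMethod("show", "NativeField", function(object) {
  d <- dim(object@field)
  cat(sprintf("NativeField: %d x %d samples (step %.3g um at MLA plane), %d depth(s) [%g..%g um]\n",
              d[1], d[2], object@step, length(object@depths),
              min(object@depths), max(object@depths)))
})

#' Sensor-plane light-field PSF
#'
#' Nonnegative intensity indexed [row, col, phase_y, phase_x, z] where the
#' scan phase is the emitter's lateral position modulo one microlens pitch.
#' Normalized so the in-focus pattern sums to 1.
#'
#' @slot hs 5-D intensity array.
#' @slot pixCoords sensor pixel-centre coordinates at the MLA plane, um.
#' @slot depths object-space depths, um.
#' @slot config generating \code{OpticalConfig}.
#' @slot nLens lateral support in pitches.
#' @export
setClass("SensorPSF", representation(
  hs = "array", pixCoords = "numeric", depths = "numeric",
  config = "OpticalConfig", nLens = "integer"
))

setValidity("SensorPSF", function(object) {
  if (length(dim(object@hs)) != 5L) return("hs must be a 5-D array")
  if (min(object@hs) < -1e-12) return("hs must be nonnegative")
  TRUE
})

setMethod("show", "SensorPSF", function(object) {
  d <- dim(object@hs)
  cat(sprintf("SensorPSF: %d x %d sensor pixels, %d x %d scan phases, %d depths\n",
              d[1], d[2], d[3], d[4], d[5]))
})

#' Spatial-angular (phase-space) PSF
#'
#' Pixel-realigned PSF hp indexed [ybar, xbar, v, u, z] on the fine spatial
#' grid (pitch/s), optionally carrying the triangle confocal modulation.
#'
#' @slot hp 5-D nonnegative intensity array [ybar, xbar, v, u, z].
#' @slot fineCoords fine-grid coordinates, MLA-plane um (ybar = xbar axis).
#' @slot depths object-space depths, um.
#' @slot config generating \code{OpticalConfig}.
#' @slot modulated logical; TRUE after confocal modulation.
#' @slot slitWidth modulation slit width (um at the image plane), NA when
#'   unmodulated.
#' @export
setClass("SpatialAngularPSF", representation(
  hp = "array", fineCoords = "numeric", depths = "numeric",
  config = "OpticalConfig", modulated = "logical", slitWidth = "numeric"
))

setValidity("SpatialAngularPSF", function(object) {
  d <- dim(object@hp)
  if (length(d) != 5L) return("hp must be a 5-D array [ybar, xbar, v, u, z]")
  if (min(object@hp) < -1e-12) return("hp must be nonnegative")
  if (d[3] != d[4]) return("view grid must be square")
  if (d[1] != length(object@fineCoords)) return("fineCoords length mismatch")
  if (d[5] != length(object@depths)) return("depth list mismatch")
  TRUE
})

setMethod("show", "SpatialAngularPSF", function(object) {
  d <- dim(object@hp)
  cat(sprintf("SpatialAngularPSF: %d x %d views, %d x %d fine grid, %d depths; %s\n",
              d[3], d[4], d[1], d[2], d[5],
              if (object@modulated) sprintf("confocal-modulated (ws = %g um)", object@slitWidth)
              else "unmodulated"))
})

#' Is a spatial-angular PSF confocal-modulated?
#' @param psf a \code{SpatialAngularPSF}.
#' @export
isModulated <- function(psf) psf@modulated

#' Depth list of a PSF or volume
#' @param x a \code{SpatialAngularPSF}, \code{SensorPSF} or \code{VolumeGrid}.
#' @export
depthsUm <- function(x) {
  if (is(x, "VolumeGrid")) return(x@zCoords)
  x@depths
}

#' 3-D intensity volume on a regular grid
#'
#' @slot data nonnegative array [y, x, z], photons per voxel.
#' @slot voxel voxel size c(dy, dx, dz), um.
#' @slot zCoords z coordinate of each slice, object um.
#' @export
setClass("VolumeGrid", representation(
  data = "array", voxel = "numeric", zCoords = "numeric"
))

setValidity("VolumeGrid", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be [y, x, z]")
  if (min(object@data) < 0) return("intensity must be nonnegative")
  if (any(object@voxel <= 0)) return("voxel size must be positive")
  if (dim(object@data)[3] != length(object@zCoords)) return("zCoords mismatch")
  TRUE
})

#' @describeIn VolumeGrid constructor.
#' @param data,voxel,zCoords see slots; \code{zCoords} defaults to a grid
#'   centred on the focal plane.
#' @export
VolumeGrid <- function(data, voxel, zCoords = NULL) {
  if (is.null(zCoords)) {
    nz <- dim(data)[3]
    zCoords <- (seq_len(nz) - (nz + 1) / 2) * voxel[3]
  }
  new("VolumeGrid", data = data, voxel = voxel, zCoords = zCoords)
}

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeGrid: %d x %d x %d voxels of %.3g x %.3g x %.3g um, total %.4g photons\n",
              d[1], d[2], d[3], object@voxel[1], object@voxel[2], object@voxel[3],
              sum(object@data)))
})

#' Raw rolling-shutter scan sequence
#'
#' One sensor frame per periodic scan position, with the scan-phase lattice
#' and acquisition mode recorded.
#'
#' @slot frames array [row, col, phase], photons; phase index runs x-fastest
#'   over the s x s lattice: phase = ky * s + kx + 1.
#' @slot s scan lattice size.
#' @slot mode "sLFM" or "csLFM".
#' @slot config generating \code{OpticalConfig}.
#' @slot confocal \code{ConfocalConfig} used (csLFM) or NULL.
#' @slot sweepSteps number of illumination-line positions integrated per frame.
#' @export
setClass("RawScanSequence", representation(
  frames = "array", s = "integer", mode = "character",
  config = "OpticalConfig", confocal = "ANY", sweepSteps = "integer"
))

setValidity("RawScanSequence", function(object) {
  if (length(dim(object@frames)) != 3L) return("frames must be [row, col, phase]")
  if (dim(object@frames)[3] != object@s^2)
    return("number of frames must equal s^2 scan phases")
  if (min(object@frames) < 0) return("frames must be nonnegative")
  if (!object@mode %in% c("sLFM", "csLFM")) return("mode must be sLFM or csLFM")
  TRUE
})

setMethod("show", "RawScanSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("RawScanSequence (%s): %d frames of %d x %d pixels (s = %d)\n",
              object@mode, d[3], d[1], d[2], object@s))
})

#' Pixel-realigned multi-view stack
#'
#' Angular views on the fine (pitch/s) spatial grid.
#'
#' @slot views array [y, x, v, u], photons.
#' @slot fineCoords fine-grid coordinates, MLA-plane um.
#' @slot config generating \code{OpticalConfig}.
#' @slot mode provenance mode string.
#' @slot provenance free-form list (noise applied, upsampled, ...).
#' @export
setClass("MultiViewStack", representation(
  views = "array", fineCoords = "numeric", config = "OpticalConfig",
  mode = "character", provenance = "list"
))

setValidity("MultiViewStack", function(object) {
  d <- dim(object@views)
  if (length(d) != 4L) return("views must be [y, x, v, u]")
  if (min(object@views) < -1e-9) return("views must be nonnegative")
  if (d[3] != d[4]) return("view grid must be square")
  TRUE
})

setMethod("show", "MultiViewStack", function(object) {
  d <- dim(object@views)
  cat(sprintf("MultiViewStack (%s): %d x %d views of %d x %d samples\n",
              object@mode, d[3], d[4], d[1], d[2]))
})

#' Extract one angular view
#' @param stack a \code{MultiViewStack}.
#' @param u,v integer view indices centred at 0.
#' @export
getView <- function(stack, u, v) {
  c0 <- (dim(stack@views)[3] + 1L) / 2L
  stack@views[, , v + c0, u + c0]
}

#' Per-view rigid displacement map (simplified digital adaptive optics)
#'
#' @slot dy,dx matrices [v, u] of lateral displacements, object um.
#' @slot maxShift configured magnitude bound, um.
#' @export
setClass("ShiftMap", representation(
  dy = "matrix", dx = "matrix", maxShift = "numeric"
))

setValidity("ShiftMap", function(object) {
  c0 <- (nrow(object@dy) + 1L) / 2L
  if (abs(object@dy[c0, c0]) > 1e-12 || abs(object@dx[c0, c0]) > 1e-12)
    return("shift of the central (reference) view must be zero")
  if (max(abs(c(object@dy, object@dx))) > object@maxShift + 1e-9)
    return("shift magnitude exceeds the configured maximum")
  TRUE
})

setMethod("show", "ShiftMap", function(object) {
  cat(sprintf("ShiftMap: %d x %d views, max |shift| %.3g um (bound %g um)\n",
              nrow(object@dy), ncol(object@dy),
              max(abs(c(object@dy, object@dx))), object@maxShift))
})

#' Result of iterative tomography
#'
#' @slot volume reconstructed \code{VolumeGrid}.
#' @slot iterations iterations run.
#' @slot fidelity per-iteration Poisson data-fidelity values.
#' @slot shifts \code{ShiftMap} used or NULL.
#' @slot psfInfo provenance list (modulated flag, ws_um, n views).
#' @export
setClass("ReconResult", representation(
  volume = "VolumeGrid", iterations = "integer", fidelity = "numeric",
  shifts = "ANY", psfInfo = "list"
))

setMethod("show", "ReconResult", function(object) {
  cat(sprintf("ReconResult: %d iterations, PSF %s\n", object@iterations,
              if (isTRUE(object@psfInfo$modulated))
                sprintf("modulated (ws_um = %g)", object@psfInfo$ws_um)
              else "unmodulated"))
  show(object@volume)
})

#' Normalized PSF energy map over depth and view
#'
#' @slot ebar array [z, v, u] of normalized energies E'/E0.
#' @slot e0 matrix [v, u] of reference (in-focus, unmodulated) energies.
#' @slot depths depth list, um.
#' @slot slitWidth slit width used, um.
#' @export
setClass("EnergyMap", representation(
  ebar = "array", e0 = "matrix", depths = "numeric", slitWidth = "numeric"
))

setMethod("show", "EnergyMap", function(object) {
  cat(sprintf("EnergyMap: %d depths x %d x %d views, slit %g um\n",
              dim(object@ebar)[1], dim(object@ebar)[2], dim(object@ebar)[3],
              object@slitWidth))
})

#' Set of fluorescence time traces
#'
#' @slot f fluorescence matrix [roi, t].
#' @slot frameInterval frame interval, s.
#' @slot stimulus character vector of per-frame stimulus labels (direction in
#'   degrees as character, or "blank"), or length 0 when absent.
#' @export
setClass("TraceSet", representation(
  f = "matrix", frameInterval = "numeric", stimulus = "character"
))

setValidity("TraceSet", function(object) {
  if (object@frameInterval <= 0) return("frameInterval must be positive")
  if (length(object@stimulus) && length(object@stimulus) != ncol(object@f))
    return("stimulus schedule length must match the number of frames")
  TRUE
})

#' @describeIn TraceSet constructor.
#' @param f,frameInterval,stimulus see slots.
#' @export
TraceSet <- function(f, frameInterval, stimulus = character(0)) {
  new("TraceSet", f = as.matrix(f), frameInterval = frameInterval,
      stimulus = as.character(stimulus))
}

#' Time-mean baseline F0 per ROI (always recomputed)
#' @param traces a \code{TraceSet}.
#' @export
baselineF0 <- function(traces) rowMeans(traces@f)

setMethod("show", "TraceSet", function(object) {
  cat(sprintf("TraceSet: %d ROI(s) x %d frames at %.4g s/frame%s\n",
              nrow(object@f), ncol(object@f), object@frameInterval,
              if (length(object@stimulus)) " (stimulus schedule attached)" else ""))
})

#' Orientation-tuning analysis result
#'
#' @slot responses matrix [roi, direction] of mean dF/F0 during stimulation.
#' @slot directions stimulus directions, degrees.
#' @slot r visual-response ratio per ROI (stim mean / blank mean).
#' @slot rPref,rOrth preferred and mean-orthogonal responses.
#' @slot osi orientation selectivity index per ROI.
#' @slot responsive logical, R > 3.
#' @slot highOsiFraction fraction of responsive ROIs with OSI > 0.8.
#' @export
setClass("TuningResult", representation(
  responses = "matrix", directions = "numeric", r = "numeric",
  rPref = "numeric", rOrth = "numeric", osi = "numeric",
  responsive = "logical", highOsiFraction = "numeric"
))

setMethod("show", "TuningResult", function(object) {
  cat(sprintf("TuningResult: %d ROI(s), %d responsive (R > 3), %.0f%% of responsive with OSI > 0.8\n",
              nrow(object@responses), sum(object@responsive),
              100 * object@highOsiFraction))
})
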