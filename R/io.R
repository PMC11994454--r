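# Readers/writers and configuration files. Images travel as multi-page
# 32-bit float TIFF with a JSON sidecar (<file>.json) carrying the intensity
# scale and grid metadata; instrument configs are YAML; reports are JSON.

sidecarPath <- function(path) paste0(path, ".json")

writePagesTiff <- function(pages, path, meta) {
  mx <- max(vapply(pages, max, numeric(1)), 0)
  # power-of-two scale: scaling to [0,1] and back is then exact in binary
  # floating point, so a write/read cycle is idempotent on float32 data
  scale <- if (mx > 0) 2^ceiling(log2(mx)) else 1
  tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                  bits.per.sample = 32L, compression = "none", reduce = FALSE)
  meta$intensity_scale <- scale
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

readPagesTiff <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("not a readable TIFF image: ", path))
  meta <- if (file.exists(sidecarPath(path)))
    jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE) else list()
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  list(pages = lapply(pages, function(p) p * scale), meta = meta)
}

#' Write a volume to a multi-page float TIFF (+ JSON sidecar)
#'
#' @param volume a \code{VolumeGrid}.
#' @param path output .tif path; the sidecar \code{<path>.json} stores voxel
#'   size, z coordinates and the intensity scale.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "VolumeGrid"))
  pages <- lapply(seq_len(dim(volume@data)[3]), function(iz) volume@data[, , iz])
  writePagesTiff(pages, path,
                 list(kind = "VolumeGrid", axes = "ZYX",
                      voxel_um = volume@voxel, z_um = volume@zCoords))
}

#' Read a volume from TIFF
#'
#' @param path .tif path.
#' @param voxel voxel size c(dy, dx, dz) um; required when the file has no
#'   JSON sidecar with grid metadata.
#' @return a \code{VolumeGrid}.
#' @export
readVolume <- function(path, voxel = NULL) {
  r <- readPagesTiff(path)
  if (is.null(voxel)) {
    if (is.null(r$meta$voxel_um))
      stop("no voxel-size metadata; pass voxel = c(dy, dx, dz) explicitly")
    voxel <- as.numeric(r$meta$voxel_um)
  }
  dat <- array(0, c(dim(r$pages[[1]]), length(r$pages)))
  for (iz in seq_along(r$pages)) dat[, , iz] <- r$pages[[iz]]
  z <- if (!is.null(r$meta$z_um)) as.numeric(r$meta$z_um) else NULL
  VolumeGrid(dat, voxel, zCoords = z)
}

#' Store a spatial-angular PSF
#'
#' Pages are the (z, v, u) kernel planes in z-major order; the sidecar keeps
#' the grids, the \code{ws_um} attribute (absent for an unmodulated PSF) and
#' the generating configuration.
#'
#' @param psf a \code{SpatialAngularPSF}.
#' @param path output .tif path.
#' @export
psfStore <- function(psf, path) {
  stopifnot(is(psf, "SpatialAngularPSF"))
  d <- dim(psf@hp)
  pages <- vector("list", d[3] * d[4] * d[5])
  i <- 0L
  for (iz in seq_len(d[5])) for (vi in seq_len(d[3])) for (ui in seq_len(d[4])) {
    i <- i + 1L
    pages[[i]] <- psf@hp[, , vi, ui, iz]
  }
  meta <- list(kind = "SpatialAngularPSF",
               n_views = d[3], n_z = d[5],
               fine_um = psf@fineCoords, z_um = psf@depths,
               config_json = configAsList(psf@config))
  if (psf@modulated) meta$ws_um <- psf@slitWidth
  writePagesTiff(pages, path, meta)
}

#' Load a spatial-angular PSF stored by \code{psfStore}
#'
#' A missing \code{ws_um} attribute is treated as "unmodulated" and
#' messaged.
#'
#' @param path .tif path.
#' @return a \code{SpatialAngularPSF}.
#' @export
psfLoad <- function(path) {
  r <- readPagesTiff(path)
  m <- r$meta
  if (is.null(m$kind) || m$kind != "SpatialAngularPSF")
    stop("file does not hold a stored spatial-angular PSF")
  nV <- m$n_views; nz <- m$n_z
  nF <- length(m$fine_um)
  hp <- array(0, c(nF, nF, nV, nV, nz))
  i <- 0L
  for (iz in seq_len(nz)) for (vi in seq_len(nV)) for (ui in seq_len(nV)) {
    i <- i + 1L
    hp[, , vi, ui, iz] <- r$pages[[i]]
  }
  hp[hp < 0] <- 0
  modulated <- !is.null(m$ws_um)
  if (!modulated) message("no ws_um attribute; treating PSF as unmodulated")
  new("SpatialAngularPSF", hp = hp, fineCoords = as.numeric(m$fine_um),
      depths = as.numeric(m$z_um), config = configFromList(m$config_json),
      modulated = modulated,
      slitWidth = if (modulated) m$ws_um else NA_real_)
}

configAsList <- function(config) {
  list(na = config@na, mag_objective = config@magObjective,
       mag_relay = config@magRelay, wavelength_nm = config@wavelength,
       refr_index = config@refrIndex, mla_pitch_um = config@mlaPitch,
       mla_focal_um = config@mlaFocal, pixel_size_um = config@pixelSize,
       n_views = config@nViews, scan = list(s = config@scanSteps))
}

configFromList <- function(x) {
  need <- c("na", "mag_objective", "mag_relay", "wavelength_nm", "refr_index",
            "mla_pitch_um", "mla_focal_um", "pixel_size_um", "n_views")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("optics config is missing keys: ", paste(miss, collapse = ", "))
  s <- if (!is.null(x$scan$s)) x$scan$s else 1L
  OpticalConfig(na = x$na, magObjective = x$mag_objective,
                magRelay = x$mag_relay, wavelength = x$wavelength_nm,
                refrIndex = x$refr_index, mlaPitch = x$mla_pitch_um,
                mlaFocal = x$mla_focal_um, pixelSize = x$pixel_size_um,
                nViews = x$n_views, scanSteps = s)
}

#' Read an optics configuration from YAML
#'
#' Keys: \code{na, mag_objective, mag_relay, wavelength_nm, refr_index,
#' mla_pitch_um, mla_focal_um, pixel_size_um, n_views, scan: \{s\}}.
#'
#' @param path YAML file.
#' @return an \code{OpticalConfig}.
#' @export
readOpticsConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  configFromList(yaml::read_yaml(path))
}

#' Write an optics configuration to YAML
#' @param config an \code{OpticalConfig}. @param path output path.
#' @export
writeOpticsConfig <- function(config, path) {
  yaml::write_yaml(configAsList(config), path)
  invisible(path)
}
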