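# Synthetic specimen generator. The phantoms emulate the study's test
# samples: sub-resolution fluorescent beads suspended in a weakly scattering
# slab (intralipid/agarose mimic, modelled as distributed background
# emitters), dense neurite-like tube meshes, and neuron populations with
# stimulus-locked calcium transients (see traces.R for the time series).

#' Specification of a synthetic phantom
#'
#' @slot kind "beads", "neurites", "slab_background" or "composite".
#' @slot dims volume size c(ny, nx, nz), voxels.
#' @slot voxel voxel size c(dy, dx, dz), um.
#' @slot beadRadius bead radius, um.
#' @slot beadDensity beads per um^3.
#' @slot beadBrightness photons per bead voxel at full coverage.
#' @slot slabThickness background slab thickness, um (centred on z = 0).
#' @slot slabDensity background emitters per um^3.
#' @slot slabBrightness photons per background emitter (relative brightness).
#' @slot nNeurites number of neurite tubes.
#' @slot neuriteRadius tube radius, um.
#' @slot offset autofluorescence offset, photons per voxel.
#' @slot seed integer seed; the same spec always renders the same volume.
#' @export
setClass("PhantomSpec", representation(
  kind = "character", dims = "integer", voxel = "numeric",
  beadRadius = "numeric", beadDensity = "numeric", beadBrightness = "numeric",
  slabThickness = "numeric", slabDensity = "numeric", slabBrightness = "numeric",
  nNeurites = "integer", neuriteRadius = "numeric",
  offset = "numeric", seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("beads", "neurites", "slab_background", "composite"))
    msg <- c(msg, "unknown phantom kind")
  if (any(object@voxel <= 0)) msg <- c(msg, "voxel size must be positive")
  if (object@beadDensity < 0 || object@slabDensity < 0)
    msg <- c(msg, "densities must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' @describeIn PhantomSpec constructor with study-condition defaults: 0.5-um
#'   beads (radius 0.25 um) at the dilute density of the bead/intralipid
#'   phantom, in a volume whose scale is set by \code{dims * voxel}.
#' @param kind,dims,voxel,beadRadius,beadDensity,beadBrightness,slabThickness,slabDensity,slabBrightness,nNeurites,neuriteRadius,offset,seed
#'   see slots.
#' @export
PhantomSpec <- function(kind = "beads", dims = c(64L, 64L, 9L),
                        voxel = c(0.5, 0.5, 0.5), beadRadius = 0.25,
                        beadDensity = 5e-4, beadBrightness = 1000,
                        slabThickness = 40, slabDensity = 2e-3,
                        slabBrightness = 50, nNeurites = 6L,
                        neuriteRadius = 0.4, offset = 0, seed = 1L) {
  new("PhantomSpec", kind = kind, dims = as.integer(dims), voxel = voxel,
      beadRadius = beadRadius, beadDensity = beadDensity,
      beadBrightness = beadBrightness, slabThickness = slabThickness,
      slabDensity = slabDensity, slabBrightness = slabBrightness,
      nNeurites = as.integer(nNeurites), neuriteRadius = neuriteRadius,
      offset = offset, seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec '%s': %d x %d x %d voxels of %g x %g x %g um (seed %d)\n",
              object@kind, object@dims[1], object@dims[2], object@dims[3],
              object@voxel[1], object@voxel[2], object@voxel[3], object@seed))
})

# rasterize a sphere with partial-voxel antialiasing (sub-voxel sampling)
rasterSphere <- function(vol, centre, radius, voxel, value, sub = 3L) {
  d <- dim(vol)
  rv <- radius / voxel
  lo <- pmax(1L, floor(centre - rv - 1))
  hi <- pmin(d, ceiling(centre + rv + 1))
  if (any(lo > hi)) return(vol)
  off <- (seq_len(sub) - (sub + 1) / 2) / sub
  for (iz in lo[3]:hi[3]) for (ix in lo[2]:hi[2]) for (iy in lo[1]:hi[1]) {
    dy <- (iy - centre[1] + off) * voxel[1]
    dx <- (ix - centre[2] + off) * voxel[2]
    dz <- (iz - centre[3] + off) * voxel[3]
    r2 <- outer(outer(dy^2, dx^2, "+"), dz^2, "+")
    cov <- mean(r2 <= radius^2)
    if (cov > 0) vol[iy, ix, iz] <- vol[iy, ix, iz] + value * cov
  }
  vol
}

#' Render a synthetic phantom volume
#'
#' Beads are rasterized as antialiased spheres with Poisson-distributed
#' count at the specified density; the scattering slab is modelled as
#' uniform-density random single-voxel emitters over its thickness; neurites
#' as smoothed random-walk tubes. Fully deterministic under the seed carried by the specification object.
#'
#' @param spec a \code{PhantomSpec}.
#' @return a \code{VolumeGrid} (z centred on the focal plane).
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  d <- spec@dims; vx <- spec@voxel
  if (spec@kind %in% c("beads", "composite") && spec@beadRadius < min(vx) / 2)
    warning("bead radius below half a voxel; beads render as single voxels")
  vol <- array(0, d)
  nBeads <- 0L
  withSeed(spec@seed, {
    if (spec@kind %in% c("beads", "composite")) {
      vUm3 <- prod(d * vx)
      nB <- rpois(1, spec@beadDensity * vUm3)
      nBeads <- nB
      for (i in seq_len(nB)) {
        ctr <- c(runif(1, 1, d[1]), runif(1, 1, d[2]), runif(1, 1, d[3]))
        vol <- rasterSphere(vol, ctr, spec@beadRadius, vx, spec@beadBrightness)
      }
    }
    if (spec@kind %in% c("slab_background", "composite")) {
      zC <- (seq_len(d[3]) - (d[3] + 1) / 2) * vx[3]
      inSlab <- which(abs(zC) <= spec@slabThickness / 2)
      if (length(inSlab)) {
        vUm3 <- prod(d[1:2] * vx[1:2]) * length(inSlab) * vx[3]
        nE <- rpois(1, spec@slabDensity * vUm3)
        iy <- sample.int(d[1], nE, replace = TRUE)
        ix <- sample.int(d[2], nE, replace = TRUE)
        iz <- sample(inSlab, nE, replace = TRUE)
        for (i in seq_len(nE))
          vol[iy[i], ix[i], iz[i]] <- vol[iy[i], ix[i], iz[i]] + spec@slabBrightness
      }
    }
    if (spec@kind %in% c("neurites", "composite")) {
      for (t in seq_len(spec@nNeurites)) {
        pos <- c(runif(1, 1, d[1]), runif(1, 1, d[2]), runif(1, 1, d[3]))
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        nStep <- 4L * max(d)
        for (st in seq_len(nStep)) {
          dir <- dir + 0.25 * rnorm(3); dir <- dir / sqrt(sum(dir^2))
          pos <- pos + dir * 0.75
          if (any(pos < 1) || any(pos > d)) break
          vol <- rasterSphere(vol, pos, spec@neuriteRadius, vx, 100, sub = 2L)
        }
      }
    }
  })
  vol <- vol + spec@offset
  attr(vol, "nBeads") <- nBeads   # realized bead count, for density checks
  VolumeGrid(vol, vx)
}
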