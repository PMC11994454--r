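# cslfm

Simulation, design analysis and 3D reconstruction for **confocal scanning
light-field microscopy (csLFM)** — a scanning light-field microscope (sLFM)
whose camera rolling shutter is synchronized with an axially elongated
line-confocal illumination, so that out-of-volume background fluorescence is
rejected optically while the extended depth of field of light-field
detection is preserved.

The package is aimed at microscope builders and computational imaging
researchers who want to (i) model the csLFM point-spread function and design
the confocality parameters (slit width, shutter height) for a given
objective/MLA/camera geometry, and (ii) simulate and reconstruct csLFM
acquisitions end to end on synthetic phantoms.

## The model

A point emitter at lateral position **p** and defocus `p_z` produces a
scalar Debye field at the native image plane, which the microlens array
(pitch `d_l`, focal length `f_ulens`) samples into a sensor-plane
light-field PSF `hs(p, x~)`. Pixel realignment — a lossless reindexing of
(microlens, pixel, scan phase) — turns this into the spatial-angular PSF
`hp(x̄, u)` on a fine spatial grid with views `u = (u, v)`.

Sweeping an illumination line of width `w_s` synchronously with a
rolling-shutter window of height `h_r` multiplies each view row by the
convolution of the two windows in the scan coordinate; with the conjugate
choice `w_s = h_r` this is the unit triangle, giving the csLFM PSF

    hp'(x̄, u, p_z; w_s) = hp(x̄, u, p_z) · tri(ȳ / w_s),

uniform along `x̄`. Per-view energies `Ē'(p_z, u) = E'(p_z, u) / E_0(u)`
quantify background suppression: they decay with |p_z|, faster for larger
|v|. Slit sizes are expressed in Airy units, `AU = 1.22·λ·M/NA` at the
conjugate image plane. Reconstruction is multi-view Richardson–Lucy
iterative tomography with the (modulated) spatial-angular PSF, optionally
preceded by simplified digital adaptive optics (per-view rigid disparity
estimation by phase correlation against the reconstruction's forward
projections).

## Worked example

```r
library(cslfm)

optics <- readOpticsConfig(system.file("extdata/optics_inverted.yaml",
                                       package = "cslfm"))
optics
#> OpticalConfig: NA 1.40, M 63.0x (63x obj x 1 relay), lambda 525 nm
#>   MLA pitch 100 um (f 2100 um), 13 x 13 views, pixel 6.5 um, scan 3 x 3

cat("Airy unit:", round(airyUnit(optics, "full"), 1), "um;  325-um slit =",
    round(325 / airyUnit(optics, "full"), 1), "AU;  pixels per lens:",
    pixelsPerLens(optics), "\n")
#> Airy unit: 28.8 um;  325-um slit = 11.3 AU;  pixels per lens: 13

psf   <- computePsf(optics, depths = seq(-2, 2, by = 0.5), nLens = 15L)
slit  <- ConfocalConfig(slitWidth = 11 * airyUnit(optics, "full"))
csPsf <- applyConfocal(psf, slit)
cat("photon efficiency within +/-2 um:",
    round(100 * photonEfficiency(psf, csPsf, c(-2, 2)), 1), "%\n")
#> photon efficiency within +/-2 um: 81.8 %
```

The first numbers reproduce the instrument design: the 325-µm optical slit
of the 63×/1.4 system is ~11 Airy units at the conjugate image plane, and
one microlens covers exactly 13 × 13 camera pixels (100 µm × 0.845 relay /
6.5 µm). The last line is the design trade-off the 11-AU choice optimizes:
emitters within the cell-scale ±2 µm depth window still deliver ~82% of the
photons an unmodulated sLFM acquisition would collect, while deep background
is rejected.

A full synthetic acquisition–reconstruction cycle:

```r
cfg <- readOpticsConfig(system.file("extdata/optics_test.yaml", package = "cslfm"))
psf <- computePsf(cfg, depths = c(-0.5, 0, 0.5))
vol <- generatePhantom(PhantomSpec("beads", dims = c(15, 15, 3),
                                   voxel = c(fineStep(cfg), fineStep(cfg), 0.5),
                                   beadDensity = 0.8, seed = 7))
scan  <- simulateRawScan(vol, psf, ConfocalConfig(slitWidth = 40), mode = "csLFM")
views <- pixelRealign(scan)
rec   <- reconstructPipeline(views, applyConfocal(psf, ConfocalConfig(slitWidth = 40)),
                             nIter = 30)
rec@volume
#> VolumeGrid: 15 x 15 x 3 voxels of 0.086 x 0.086 x 0.5 um, total 8.848e+04 photons
```

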