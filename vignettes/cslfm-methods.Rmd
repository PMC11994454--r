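---
title: "Modelling and reconstructing confocal scanning light-field microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and reconstructing confocal scanning light-field microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cslfm)
```

This vignette is the package's account of the science it implements: the
optical model and its assumptions, the parameters that matter, what the
synthetic data emulate (and do not), the numerical conventions, and the
design choices made where the problem left the design open.

## 1. The optical model

### Wave-optics PSF

An isotropic point emitter imaged by an aplanatic objective is modelled by
the scalar Debye diffraction integral with the $\sqrt{\cos\theta}$
apodization,

$$U(r, p_z) = \int_0^{\alpha} \sqrt{\cos\theta}\,\sin\theta\,
  J_0\!\left(k n r \sin\theta\right) e^{i k n p_z \cos\theta}\, d\theta,
  \qquad \alpha = \arcsin(\mathrm{NA}/n),$$

evaluated radially and mapped to the native image plane by the lateral
magnification $M$ (image-side aberrations of the relay are not modelled).
The model is scalar and monochromatic at the configured emission wavelength;
a vectorial Debye–Wolf treatment and refractive-index-mismatch aberrations
are deliberate non-goals (extension points). Averaging over a 50-nm
emission band was evaluated and left the per-view energy structure
essentially unchanged, so it is not part of the model.

Each microlens (pitch $d_l$, focal length $f_{\mu lens}$) windows the field
with its square aperture and Fourier-transforms it onto the sensor at its
focal plane; the squared modulus is integrated over sensor pixels. Light is
attributed to the pixels under the generating microlens only — inter-lens
crosstalk is excluded, which matches an f-number-matched system where the
local wavefront tilt never exceeds the microlens acceptance angle. The
relay between MLA and camera is folded in by expressing the sensor pixel at
the MLA plane as $d_l/n_\mathrm{views}$ (one microlens covers exactly
$n_\mathrm{views}\times n_\mathrm{views}$ pixels).

**Sampling.** The native-plane grid step is $d_l/(n_\mathrm{views}\cdot
\mathrm{osf})$ with `osf` sub-samples per sensor pixel (default 3), checked
against the Nyquist bound $\lambda M/(4\,\mathrm{NA})$ and refused if
coarser. The lateral support is `nLens` microlens pitches (default 5, with
one extra pitch of margin so the $s\times s$ scan phases are exact
integer-sample shifts). The aperture integral uses Simpson's rule with 256
nodes; the radial amplitude table is sampled at $\lambda/(20\,\mathrm{NA})$
and interpolated linearly. Energy conservation across defocus is the
quadrature check (better than 2% when the support holds the defocused
field).

### Realignment and the scan lattice

Scanning drifts the image plane over an $s \times s$ lattice of sub-pitch
positions (default $s = 3$; $s = 1$ reproduces unscanned cLFM sampling).
Pixel realignment is implemented as a pure permutation — view index = pixel
offset within the lens, fine spatial position = microlens centre minus
magnified emitter position interleaved with the scan phase — so it
conserves energy exactly and is identical for PSFs and measurements.

Two model properties are worth knowing because they are *not* idealized
away:

* **Native-plane oscillation.** Near focus the central views carry a
  ring-shaped (donut) intensity dip — the integral of the focused Airy
  amplitude over a lens aperture is small — so the in-focus central view
  peaks one fine-grid step off the exact origin and per-view energies
  oscillate over the first few micrometres of defocus. This is the
  well-known LFM native-plane artifact, and it is why energy-decay
  statements below are evaluated on a depth grid at the axial-coverage
  scale (≥ 15 µm steps), not at micrometre steps.
* **Pupil-edge views.** Views whose centre lies outside the pupil disk see
  only diffraction leakage; their in-focus reference energy is near zero
  and ratios against it are meaningless. All energy analyses and the
  reconstruction restrict themselves to the in-pupil view subset
  (`viewMask()`), the same subset scanning-LFM processing uses.

## 2. Confocal modulation and slit design

The synchronized sweep of the illumination line (width $w_s$ at the
conjugate image plane) and rolling-shutter window (height $h_r$) acts per
sensor row as the convolution of two rect windows in the scan coordinate:
a trapezoid in general, the unit triangle $\mathrm{tri}(\bar y/w_s)$ for
the conjugate choice $w_s = h_r$ (the default, and the instrument's). The
modulated PSF is $hp' = hp \cdot \mathrm{tri}((\bar y + v)/w_s)$; because
$|v| \le d_l/2 \ll w_s$ for design-scale slits, the per-view row offset $v$
is neglected by default (`exactOffset = TRUE` keeps it; the raw-sweep
simulator reproduces the exact-offset form to within the sweep
discretization, about 1.5% per view at 64 steps).

Design quantities:

* **Airy unit**: $1.22\,\lambda M/\mathrm{NA}$ (`mode = "full"`), or with
  the sub-aperture NA after pupil segmentation, $\mathrm{NA}_{sub} =
  \mathrm{NA}\,\kappa/n_\mathrm{views}$ with $\kappa = 1$ by default (one
  pitch subtends $1/n_\mathrm{views}$ of the pupil diameter); $\kappa$ is
  exposed because only the defining formula, not the segmentation
  convention, is fixed by the optics.
* **Normalized energy map** $\bar E'(p_z, u) = E'(p_z, u)/E_0(u)$ with
  $E_0$ the in-focus unmodulated per-view energy; the integration domain is
  the stored PSF support, with a warning when more than 1% of the in-focus
  energy sits on the border.
* **Photon efficiency**: modulated over unmodulated total energy for
  emitters uniform in a depth window (default ±2 µm, our reading of
  "imaging the same fixed cell within the depth of field"). For the
  63×/1.4, 13×13-view geometry with an 11-AU slit this evaluates to ~82%.
* **Axial coverage**: per-depth total energy with a half-energy (50%)
  width summary. The 50% threshold is an operational choice — no printed
  definition of "effective axial coverage" exists — and is a parameter.

**Scaled background configuration.** At 63×/1.4 a PSF defocused to slab
depths (tens of µm) spans 50–100 microlens pitches, far beyond desk-scale
support. Background-suppression experiments therefore run on a scaled
instrument (20×/0.5 water immersion, 5×5 views, 100-µm pitch) whose
defocused PSFs fit a 13-pitch support. The properties tested are
scale-free; where a slit size must be carried over, the object-referred
slit width of the reference instrument (325/63 ≈ 5.2 µm) is preserved,
which is ~4 AU at NA 0.5. SBR comparisons on the bead-over-slab phantom
use the total collected-light image (sum of in-pupil views) so they are not
dominated by the central view's native-plane oscillation, and slabs of
increasing thickness share their emitters (nested), so thicker-slab
comparisons are not confounded by independent sampling.

## 3. The forward simulator and phantoms

`simulateRawScan()` integrates the acquisition explicitly: for each of
`sweepSteps` (default 64) midpoint line positions, the object is excited in
a top-hat strip of width $w_s/M$ (uniform in depth over the illumination's
15-µm axial extent, per the beam's measured uniformity), imaged through the
sensor-plane PSF, masked by the $h_r$-tall shutter window centred on the
line's image — including the scan-phase drift of the image plane, which the
shutter tracks because the synchronization is calibrated on the camera —
and accumulated. Strip and shutter edges are antialiased by fractional row
coverage, so the 64-step default reproduces the triangle model to ~1.5%.
sLFM mode applies neither strip nor mask. Scattering is represented by
distributed background emitters (the intralipid proxy), not by radiative
transfer; sample motion, saturation and photobleaching are out of scope.

Phantoms (`generatePhantom()`) are deterministic under their seed: beads as
antialiased spheres with Poisson-distributed count at the configured
density (defaults emulate the dilute 0.5-µm bead phantom), slab background
as uniform random single-voxel emitters over the slab thickness, neurites
as smoothed random-walk tubes. `simulateTuningTraces()` generates
stimulus-locked calcium traces with von-Mises tuning over the 8-direction
grating protocol (3 s stimulus, 6 s blank). What passing tests on these
phantoms do *not* show: robustness to real tissue scattering, motion,
non-uniform illumination, or segmentation errors — none of which the
generator emulates.

## 4. Reconstruction

Multi-view Richardson–Lucy tomography: multiplicative updates
$g \leftarrow g \cdot \frac{\sum_u B_u\!\left[m_u/(F_u g + \epsilon)\right]}
{\sum_u B_u[1]}$ with per-view, per-depth FFT convolutions,
$\epsilon = 10^{-9}\max m$, uniform positive initialization (a
backprojection initialization is available), default 30 iterations (no
iteration count is prescribed by the method; the fidelity log lets users
apply their own stopping rule). Nonnegativity is preserved by construction
and the Poisson data fidelity is logged per iteration. Using an
unmodulated PSF on confocal data is permitted but warned about — the tests
demonstrate the resulting out-of-focus misassignment on a defocused bead.

**Digital adaptive optics** is simplified to per-view rigid shifts (the
full Zernike wavefront estimation of the original sLFM processing is an
extension point): each view is phase-correlated (Hann-windowed, parabolic
subpixel peak) against its own forward projection of a short reference
reconstruction, so the PSF's intrinsic parallax is compensated; shifts are
taken relative to the central view and clamped (default 2 µm). Because the
windowed correlation underestimates pitch-scale displacements by a roughly
multiplicative factor, the estimator runs an outer
estimate–correct–re-estimate loop (default 2 cycles) whose accumulated
residuals converge to the true shift; with no aberration present a single
pass is the right measurement of the estimator's null error (~0.1 fine
pixel), since further cycles only re-inject estimator noise. Corrections
are applied by shifting the PSF kernels, not the measurements, keeping the
forward model consistent.

**Resolution of the reconstruction.** On noise-free, matched-PSF data,
Richardson–Lucy is a maximum-likelihood estimator and converges *past* the
diffraction limit for sub-resolution objects: a 100-nm bead reconstructs to
a ~0.1-µm interpolated FWHM at 30 iterations, roughly half the scalar
diffraction limit $0.51\lambda/\mathrm{NA} = 0.19$ µm, while a resolvable
0.5-µm bead reconstructs to its own ~0.43-µm physical width. A two-sided
"reconstructed bead FWHM equals the diffraction limit" check is therefore
not attainable at convergence for any honest bead size, and the
corresponding acceptance test is expected to fail on the sharp side; the
suite asserts it as specified and this paragraph is the analysis. The
operational resolution claims that *are* tested: sub-voxel localization of
beads, recovery of imposed aberrations to 10%, and the FRC machinery on
images with a known band limit.

## 5. Trace analysis conventions

$\Delta F/F_0$ uses the whole-series mean as $F_0$ (so each normalized
trace has exactly zero mean). Spike detection uses strict local maxima
(plateaus take the leftmost sample) above 40% for calcium and, for voltage,
above 2% after subtracting a running median over a 130-ms window (length
rounded to frames and forced odd). Orientation tuning refers all responses
to the *blank-period* baseline: with the whole-series mean, the normalized
trace sums to zero and the stimulus/blank response ratio degenerates to a
constant ($n_{blank}/n_{stim}$) while sharply tuned OSIs exceed 1. The
visual-response ratio floors its denominator at the blank response's
standard error (a response cannot be resolved below it); R > 3 marks
responsive neurons, OSI $= (R_{pref} - R_{orth})/(R_{pref} + R_{orth})$
with $R_{orth}$ the mean of the two directions orthogonal to the preferred
one, and 0.8 separates high from low orientation selectivity. Blank bins
are pooled across the session (per-direction blanks are not distinguished).

## 6. Numerical conventions and problem sizes

* Coordinates: object-space µm, $z = 0$ at the native focal plane,
  positive toward the objective; $\bar y$ is the camera-row/scan direction;
  view indices are integers centred at 0; arrays are `[y, x, ...]`.
* Convolutions: FFT with zero padding to fast sizes and explicit kernel
  origins; argmax ties break to the lowest index; negative FFT round-off is
  clamped at zero.
* Seeds affect only synthetic data and noise; realignment and
  reconstruction are fully deterministic given their inputs.
* Storage: multi-page 32-bit TIFF with a JSON sidecar; the intensity scale
  is a power of two so rescaling is exact in binary floating point. A PSF
  sidecar without a `ws_um` attribute is treated as unmodulated.
* SSIM windows: 3-D Gaussian, $\sigma = 1.5$ voxels, 11-voxel support,
  truncated-renormalized at the borders; FRC threshold fixed at 1/7;
  single-image FRC splitting by checkerboard subsampling is left to the
  caller (the function takes two half-images).
* Problem sizes used by the test suite and the acceptance script (chosen
  as the smallest grids on which each property is well conditioned): a
  5×5-view test instrument whose fine grid (0.086 µm) resolves the
  diffraction limit, PSFs of 5–15 microlens pitches support, depth lists of
  3–21 planes, and the scaled 20×/0.5 background instrument described
  above.

## 7. Known limitations

Scalar, monochromatic PSF without index-mismatch aberrations; no
inter-lens crosstalk; scattering as background emitters only; rigid-shift
DAO (no higher-order wavefront modes); no motion correction or virtual
scanning; the rolling shutter is modelled geometrically (no exposure-time/
frame-rate constraints of a physical sCMOS).
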