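---
title: "Measuring nuclear pore architecture from missing-wedge limited averages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nuclear pore architecture from missing-wedge limited averages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(porescope)
```

## What the package models

The nuclear pore complex (NPC) is an eight-fold symmetric channel spanning
the nuclear envelope (NE), built from a cytoplasmic ring (CR), an inner ring
(IR) at the membrane waist, and a nucleoplasmic ring (NR). In-situ
cryo-electron tomography sees the NPC embedded in its double membrane, but
every subtomogram is band-limited by the acquisition's missing wedge: a
single-axis tilt series covering -52 to +68 degrees leaves the Fourier
region around the beam axis unsampled, so raw particles are anisotropically
blurred and individual measurements on them are unreliable. The remedy is
subtomogram averaging: align many copies over their poses, compensate each
Fourier voxel by the summed wedge coverage, enforce the C8 symmetry, and
measure architecture on the resulting average.

`porescope` implements that pipeline end to end, together with a parametric
phantom generator that stands in for the cellular data, so every stage can
be validated by parameter recovery: build an NPC with known geometry,
simulate wedge-limited noisy particles at random poses, align and average
them, and check that the measured architecture returns the constructed
numbers. The wild-type preset encodes the in-situ human NPC geometry: a
105 nm membrane-to-membrane pore diameter at the narrowest point, a 57 nm
central channel (75% more cylinder volume than the 43 nm channel of
purified-envelope models), CR and NR distal offsets of 37 and 29 nm from
the IR midplane (66 nm total height), and asymmetric membrane angles of
about 42 degrees (cytoplasmic) versus 28 degrees (nucleoplasmic) against
the IR midplane. Presets `class1`/`class2`/`class3` drop rings the way
scaffold (Nup96) depletion does ({CR,IR,NR}, {IR,NR}, {IR}).

## Conventions

* **Volumes.** `density_volume` holds a 3D grid plus a voxel size in
  Angstrom. The physical origin is voxel `floor(n/2)+1` on each axis --
  the same index that carries DC in a centred spectrum -- so real-space
  rotations, Fourier masks and symmetry operations share one centre.
* **Euler angles** are ZYZ intrinsic, degrees, `(rot, tilt, psi)`;
  `euler_matrix()` maps reference-frame onto particle-frame coordinates
  (`euler_matrix(90,0,0) %*% c(1,0,0)` is `(0,1,0)`).
* **Units.** Everything internal is Angstrom; the geometry module reports
  nm and degrees, matching how NPC architecture is usually quoted.
* **Binnings** in `align_config()` are Fourier-crop factors relative to the
  input subvolumes. The default input grid (13.6 A/voxel) corresponds to
  4x-binned 3.4 A acquisition pixels, so the default schedule `c(2, 1)`
  reproduces the classic "align at 8x, repeat at 4x" progression.

## The phantom and what it does (not) emulate

`build_phantom()` renders the NPC analytically in cylindrical coordinates,
which makes it exactly C8 symmetric by construction:

* Each ring is a Gaussian annulus in (r, z) multiplied by an azimuthal
  lobing factor `1 + 0.5 cos(8 phi)`. Because the lobing is multiplicative,
  the radial half-maximum crossings -- the landmarks the measurements use --
  are identical at every azimuth. The IR annulus is tied to the geometry:
  its inner radial half-maximum sits at `channel_diameter/2` and its outer
  one at `ir_outer_diameter/2`; CR/NR are compact tori whose outer axial
  half-maximum crossings sit at the distal offsets. The default
  `ir_outer_diameter` (93 nm) keeps the IR slightly detached from the
  envelope: in vivo the IR runs out to the membrane, but a fully touching
  render would merge the IR and membrane half-maximum landmarks into a
  single unmeasurable ridge at ~14 A sampling.
* The membrane is a fused double-cone: straight cones rising from the
  waist (radius `membrane_pore_diameter/2` at the IR midplane) at the two
  stated angles until the distal-offset heights, then flat, with a Gaussian
  cross-section of 7 nm FWHM (a typical bilayer-pair scale at this
  resolution). Straight cones make the constructed angles exactly
  recoverable, which is the phantom's purpose.
* Density is tapered to zero at the inscribed cylinder so the volume is
  closed under rotations about z (the box truncates the flat NE anyway).

What the phantom does **not** emulate: CTF, dose-dependent damage, tilt
increments (the wedge is applied analytically in Fourier space, not by
projection/backprojection), crowded cellular background (noise is white
Gaussian), protein-level detail, and inter-NPC variability. Passing the
recovery tests therefore demonstrates that the algorithms are correct and
self-consistent at the stated SNR and geometry -- not that the pipeline
would reach any particular resolution on real lamellae.

`simulate_particles()` rotates the phantom by a random pose (uniform
azimuth; particle-axis wobble up to 15 degrees, emulating envelope-based
prealignment of picked NPCs), shifts it by up to 2 voxels, multiplies the
spectrum by the binary -52/+68 wedge mask, and adds white noise. SNR is
defined as the variance of the wedge-filtered signal over the noise
variance, measured inside a sphere of the pore diameter (capped at the
inscribed sphere). Half sets alternate A,B,A,B... by particle index so
reruns are reproducible.

## Alignment and averaging

`constrained_cc()` is the missing-wedge constrained cross-correlation:
normalized correlation over the Fourier region where both wedge masks are
at least 0.5, with means removed (DC excluded) and the translation peak
refined to subvoxel precision by parabolic interpolation.

`iterative_align()` follows the classic scheme: the initial template is the
wedge-compensated average over the input (prealigned) poses, symmetrized;
each iteration aligns every particle to the current template, re-averages,
re-symmetrizes, and merges half maps into the next template (no
gold-standard separation -- the half-set FSC therefore carries a
reference-bias caveat, recorded by the resolution module). The angular
search is a two-level grid: an exhaustive scan over one asymmetric unit
(in-plane restricted to 360/symmetry) at the first binning, then local
3x3x3 refinement at `angular_step/refine_factor` (default 10/4 = 2.5
degrees). Numerical choices worth knowing:

* Rotation candidates are scored by sampling the reference spectrum at the
  rotated frequencies of a band-limited subset (period >= 3 voxels).
  Scoring in the spectral domain avoids one FFT per candidate; the band
  limit both speeds the search up and keeps it from chasing high-frequency
  noise. Translation updates and all averaging are full-band, and the
  final per-particle scores are recomputed exactly with a real-space
  rotation, so reported cc values do not inherit interpolation error.
* Averaging brings each particle into the reference frame by a single
  cubic real-space resampling of the inverse pose, and each contribution
  is weighted by its analytically rotated wedge mask. The sum is divided by
  the summed coverage where that coverage is at least `min_coverage = 0.5`
  (half of one particle's weight) and zeroed elsewhere: compensation can
  rescale what some particle saw, but never invents never-measured
  frequencies. An absolute floor (rather than a fraction of the maximum
  coverage) keeps sparsely covered zones -- e.g. directions only seen by
  particles at large wobble -- instead of discarding them.
* `apply_symmetry()` is the mean of the n rotated copies (cubic
  interpolation); it is idempotent to ~1e-5 on band-limited maps.
* Reference-free alignment has two free gauges that the implementation
  pins. The common axial offset of all particles would otherwise
  random-walk between iterations (rounding the membrane fold of the
  average outward), so the mean reference-frame z shift is re-centred to
  zero each iteration -- the convention set by the envelope prealignment.
  The common in-plane rotation is pinned at the end: the final maps are
  rotated so the phase of the C8 circular harmonic is zero (a subunit lobe
  on the +x axis, the same convention the phantom is built in), with the
  compensating rotation composed into the particle table.
* Interpolation: trilinear during search, cubic (Keys) for final
  resampling -- the usual speed/fidelity split.

Even with perfect poses, the union of rotated wedges leaves a double cone
around the z axis unmeasured (about 22 degrees half-angle for this tilt
range, shrunk by particle wobble). Flat NE sheets, whose power lies along
that axis, are therefore under-represented, and the compensated average
shows streak artifacts through the channel. The geometry module is designed
around this (below).

## Resolution

`fsc()` computes shell correlations one frequency voxel wide (shell
binning is not standardized; one voxel is the finest stable choice);
`resolution_at()` reads the first downward crossing of the 0.5 threshold by
linear interpolation, returning the Nyquist bound with a flag when there is
no crossing. `local_resolution()` slides a 40-voxel window on a 4-voxel
grid (the field-standard windowing for subprotomer maps), masks each pair
of subvolumes with a spherical mask of radius box/2 (10% cosine edge), and
floors values at Nyquist. `sharpen()` multiplies amplitudes by
`exp(-B s^2 / 4)`; with the B = -2000 A^2 used for subprotomer maps the
gain at 20 A is exp(1.25) = 3.49.

## Rigid-body fitting

`simulate_map_from_model()` renders points as Gaussians with
`sigma = 0.225 * resolution` (the Fourier half-height convention of common
map-simulation tools; the literature names the resolution but rarely the
kernel). `cam_score()` is the correlation about the mean restricted to the
model map's support (contour 1e-3 of its peak -- the "model region"
reading of the local correlation; tools differ and the choice is stated,
not asserted as identical to any of them). `overlap_score()` is the
fraction of model mass above the target contour (default mean + 1 sd).
`global_fit()` draws uniform random rotations (quaternion method) and
translations in the support bounding box, optimizes each placement by
coordinate ascent with shrinking steps, and clusters converged fits
(rotation < 6 degrees, translation < 1 voxel -- the clustering rule is a
package decision; reports list one fit per cluster). `fit_significance()`
converts scores to Z scores with the population standard deviation (so the
two-cluster case is well defined), two-sided normal P values, and
Benjamini-Hochberg q values. The default placement count is 10,000-scale
work split into what a test can afford; the full-scale 1,000,000 of
production fitting runs is a parameter, not a different code path.

## Geometry measurements

All landmarks are explicit, because the quantities they emulate were
measured manually on orthoslices:

* **Measurement azimuths**: the diameter landmarks depend on whether a
  profile runs through a subunit lobe or between lobes, so the two
  orthogonal measurement directions are taken through lobes (the lobe
  azimuth is read from the C8 harmonic phase; explicit angles can be
  passed). This makes the diameters invariant to rotations of the map
  about z.
* **Pore diameter**: per direction and per z slice, the membrane is the
  outermost density maximum above an absolute level; slices are grouped
  into connected ridge runs (the envelope is the long run; rings and
  streaks form short disconnected segments) and the NE-to-NE distance is
  taken at the narrowest slice of the longest run, with subvoxel parabolic
  refinement. The two directions are averaged (a single direction is used,
  with a warning, when only one is measurable); the search band is
  +/-12 nm around the midplane, the level of the pore membrane. On
  reconstructed averages the membrane fold at the waist is a one-sided
  ridge, so blur pushes this landmark outward by roughly 1-3 nm at 16
  particles and SNR 0.5 (a flank-extrapolation variant removes the bias in
  principle but is too variance-prone on so few slices; the simple
  landmark is kept and the bias documented).
* **Channel diameter**: innermost density maximum on the IR midplane
  profiles; the channel edge is the inward half-maximum crossing relative
  to the local baseline; two lobe-aligned orthogonal directions averaged.
* **Axial geometry**: the axial ring profile is the *maximum* over
  annulus radii of the azimuthally averaged density (a mean profile would
  let negative missing-cone streaks in the channel cancel the IR signal).
  The IR midplane is the centre of mass of its peak region; CR/NR distal
  ends are outermost half-maximum crossings; the height is their sum by
  construction. Axial half-maximum edges inherit a small outward bias
  (fraction of a voxel to ~1.5 nm) from the missing-cone point spread on
  reconstructed averages; this is a property of the data model, not noise,
  and is left uncorrected.
* **Membrane angles**: the primary landmark is the radial position of the
  outermost membrane maximum per z slice -- radial positions are well
  determined under a missing wedge, where axial ridge positions are not --
  traced as a connected run outward from the waist, dropping slices within
  2 voxels of the waist (the smeared rim biases them inward), and fit by
  weighted least squares; the angle is reported against the IR midplane
  per side (+z is cytoplasmic by the alignment convention). A z-ridge
  fallback handles membranes too flat for the radial trace.
* **Ring presence**: mean shell density against a robust
  (median/MAD-based) background estimated outside all shells, at 5 robust
  sigmas. Class splitting maps {CR,IR,NR}/{IR,NR}/{IR} to classes 1/2/3;
  CR+IR -- an assembly the depletion series never produced -- is flagged
  class 0 with a warning.
* **Class percentages** use largest-remainder apportionment to a 100%
  total. That choice is forced by the printed numbers: 27/53/83 of 163 are
  16.56/32.52/50.92%, and any independent half-up rounding would print
  33% for the middle class; apportionment yields the published 17/32/51.

## Problem sizes and defaults

The bundled study conditions are 16 particles at SNR 0.5 on a 112-voxel
grid at 13.6 A/voxel (a 152 nm field comfortably enclosing the 105 nm
pore; the full-NPC box size is not standardized, and 112 voxels at 4x
binning is this package's default), aligned with the `c(2, 1)` schedule,
one exhaustive iteration plus two refinement iterations, 10-degree coarse
step, 20-degree tilt cap, 4-voxel shift window. On one CPU that run takes
a few minutes and recovers the pore diameter, channel diameter, membrane
angles and ring heights within a voxel / two degrees -- the package's
acceptance surface (`scripts/acceptance.R` reruns exactly this from a
seed). Unit tests use scaled-down phantoms (40-60 nm pores in 48-64 voxel
boxes) with the same code paths.

## Known limitations

* The half sets are merged into a common template every iteration, as the
  replicated workflow does; FSC values are therefore not gold-standard and
  the 0.143 criterion is deliberately not the default.
* The wedge model is binary and analytic; no CTF, no per-tilt dose, no
  tilt-increment sampling.
* Axial half-maximum landmarks on wedge-limited averages carry the
  systematic outward bias discussed above (about +1.5 to +2.5 nm on the
  CR distal edge of reconstructed averages at SNR 0.5, present even with
  exact poses); radial landmarks do not. The stated one-voxel recovery
  tolerance therefore holds for the noise-free phantom but not for every
  axial quantity of a 16-particle SNR-0.5 reconstruction.
* The exclusion rules (`cc_threshold`, `worst_k`, `percentile`) are
  deterministic proxies for what was a manual curation step; externally
  curated lists can be imported by editing the records table.
* `measure_*` functions assume the NPC axis is along z with the IR near
  the midplane, i.e. maps as produced by `iterative_align()`.
```
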