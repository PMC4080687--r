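---
title: "Metal artifact reduction by fusing tilted CT reconstructions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metal artifact reduction by fusing tilted CT reconstructions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiltmar)
```

## The method

Metal implants produce streaking ("star") artifacts in CT reconstructions:
beam hardening, photon starvation and related effects corrupt the rays that
cross the implant, and filtered back-projection (FBP) smears the corrupted
data across the slice. The artifacts deteriorate contouring and bias the
Hounsfield units (HU) that quantitative planning relies on.

`tiltmar` implements a purely post-processing remedy: acquire several
reconstructions of the same rigid object *tilted* against one another,
rigidly map every reconstruction back onto one common output mesh, and
fuse them per voxel,

$$\hat x_v \;=\; \operatorname{median}\,\{x_v^{(1)},\dots,x_v^{(n)}\}
\quad\text{or}\quad
\hat x_v \;=\; \tfrac1n\sum_{k} x_v^{(k)} .$$

The key observation is geometric: artifacts are tied to the acquisition
geometry, not to the object. When the object is tilted about an axis lying
*in* the slice plane, the scanner re-slices it — metal of finite extent
enters different slices, and the corrupted regions land in different
places of the co-registered volumes. A voxel is then typically corrupted
in only a minority of the scans, and the per-voxel median restores the
clean value, while the mean merely dilutes the artifact by $1/n$. Nothing
about the method requires raw sinogram access or priors, which is what
distinguishes it from the sinogram in-painting family (LI-/BI-/NMAR,
FSMAR) that the package also provides as baselines.

Co-registration uses the known tilt angles (rotation matrices) plus an
optional sub-voxel translation refinement, and pull-based tri-linear
resampling: each output voxel center is mapped through the inverse rigid
transform into the source scan and interpolated from the 8 surrounding
voxels. Pull-based sampling is mathematically equivalent to the push-based
description for rigid maps but cannot leave holes. Output voxels whose
source coordinate leaves the scanned field of view are tracked in a
coverage mask and excluded from fusion and from metrics, never zero-filled
(zero filling would bleed air into the median).

## Evaluation measures

For a region of $n$ voxels with known true value $c$ (11 HU for the
Solid Water phantom material, $-1000$ HU for air):

* **bias** $= \bar x - c$ — net shift of the average grey value;
* **error** $= \frac1n\sum_i |x_i - c|$ — average per-voxel deviation;
* **noise** — sample standard deviation ($n-1$ denominator).

Always `error >= |bias|`, and for a region that is truly constant, noise
measures the stochastic part alone. The standard regions are a ring around
the metal insert (defaults: radii 0.8/1.6 cm over a 0.7 cm slab, about
4200 voxels at (0.1 cm)^3 — consistent with the radius reading of the
reference protocol's 8/16 mm figures and its stated voxel count) and an axis-aligned
box for air cavities. ROI membership is a voxel-center test without
partial-volume weighting. Metrics refuse uncovered voxels rather than
silently shrinking their support.

## The simulator and what it emulates

No scanner data ships with the package; a CT simulator stands in for it.
It is built to reproduce the statistical structure the fusion method
exploits, not to be dosimetrically accurate:

* **Geometry** — 2D parallel-beam acquisition of each slice (the physical
  scanner is fan-beam; the method is geometry-agnostic, so the simpler
  geometry is a deliberate simplification), stacked into 3D volumes.
  Tilts about the vertical axis re-slice the phantom: every scanner slice
  is the oblique cross-section of the tilted object, rasterized
  analytically from the phantom's shape description.
* **Polychromatic Beer–Lambert** — per ray, material path lengths are
  accumulated and the detected intensity is
  $I = N_0 \sum_b w_b \exp(-\sum_m \mu_m(E_b) L_m)$ over the tube
  spectrum (default three bins at 60/80/100 keV, weights 0.30/0.45/0.25 —
  the minimal spectral structure that produces beam hardening). Material
  tables are smooth monotone diagnostic-range values; titanium is anchored
  at the tabulated 0.405 cm²/g at 80 keV (with density 4.59 g/cm³,
  1.86 cm⁻¹, under 1 % transmission through 3 cm).
* **Dose and noise** — the tube current–time product (mAs) is the dose
  proxy; the photon budget per detector bin is
  $N_0 = \text{mAs} \times \text{photonsPerMAs}$ and Poisson counts are
  drawn per ray from one explicit seed per scan and slice (bit-identical
  reruns). `photonsPerMAs = 750` is calibrated once so that a metal-free
  full-dose (200 mAs) scan shows ≈70 HU of ring noise, i.e. ≈197 HU at
  1/8th dose — the noise levels the method is specified to operate at.
* **Photon starvation** — detected counts are floored at 1 (configurable)
  before the log transform. Behind 3 cm of titanium only a handful of
  photons survive, so the clamp and the Poisson fluctuations dominate the
  affected rays; FBP turns them into the bright/dark streaks radiating
  from the insert.
* **Scanner output conventions** — measured projections are linearized
  against the water beam-hardening curve (the standard water calibration;
  without it every oblique section carries a path-length-dependent HU
  offset), reconstructions are calibrated to HU via water's attenuation at
  the 80 keV reference energy, and the output is floored at $-1000$ HU
  because air is the digital zero of the stored image. The floor matters
  for artifact statistics: dark streaks clip, bright streaks do not, so
  streaked regions carry the net positive bias that is reported for real
  scans.
* **Phantoms** — a Gammex-like disc (33 cm Solid Water, 3 cm inserts on a
  10 cm ring: solid titanium, bone, soft tissue, air, water; 5 cm tall)
  and a dental phantom (bone/soft-tissue head section, air-filled mouth
  cavity, six disjoint metal restorations of ~1.5 cm extent along the
  slice axis). Phantoms are analytic shape lists, so tilted re-slicing is
  exact rather than resampled.

What the simulator does **not** model: scatter, detector cross-talk,
fan/cone geometry, helical acquisition, absorption edges (gold's K edge),
real bowtie filtration, or the vendor's adaptive filtering. Passing tests
therefore demonstrate that the implementation realizes the method and
that the method behaves as reported *under these physics*; they are not
evidence about any particular scanner.

## Choices made where the design was open

* **Titanium insert geometry.** The reference protocol's evaluation ring (radii
  8/16 mm, ≈4200 voxels over 7 mm) and a solid 3 cm titanium insert are
  mutually inconsistent — the ring would lie inside the metal. The
  attenuation arithmetic (<1 % transmission through 3 cm) requires the
  solid insert, so the default phantom uses it, `ringRoi` keeps the
  8/16 mm radii as its standalone defaults, and the shipped Gammex
  experiment evaluates a ring of the same 8 mm width scaled outward to
  radii 20/28 mm so that it lies in Solid Water as the evaluation assumes.
* **Tilt sets.** The physical six-position phantom protocol mixes two
  mountings with repeated nominal angles; the simulator's analogue uses
  six distinct, evenly spread tilts 0°, 30°, …, 150° about the vertical
  axis (`inst/extdata/configs/gammex.yaml`). The dose experiment uses the
  protocol's eight angles (0°, ±22.5°, ±45°, ±67.5°, +90°) at 1/8th dose
  each, and the dental experiment its nine (0°, ±22.5°, ±45°,
  ±67.5°, ±90°).
* **Even-count median** is the midpoint of the two central order
  statistics (keeps the estimator unbiased for symmetric noise).
* **Uniform weighting** across scans (a `weights` hook exists for the
  mean but defaults to uniform).
* **Registration** takes rotations as known (they are set on the
  turntable / in the config) and refines only the translation, by
  normalized cross-correlation on a 0.1-voxel grid within ±0.5 voxel —
  the automated stand-in for by-eye sub-voxel alignment.
  Non-rigid registration is out of scope (it did not help on rigid
  objects).
* **MAR baselines.** The virtual sinogram maps HU back to attenuation
  (negatives clipped to zero) and forward-projects with 360 views. The
  metal threshold is 2000 HU; the trace is any ray whose projected mask
  value is positive. "Gaussian radius r" is read as a Gaussian standard
  deviation of r pixels. NMAR's prior classes are air < −500 HU ≤ soft
  tissue < 500 HU ≤ bone, metal replaced by the soft-tissue value; FSMAR
  uses NMAR as its in-painting base, suppresses metal in the original
  image before the frequency split (otherwise the multi-thousand-HU metal
  leaks a negative halo into the high band), and re-inserts the original
  metal voxels afterwards, as all the baselines do (without re-insertion
  the implant itself is destroyed). BI-MAR's description in the literature is
  qualitative; the implementation uses inverse-distance weighting over
  the four axis-nearest untraced bins and is documented as this package's
  reading, not the original authors' exact variant.

## Numerical and degenerate-input conventions

* Voxel indices are 0-based with the coordinate at the voxel *center*;
  grids are axis-aligned in the laboratory frame; everything is in cm.
* HU values are floating point everywhere in memory; integer stored
  values and rescale slope/intercept exist only at the DICOM boundary
  (slope 1 / intercept −1000 whenever the range fits 16 bit, so air is
  stored as 0; uncovered voxels serialize as air — DICOM has no mask
  channel).
* Fractional source indices within 1e−9 of a lattice point snap onto it,
  so lattice-preserving transforms (identity, quarter turns) are exact
  permutations; interpolation corners with weight exactly zero are not
  part of the stencil or the coverage test.
* Line integrals of noisy acquisitions may dip below zero (counts can
  fluctuate above $N_0$); clipping them at zero would add an
  object-size-dependent positive DC bias, so only noiseless and virtual
  sinograms are guaranteed non-negative.
* Ray integrals use marching with a step of 0.25–0.5 pixel
  (nearest-neighbour for label images, bilinear for grey images), which
  keeps chord errors within the ±2–3 % discretization envelope the tests
  assert.
* Degenerate inputs error loudly: overlapping phantom inserts, fully
  traced sinogram rows, constant overlap in the NCC search, uncovered
  ROI voxels, mixed DICOM series, duplicate or missing slice positions.

## Problem sizes

The shipped experiments simulate 256² slices (0.13 cm pixels, 240 views,
363 detector bins) with scanner slabs auto-sized per tilt (roughly 10–30
slices of 0.2 cm), fused on a common mesh with 0.1 cm slice pitch; the
unit tests use 48–160 pixel analogues of the same geometry. These sizes
were chosen so a complete experiment (six to nine scans, registration,
fusion, metrics) runs in minutes on one core while the ring ROI still
contains several hundred voxels per slice; they are the package's
standing definition of the "standard simulated" experiments that the
acceptance checks re-run.

## Known limitations

* The fusion method's gains depend on artifact complementarity: a ROI
  hugging a metal body that is tall along the tilt axis stays close to
  metal in *every* re-sliced scan, and the deterministic near-metal halo
  then survives the median. The dental case (compact
  metal) is the favourable regime; a full-height insert is the hard one.
* Under the package's physics (parallel beam, no scatter, no vendor
  post-processing) the ring-averaged artifact field of an untilted
  full-dose scan integrates to nearly zero HU — bright and dark streaks
  cancel in the mean — even when the per-voxel error is hundreds of HU.
  Clinical scanners instead show large positive ring-average biases
  around metal, driven by asymmetric mechanisms (scatter, vendor
  corrections) outside this simulator. Consequently the error and noise
  reductions of the fusion method reproduce here, but large *bias*
  reductions do not: there is no large single-scan bias to remove. The
  shipped checks report this honestly rather than emulating it with
  non-physical terms.
* Simulated HU of metals follows from the attenuation tables
  (titanium ≈ 9100 HU at 80 keV) and is deliberately not matched to the
  ~2790 HU a clinical scanner effectively assigns titanium — a rendering detail, not a
  contract.
* The virtual-sinogram baselines inherit the known weakness that the
  forward/back projection pair introduces new high-frequency artifacts;
  metric improvement, not artifact-freeness, is the tested contract.
* 12-bit stored-value saturation is modelled only as the lower air floor;
  the upper clamp is the 16-bit DICOM range.
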