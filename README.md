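# tiltmar

Metal implants — dental restorations, hip prostheses, surgical clips —
produce streaking ("star") artifacts in CT reconstructions. The corrupted
Hounsfield units (HU) complicate contouring and bias quantitative
radiotherapy planning. `tiltmar` implements a post-processing remedy that
needs no raw sinogram data and no prior: scan the same rigid object
several times, *tilted* between acquisitions, rigidly co-register the
reconstructions onto one output mesh with tri-linear resampling, and fuse
them per voxel

```
x̂_v = median{ x_v^(1), …, x_v^(n) }     (or the mean)
```

Because artifacts follow the acquisition geometry rather than the object,
a tilted scan carries them in different places; each voxel is corrupted in
only a minority of the co-registered scans and the median restores the
clean value. The package is aimed at medical-physics researchers who want
to study or prototype this fusion method and compare it against the
classical sinogram-domain baselines.

It contains:

* **Volumes and DICOM I/O** — an S4 `CTVolume` class (HU values, spacing,
  origin, coverage mask) with a minimal DICOM CT series reader/writer
  (Explicit VR Little Endian, rescale slope/intercept honored exactly).
* **A CT simulator** — digital Gammex-like and dental phantoms, parallel
  -beam polychromatic forward projection with beam hardening,
  photon-starvation clamping and dose-dependent Poisson noise, water-
  calibrated filtered back-projection, and tilted-series acquisition that
  re-slices the phantom obliquely per tilt.
* **Registration and fusion** — rigid transforms, pull-based tri-linear
  resampling with conservative coverage, NCC sub-voxel translation
  refinement, per-voxel mean/median combination and incremental series.
* **Evaluation metrics** — bias / error / noise in HU over ring and box
  regions of interest.
* **MAR baselines** — LI-MAR, BI-MAR, NMAR and FSMAR operating on virtual
  sinograms, with metal segmentation at 2000 HU and metal re-insertion.
* **An experiment driver** — YAML configs (`inst/extdata/configs/`) that
  fully determine a run, the `cmdSimulate`/`cmdPipeline` functions, and a
  thin CLI (`inst/scripts/tiltmar`).

## Worked example

Simulate six tilted scans of the Gammex-like phantom with a titanium
insert, co-register, fuse, and evaluate the ring of Solid Water around
the insert (true value 11 HU):

```r
library(tiltmar)

cfg <- readExperimentConfig(system.file("extdata/configs/gammex.yaml",
                                        package = "tiltmar"))
res <- runPipeline(cfg, runSimulation(cfg))
subset(res$report, k == 6 | method == "single",
       select = c(method, k, bias, error, noise))
```

With the shipped configuration (seed 1) this prints:

```
   method k       bias     error     noise
1  single 1 -0.3722561 286.28257 366.08157
2  single 2 -2.3800513  83.64936 108.69499
3  single 3 25.6051167  57.19376  85.23830
4  single 4 38.3364884  53.98366  87.19165
5  single 5 22.9743129  59.32008  86.87374
6  single 6  2.5466658  88.61883 115.29094
12 median 6 15.7649258  34.78498  45.52816
18   mean 6 14.4517127  58.06881  71.13943
```

Reading the table: the untilted scan (row 1) has an average per-voxel
error of ~286 HU in the ring — severe streaking. Tilted scans carry their
artifacts elsewhere, and the per-voxel median of all six (row `median 6`)
cuts the error to ~35 HU — a 67 % reduction against the single-scan
average of ~105 HU and close to the noise floor of the fused stack —
while the mean only dilutes the streaks (~58 HU). A single MAR baseline comparison on one slice:

```r
rec <- fbpReconstruct(forwardProject(makeGammexPhantom()),
                      outSpacing = 0.13, outDim = 256)
corrected <- runMar(rec, "nmar")
```

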