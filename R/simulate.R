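#' Construct an acquisition configuration
#'
#' The tube current-time product (mAs) is the dose proxy: the unattenuated
#' photon budget per detector bin is `N0 = mAs * photonsPerMAs` and scales
#' linearly with mAs. The default of 200 mAs stands for the full-dose
#' head-and-neck protocol; split-dose experiments divide it by the number
#' of scans. `photonsPerMAs` is the scanner sensitivity constant; its
#' default is calibrated so that a full-dose metal-free acquisition of the
#' Gammex phantom shows about 70 HU of noise in the standard evaluation
#' ring, i.e. about 197 HU at 1/8th dose (the noise levels the method is
#' meant to operate at).
#'
#' @param mAs tube current-time product; `Inf` for a noiseless acquisition.
#' @param photonsPerMAs unattenuated photons per detector bin per mAs.
#' @param nAngles projections over the half turn.
#' @param nDetectors detector bins.
#' @param detSpacing detector pitch in cm.
#' @param noiseSeed integer seed for the Poisson noise.
#' @param countsFloor floor applied to detected counts before the log
#'   (photon-starvation clamp).
#' @return an [AcquisitionConfig-class].
#' @export
acquisitionConfig <- function(mAs = 200, photonsPerMAs = 750,
                              nAngles = 240L, nDetectors = 363L,
                              detSpacing = 0.13, noiseSeed = 1L,
                              countsFloor = 1) {
  new("AcquisitionConfig", mAs = mAs, photonsPerMAs = photonsPerMAs,
      nAngles = as.integer(nAngles), nDetectors = as.integer(nDetectors),
      detSpacing = detSpacing, noiseSeed = as.integer(noiseSeed),
      countsFloor = countsFloor)
}

# Evaluate code with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Default projection angles: nAngles views evenly covering [0, 180).
projectionAngleSet <- function(nAngles)
  seq(0, 180, length.out = nAngles + 1L)[seq_len(nAngles)]

#' Forward-project a phantom (polychromatic Beer-Lambert)
#'
#' Parallel-beam acquisition of one phantom slice. Per ray, the pathlength
#' through each material is accumulated, the detected intensity is
#' `I = N0 * sum_b w_b * exp(-sum_m mu_m(E_b) * L_m)`, Poisson counts are
#' drawn when `N0` is finite, counts are floored at `countsFloor` before
#' the log transform (this clamp is what turns photon starvation behind
#' metal into streaks), and the recorded line integral is `log(N0 / I)`
#' (which may dip below zero by Poisson fluctuation, as on a calibrated
#' detector).
#'
#' @param p a [PhantomImage-class].
#' @param angles projection angles in degrees; default
#'   `projectionAngleSet(cfg@nAngles)`. Must span at least 180 degrees.
#' @param spect a [Spectrum-class]; default [defaultSpectrum()].
#' @param cfg an [AcquisitionConfig-class].
#' @param stepFrac ray-marching step as a fraction of the pixel size.
#' @return a [Sinogram-class].
#' @export
forwardProject <- function(p, angles = NULL, spect = defaultSpectrum(),
                           cfg = acquisitionConfig(), stepFrac = 0.25) {
  if (is.null(angles)) angles <- projectionAngleSet(cfg@nAngles)
  n0 <- cfg@mAs * cfg@photonsPerMAs
  if (is.na(n0) || n0 <= 0) stop("photon budget N0 must be positive")
  nm <- length(p@materials)
  L <- cpp_radon_labels(p@labels, nm, p@spacing, angles * pi / 180,
                        cfg@nDetectors, cfg@detSpacing, stepFrac)
  # mu[m, b]: linear attenuation of material m in energy bin b
  mu <- vapply(spect@energies,
               function(e) vapply(p@materials, linearAttenuation, 0,
                                  energy = e),
               numeric(nm))
  mu <- matrix(mu, nrow = nm)
  dim(L) <- c(length(angles) * cfg@nDetectors, nm)
  trans <- numeric(nrow(L))
  for (b in seq_along(spect@energies))
    trans <- trans + spect@weights[b] * exp(-as.numeric(L %*% mu[, b]))
  if (is.finite(n0)) {
    counts <- withSeed(cfg@noiseSeed, rpois(length(trans), n0 * trans))
    counts <- pmax(counts, cfg@countsFloor)
    # no lower clip: counts can exceed N0 by Poisson fluctuation, and
    # clipping the post-log values at 0 would add an object-size-dependent
    # positive DC bias that a calibrated scanner does not have
    data <- log(n0 / counts)
  } else {
    data <- pmax(-log(trans), 0)
  }
  new("Sinogram",
      data = matrix(data, length(angles), cfg@nDetectors),
      angles = angles, detSpacing = cfg@detSpacing)
}

#' Water-based beam-hardening precorrection (linearization)
#'
#' The standard scanner calibration: each measured polychromatic line
#' integral is mapped to the equivalent water path length L solving
#' `A = -log(sum_b w_b exp(-mu_w(E_b) L))` and replaced by
#' `mu_w(ref) * L`, which makes water-like media reconstruct at their
#' nominal HU regardless of path length. Attenuation beyond the water
#' curve (metal hardening, starvation noise) is extrapolated linearly and
#' survives as artifact — as on a clinical scanner without a dedicated
#' metal correction.
#'
#' @param s a [Sinogram-class] of measured line integrals.
#' @param spect the tube [Spectrum-class] assumed by the calibration.
#' @param maxPath largest water path length tabulated, cm.
#' @return a [Sinogram-class] of linearized integrals.
#' @export
waterPrecorrect <- function(s, spect = defaultSpectrum(), maxPath = 60) {
  w <- materialTable()$water
  muw <- linearAttenuation(w, spect@energies)
  L <- seq(0, maxPath, by = 0.25)
  A <- vapply(L, function(l) -log(sum(spect@weights * exp(-muw * l))), 0)
  slope <- (A[length(A)] - A[length(A) - 1L]) / 0.25
  slope0 <- (A[2] - A[1]) / 0.25
  x <- as.vector(s@data)
  Lx <- numeric(length(x))
  neg <- x < 0; high <- x > A[length(A)]
  mid <- !neg & !high
  Lx[mid] <- approx(A, L, xout = x[mid])$y
  Lx[neg] <- x[neg] / slope0              # noise excursions below zero
  Lx[high] <- maxPath + (x[high] - A[length(A)]) / slope
  initialize(s, data = matrix(muWaterRef() * Lx,
                              nrow(s@data), ncol(s@data)))
}

# Ramp (Ram-Lak) filtering of projections along the detector axis, by FFT
# convolution with the band-limited spatial kernel:
#   h(0) = 1/(4 d^2), h(n odd) = -1/(pi n d)^2, h(n even) = 0.
# Returns a matrix of the same shape as `data` (angles x detectors).
rampFilter <- function(data, detSpacing) {
  nd <- ncol(data)
  N <- 2^ceiling(log2(max(2L * nd, 64L)))
  h <- numeric(N)
  h[1] <- 1 / (4 * detSpacing^2)
  nodd <- seq(1L, N / 2, by = 2L)
  h[nodd + 1L] <- -1 / (pi * nodd * detSpacing)^2
  h[N + 1L - nodd] <- -1 / (pi * nodd * detSpacing)^2
  H <- Re(fft(h))
  X <- rbind(t(data), matrix(0, N - nd, nrow(data)))
  Q <- mvfft(X)
  q <- Re(mvfft(Q * H, inverse = TRUE)) / N * detSpacing
  t(q[seq_len(nd), , drop = FALSE])
}

#' Filtered back-projection reconstruction
#'
#' Ramp-filters each projection and back-projects onto a square grid. The
#' attenuation image is calibrated to Hounsfield units with water's
#' attenuation at the reference energy (80 keV):
#' `HU = 1000 (mu - mu_water) / mu_water`. A polychromatic acquisition
#' therefore keeps its beam-hardening bias — as on a scanner without
#' spectral corrections.
#'
#' The output is floored at `huFloor` (default -1000): air is the digital
#' zero of the stored image, so no voxel can fall below it. This matters
#' for artifacts — dark streaks clip at the floor while bright streaks do
#' not, which is why streaked regions carry a net positive bias.
#'
#' @param s a [Sinogram-class].
#' @param outSpacing output pixel size in cm.
#' @param outDim output grid size (pixels per side); default covers the
#'   detector extent.
#' @param sliceSpacing slice thickness of the returned single-slice volume.
#' @param huFloor lower clamp of the stored HU scale (`NULL` to disable).
#' @return a single-slice [CTVolume-class] in HU.
#' @export
fbpReconstruct <- function(s, outSpacing = s@detSpacing, outDim = NULL,
                           sliceSpacing = 0.1, huFloor = -1000) {
  if (length(s@angles) < 16L)
    warning("fewer than 16 projection angles: severe undersampling")
  if (is.null(outDim))
    outDim <- floor(ncol(s@data) * s@detSpacing / outSpacing)
  filt <- rampFilter(s@data, s@detSpacing)
  mu <- cpp_backproject(filt, s@angles * pi / 180, s@detSpacing,
                        as.integer(outDim), as.integer(outDim), outSpacing)
  hu <- huFromMu(mu)
  if (!is.null(huFloor)) hu <- pmax(hu, huFloor)
  ctVolume(hu, spacing = c(outSpacing, outSpacing, sliceSpacing))
}

#' @rdname Sinogram-class
#' @export
setMethod("sinogramData", "Sinogram", function(x) x@data)

#' @rdname Sinogram-class
#' @export
setMethod("projectionAngles", "Sinogram", function(x) x@angles)

setMethod("show", "Sinogram", function(object) {
  cat(sprintf(
    "Sinogram: %d angles [%.4g, %.4g] deg x %d bins (pitch %.3g cm)\n",
    length(object@angles), min(object@angles), max(object@angles),
    ncol(object@data), object@detSpacing))
})

#' Simulate a series of tilted acquisitions
#'
#' The tilted-scan experiment: for each tilt angle the phantom is rotated,
#' acquired slice by slice (forward projection and FBP), and returned
#' together with the exact rigid transform that maps the reconstruction
#' back into the laboratory frame. Each scan and slice uses a distinct
#' noise seed derived from `cfg@noiseSeed`. In split-dose mode each scan
#' runs at `mAs / n` so the series deposits the dose of one full scan.
#'
#' With the default `tiltAxis = "vertical"` the object is tilted about the
#' y axis, which lies *in* the slice plane: every scan re-slices the
#' phantom obliquely, so metal of finite extent enters different slices in
#' different scans and each reconstruction carries artifacts in different
#' places — the complementary information the per-voxel median exploits.
#' The scanner slab of each scan is auto-sized (unless `nSlices` is given)
#' to cover, after rotating back, the lab-frame region within
#' `coverRadius` of `focus` in-plane and `coverHalfZ` along z.
#' `tiltAxis = "inplane"` instead rotates about the slice normal
#' (z-invariant geometry, one independent-noise slice stack).
#'
#' @param p a [PhantomImage-class] built from analytic shapes.
#' @param tiltAngles distinct tilt angles in degrees.
#' @param cfg an [AcquisitionConfig-class].
#' @param spect a [Spectrum-class].
#' @param tiltAxis `"vertical"` (y axis, re-slicing) or `"inplane"`
#'   (slice normal).
#' @param nSlices slices per scan; `NULL` auto-sizes the slab (vertical
#'   mode) or defaults to 1 (inplane mode).
#' @param sliceSpacing scanner slice thickness in cm (deliberately coarser
#'   than the in-plane pitch, as on real scanners).
#' @param focus lab-frame point the scan slabs are centered on (cm).
#' @param coverRadius,coverHalfZ lab-frame region around `focus` that must
#'   stay covered after registration (cm).
#' @param doseMode `"full"` (each scan at `cfg@mAs`) or `"split"` (each at
#'   `cfg@mAs / length(tiltAngles)`).
#' @param outSpacing,outDim in-plane reconstruction grid; defaults to the
#'   phantom raster.
#' @param waterCorrection apply the scanner's water-based beam-hardening
#'   linearization ([waterPrecorrect()]) before reconstruction (default
#'   `TRUE`, as on clinical scanners).
#' @return list with one element per tilt angle, each a list with elements
#'   `volume` ([CTVolume-class]), `transform` ([RigidTransform-class]) and
#'   `tiltAngle`.
#' @export
simulateTiltedSeries <- function(p, tiltAngles, cfg = acquisitionConfig(),
                                 spect = defaultSpectrum(),
                                 tiltAxis = c("vertical", "inplane"),
                                 nSlices = NULL, sliceSpacing = 0.2,
                                 focus = c(0, 0, 0), coverRadius = 2.8,
                                 coverHalfZ = 0.5,
                                 doseMode = c("full", "split"),
                                 outSpacing = p@spacing,
                                 outDim = nrow(p@labels),
                                 waterCorrection = TRUE) {
  doseMode <- match.arg(doseMode)
  tiltAxis <- match.arg(tiltAxis)
  if (anyDuplicated(tiltAngles)) stop("tilt angles must be distinct")
  scanMAs <- if (doseMode == "split") cfg@mAs / length(tiltAngles) else cfg@mAs
  origin2 <- -(outDim - 1) / 2 * outSpacing
  lapply(seq_along(tiltAngles), function(i) {
    ang <- tiltAngles[i]
    th <- ang * pi / 180
    if (tiltAxis == "vertical") {
      zc <- -sin(th) * focus[1] + cos(th) * focus[3]
      ns <- nSlices %||% {
        half <- abs(sin(th)) * coverRadius + abs(cos(th)) * coverHalfZ +
          1.5 * sliceSpacing
        2L * as.integer(ceiling(half / sliceSpacing)) + 1L
      }
      zs <- zc + (seq_len(ns) - (ns + 1) / 2) * sliceSpacing
      sections <- lapply(zs, function(z) phantomSlice(p, ang, z))
      rot <- axisAngleTransform(c(0, 1, 0), -ang)
    } else {
      ns <- nSlices %||% 1L
      zs <- focus[3] + (seq_len(ns) - (ns + 1) / 2) * sliceSpacing
      sections <- rep(list(rotatePhantom(p, ang)), ns)
      rot <- axisAngleTransform(c(0, 0, 1), -ang)
    }
    vals <- array(0, c(outDim, outDim, ns))
    for (k in seq_len(ns)) {
      scfg <- cfg
      scfg@mAs <- scanMAs
      scfg@noiseSeed <- as.integer(
        (cfg@noiseSeed + 7919 * (i - 1) + 104729 * (k - 1)) %%
          .Machine$integer.max)
      sino <- forwardProject(sections[[k]], spect = spect, cfg = scfg)
      if (waterCorrection) sino <- waterPrecorrect(sino, spect)
      rec <- fbpReconstruct(sino, outSpacing = outSpacing, outDim = outDim)
      vals[, , k] <- axialSlice(rec)
    }
    vol <- ctVolume(vals, spacing = c(outSpacing, outSpacing, sliceSpacing),
                    origin = c(origin2, origin2, zs[1]))
    list(volume = vol, transform = rot, tiltAngle = ang)
  })
}
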