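#' @import methods
#' @importFrom stats approx fft mvfft rnorm rpois runif sd
#' @importFrom utils head tail write.csv read.csv
#' @useDynLib tiltmar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' CT volume in Hounsfield units
#'
#' The central data container: a 3D scalar grid of voxel grey values in
#' Hounsfield units (HU) on an axis-aligned grid in the laboratory frame.
#' A voxel's coordinate is the coordinate of its *center*; the voxel with
#' 0-based index (0,0,0) sits at `origin`. `coverage` flags voxels that carry
#' valid data — after rigid resampling, target voxels that fall outside the
#' source scan's field of view are uncovered and are excluded from
#' combination and metrics rather than zero-filled.
#'
#' Values are always floating-point HU internally; integer stored values and
#' rescale slope/intercept exist only at the DICOM I/O boundary.
#'
#' @slot values 3D numeric array of HU values (`NA` allowed where uncovered).
#' @slot spacing numeric(3), voxel edge lengths in cm (all > 0).
#' @slot origin numeric(3), lab-frame position of the center of voxel
#'   (0,0,0), in cm.
#' @slot coverage logical array, same dim as `values`.
#'
#' @seealso [ctVolume()], [readDicomSeries()], [resample()], [combine()]
#' @export
setClass("CTVolume",
  representation(values = "array", spacing = "numeric",
                 origin = "numeric", coverage = "array"))

setValidity("CTVolume", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 positive finite numbers (cm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite numbers (cm)")
  if (!identical(dim(object@coverage), d))
    return("coverage must match dim(values)")
  if (!is.logical(object@coverage)) return("coverage must be logical")
  cov <- object@coverage
  if (any(!is.finite(object@values[cov])))
    return("values must be finite wherever coverage is TRUE")
  TRUE
})

#' Rigid transform between scanner frames
#'
#' Maps coordinates of a source volume into the laboratory frame:
#' `x_lab = rotation %*% x_src + translation`. Rotations are proper
#' (orthonormal, determinant +1); composition and inversion stay within the
#' class.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation numeric(3), cm.
#' @seealso [rigidTransform()], [axisAngleTransform()], [resample()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!is.numeric(R) || !identical(dim(R), c(3L, 3L)))
    return("rotation must be a numeric 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation must be orthonormal")
  if (abs(det(R) - 1) > 1e-6)
    return("rotation must be proper (det +1)")
  if (length(object@translation) != 3L || any(!is.finite(object@translation)))
    return("translation must be 3 finite numbers (cm)")
  TRUE
})

#' Parallel-beam sinogram
#'
#' Line integrals (dimensionless, `log(N0/I)`) indexed by projection angle
#' (rows) and detector bin (columns) for one slice. Angles are in degrees,
#' strictly increasing, and must cover at least a half turn (180 degrees,
#' counting the angular bin width of the last view).
#'
#' @slot data numeric matrix, `length(angles)` x `nDetectors`.
#' @slot angles numeric, projection angles in degrees.
#' @slot detSpacing detector bin pitch in cm.
#' @seealso [forwardProject()], [virtualSinogram()], [fbpReconstruct()]
#' @export
setClass("Sinogram",
  representation(data = "matrix", angles = "numeric", detSpacing = "numeric"))

setValidity("Sinogram", function(object) {
  a <- object@angles
  if (nrow(object@data) != length(a))
    return("nrow(data) must equal length(angles)")
  if (length(a) > 1 && any(diff(a) <= 0))
    return("angles must be strictly increasing")
  if (length(a) > 1) {
    span <- (max(a) - min(a)) * length(a) / (length(a) - 1)
    if (span < 180 - 1e-6)
      return("angles must span at least 180 degrees")
  }
  if (length(object@detSpacing) != 1L || object@detSpacing <= 0)
    return("detSpacing must be a single positive number (cm)")
  if (any(!is.finite(object@data)))
    return("sinogram data must be finite")
  TRUE
})

#' Simulator material
#'
#' A material known to the CT simulator: physical density and a tabulated
#' mass attenuation coefficient over diagnostic energies. Tables must be
#' strictly positive and non-increasing with energy (no absorption edges in
#' the modelled range).
#'
#' @slot name character scalar.
#' @slot density g/cm^3, > 0.
#' @slot energies keV bin centers of the table (increasing).
#' @slot massAtten cm^2/g at each tabulated energy.
#' @slot referenceHU nominal HU at the scanner reference energy (`NA` if not
#'   pinned).
#' @seealso [linearAttenuation()], [materialTable()]
#' @export
setClass("Material",
  representation(name = "character", density = "numeric",
                 energies = "numeric", massAtten = "numeric",
                 referenceHU = "numeric"))

setValidity("Material", function(object) {
  if (object@density <= 0) return("density must be > 0")
  if (length(object@energies) != length(object@massAtten))
    return("energies and massAtten must have equal length")
  if (any(diff(object@energies) <= 0))
    return("energies must be strictly increasing")
  if (any(object@massAtten <= 0))
    return("mass attenuation must be strictly positive")
  if (any(diff(object@massAtten) > 1e-12))
    return("mass attenuation must be non-increasing with energy")
  TRUE
})

#' X-ray tube spectrum
#'
#' Relative photon fluence per energy bin; weights are non-negative and
#' normalized to sum 1. A single bin is the monochromatic limit.
#'
#' @slot energies keV bin centers.
#' @slot weights relative fluence per bin, summing to 1.
#' @export
setClass("Spectrum",
  representation(energies = "numeric", weights = "numeric"))

setValidity("Spectrum", function(object) {
  if (length(object@energies) < 1L) return("need at least one energy bin")
  if (length(object@energies) != length(object@weights))
    return("energies and weights must have equal length")
  if (any(object@weights < 0)) return("weights must be >= 0")
  if (abs(sum(object@weights) - 1) > 1e-9)
    return("weights must sum to 1")
  TRUE
})

#' Digital phantom
#'
#' A material-label grid plus a material table. Label 1 is always the
#' background (air). When the phantom was built from analytic shapes the
#' `shapes` slot retains them so that tilted acquisitions can re-rasterize
#' the rotated geometry exactly instead of resampling labels.
#'
#' @slot labels integer matrix (one slice) of 1-based material indices.
#' @slot materials list of [Material-class] objects; `labels` indexes it.
#' @slot spacing pixel edge length in cm.
#' @slot shapes list of analytic primitives (discs/ellipses/boxes), possibly
#'   empty.
#' @seealso [makeGammexPhantom()], [makeDentalPhantom()], [forwardProject()]
#' @export
setClass("PhantomImage",
  representation(labels = "matrix", materials = "list",
                 spacing = "numeric", shapes = "list"))

setValidity("PhantomImage", function(object) {
  if (!is.integer(object@labels)) return("labels must be integer")
  rng <- range(object@labels)
  if (rng[1] < 1L || rng[2] > length(object@materials))
    return("every label must index a defined material")
  if (!identical(tolower(object@materials[[1]]@name), "air"))
    return("material 1 (background) must be air")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    return("spacing must be a single positive number (cm)")
  TRUE
})

#' Acquisition configuration
#'
#' Scanner settings for one simulated acquisition. The tube current-time
#' product (mAs) is a proxy for dose: the photon budget per detector bin is
#' `N0 = mAs * photonsPerMAs` and scales linearly with mAs. `mAs = Inf`
#' means a noiseless acquisition. Detected counts are floored at
#' `countsFloor` before the log transform (photon-starvation clamp).
#'
#' @slot mAs tube current-time product; `Inf` disables noise.
#' @slot photonsPerMAs unattenuated photons per detector bin and mAs.
#' @slot nAngles number of projection angles over the half turn.
#' @slot nDetectors number of detector bins.
#' @slot detSpacing detector pitch in cm.
#' @slot noiseSeed integer seed; every random draw flows from it.
#' @slot countsFloor floor applied to detected counts before `log` (>0).
#' @seealso [acquisitionConfig()], [forwardProject()], [simulateTiltedSeries()]
#' @export
setClass("AcquisitionConfig",
  representation(mAs = "numeric", photonsPerMAs = "numeric",
                 nAngles = "integer", nDetectors = "integer",
                 detSpacing = "numeric", noiseSeed = "integer",
                 countsFloor = "numeric"))

setValidity("AcquisitionConfig", function(object) {
  if (object@mAs <= 0) return("mAs must be > 0")
  if (object@photonsPerMAs <= 0) return("photonsPerMAs must be > 0")
  if (object@nAngles < 1L) return("need at least one angle")
  if (object@nDetectors < 2L) return("need at least two detector bins")
  if (object@detSpacing <= 0) return("detSpacing must be > 0")
  if (object@countsFloor <= 0) return("countsFloor must be > 0")
  TRUE
})

#' Combined (fused) volume
#'
#' Result of per-voxel fusion of co-registered scans. Extends
#' [CTVolume-class] with the per-voxel count of contributing scans and the
#' estimator used. Values are defined wherever at least one scan covers the
#' voxel.
#'
#' @slot nSamples integer array, per-voxel number of contributing scans.
#' @slot method `"mean"` or `"median"`.
#' @seealso [combine()], [incrementalSeries()]
#' @export
setClass("CombinedVolume", contains = "CTVolume",
  representation(nSamples = "array", method = "character"))

setValidity("CombinedVolume", function(object) {
  if (!identical(dim(object@nSamples), dim(object@values)))
    return("nSamples must match dim(values)")
  if (!object@method %in% c("mean", "median"))
    return("method must be 'mean' or 'median'")
  if (any(object@nSamples < 0L)) return("nSamples must be >= 0")
  if (any(object@coverage != (object@nSamples >= 1L)))
    return("coverage must equal (nSamples >= 1)")
  TRUE
})

#' Region of interest
#'
#' A set of voxel indices within a fixed grid, plus a human-readable
#' descriptor of how it was constructed (ring or box parameters).
#'
#' @slot indices integer vector of linear voxel indices (1-based, non-empty).
#' @slot dim grid dimension the indices refer to.
#' @slot descriptor named list describing the ROI geometry.
#' @seealso [ringRoi()], [boxRoi()], [evaluateRoi()]
#' @export
setClass("Roi",
  representation(indices = "integer", dim = "integer", descriptor = "list"))

setValidity("Roi", function(object) {
  if (length(object@indices) < 1L) return("ROI must be non-empty")
  if (any(object@indices < 1L) ||
      any(object@indices > prod(object@dim)))
    return("ROI indices out of grid")
  TRUE
})
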