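#' Construct a CT volume
#'
#' Builds a [CTVolume-class] from an array of Hounsfield values. A matrix is
#' promoted to a single-slice 3D array, which makes 2D slice work (the MAR
#' baselines, single-slice simulations) convenient.
#'
#' @param values numeric array (3D) or matrix (promoted to nx x ny x 1) of
#'   HU values.
#' @param spacing voxel edge lengths in cm; a scalar is recycled to all three
#'   axes. Default 0.1 cm isotropic.
#' @param origin lab-frame coordinate of the center of voxel (0,0,0) in cm.
#'   Default places the grid center at the lab origin.
#' @param coverage logical array matching `values`; default all `TRUE`.
#' @return a `CTVolume`.
#' @examples
#' v <- ctVolume(array(0, c(8, 8, 4)))
#' spacing(v)
#' @export
ctVolume <- function(values, spacing = 0.1, origin = NULL, coverage = NULL) {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L)
    stop("values must be a matrix or 3D array")
  storage.mode(values) <- "double"
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(origin)) origin <- -(dim(values) - 1) / 2 * spacing
  if (is.null(coverage)) coverage <- array(TRUE, dim(values))
  if (is.matrix(coverage)) dim(coverage) <- c(dim(coverage), 1L)
  new("CTVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), coverage = coverage)
}

#' @rdname CTVolume-class
#' @export
setMethod("voxelData", "CTVolume", function(x) x@values)

#' @rdname CTVolume-class
#' @export
setMethod("spacing", "CTVolume", function(x) x@spacing)

#' @rdname CTVolume-class
#' @export
setMethod("origin", "CTVolume", function(x) x@origin)

#' @rdname CTVolume-class
#' @export
setMethod("coverage", "CTVolume", function(x) x@coverage)

#' @rdname CTVolume-class
#' @export
setMethod("dim", "CTVolume", function(x) dim(x@values))

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@values)
  cov <- mean(object@coverage)
  rng <- if (any(object@coverage))
    range(object@values[object@coverage]) else c(NA, NA)
  cat(sprintf("%s %d x %d x %d, spacing %s cm\n", class(object),
              d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = " x ")))
  cat(sprintf("  HU range [%s, %s], coverage %.1f%%\n",
              signif(rng[1], 4), signif(rng[2], 4), 100 * cov))
})

#' Extract one axial slice of a volume as a matrix
#'
#' @param v a [CTVolume-class].
#' @param k 1-based slice index along the third axis.
#' @return numeric matrix of HU values.
#' @export
axialSlice <- function(v, k = 1L) {
  stopifnot(is(v, "CTVolume"), k >= 1L, k <= dim(v)[3])
  v@values[, , k]
}

# Lab-frame coordinates of voxel centers along one axis (0-based index i
# maps to origin + i * spacing).
axisCoords <- function(v, axis) {
  v@origin[axis] + (seq_len(dim(v)[axis]) - 1L) * v@spacing[axis]
}

#' Grid specification of a volume
#'
#' A target-grid descriptor (`dim`, `spacing`, `origin`) as used by
#' [resample()]. Useful to resample several scans onto one common mesh.
#'
#' @param dim integer(3) grid size.
#' @param spacing numeric(3) (or scalar) voxel size in cm.
#' @param origin numeric(3) center of voxel (0,0,0) in cm; default centers
#'   the grid on the lab origin.
#' @return a named list with elements `dim`, `spacing`, `origin`.
#' @export
gridSpec <- function(dim, spacing = 0.1, origin = NULL) {
  dim <- as.integer(dim)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(origin)) origin <- -(dim - 1) / 2 * spacing
  stopifnot(length(dim) == 3L, all(dim >= 1L), all(spacing > 0))
  list(dim = dim, spacing = as.numeric(spacing), origin = as.numeric(origin))
}

sameGrid <- function(a, b, tol = 1e-9) {
  identical(dim(a@values), dim(b@values)) &&
    max(abs(a@spacing - b@spacing)) < tol &&
    max(abs(a@origin - b@origin)) < tol
}
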