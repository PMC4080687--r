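#' Rigidly resample a volume onto a target grid
#'
#' Pull-based resampling: every target voxel center is mapped through the
#' inverse of `transform` into the source volume and sampled by tri-linear
#' interpolation, the weights coming from the fractional part of the source
#' coordinate. For rigid maps this is equivalent to pushing source voxels
#' through `transform` but cannot leave holes. Coverage is conservative: a
#' target voxel is covered only if every source corner carrying a non-zero
#' interpolation weight is inside the source grid and itself covered;
#' everything else is marked uncovered (and `NA`) rather than zero-filled,
#' so out-of-field air never bleeds into a later combination. Fractional
#' indices within 1e-9 of the lattice snap onto it, so lattice-preserving
#' transforms are exact permutations.
#'
#' @param x a [CTVolume-class] (source, in its own scanner frame).
#' @param transform a [RigidTransform-class] mapping source coordinates into
#'   the laboratory frame (`x_lab = R x_src + t`).
#' @param target target grid: a [gridSpec()] list or a [CTVolume-class]
#'   whose grid is reused. Default: the source's own grid.
#' @param ... unused.
#' @return a [CTVolume-class] on the target grid.
#' @examples
#' v <- ctVolume(array(rnorm(8 * 8 * 4), c(8, 8, 4)))
#' identical(voxelData(resample(v, rigidTransform())), voxelData(v))
#' @export
setMethod("resample", "CTVolume",
          function(x, transform = rigidTransform(), target = NULL, ...) {
  if (!is(transform, "RigidTransform"))
    stop("transform must be a RigidTransform (orthonormal rotation)")
  if (is.null(target))
    target <- gridSpec(dim(x), x@spacing, x@origin)
  if (is(target, "CTVolume"))
    target <- gridSpec(dim(target), target@spacing, target@origin)
  stopifnot(all(target$spacing > 0))
  res <- cpp_resample_rigid(x@values, x@coverage, dim(x@values), x@spacing,
                            x@origin, transform@rotation,
                            transform@translation, target$dim,
                            target$spacing, target$origin)
  vals <- array(res$values, target$dim)
  cov <- array(res$coverage, target$dim)
  ctVolume(vals, spacing = target$spacing, origin = target$origin,
           coverage = cov)
})

#' Sub-voxel translation refinement
#'
#' Grid search for the translation (within `radius` voxels per axis, step
#' `step` voxels) that maximizes the normalized cross-correlation between
#' `fixed` and `moving` resampled onto the fixed grid — the automated
#' replacement for the by-eye sub-voxel alignment of tilted scans. Only the
#' translation is searched; rotations are taken as known.
#'
#' @param moving,fixed [CTVolume-class] objects (already rotationally
#'   aligned; `moving` is sampled at the shifted fixed grid).
#' @param radius search radius in fixed-grid voxels per axis (default 0.5).
#' @param step search step in voxels (default 0.1).
#' @param axes which axes to search (default all three).
#' @param minOverlap minimum fraction of fixed voxels that must overlap the
#'   moving volume at zero shift.
#' @param minNcc optional correlation floor; if the best NCC falls below
#'   it, an error is raised (guards against structureless inputs).
#' @return a [RigidTransform-class] with identity rotation and the best
#'   translation (cm); the achieved correlation is attached as attribute
#'   `"ncc"`.
#' @export
refineTranslation <- function(moving, fixed, radius = 0.5, step = 0.1,
                              axes = 1:3, minOverlap = 0.1, minNcc = NULL) {
  stopifnot(is(moving, "CTVolume"), is(fixed, "CTVolume"))
  offs <- seq(-radius, radius, by = step)
  grid <- list(0, 0, 0)
  for (a in axes) grid[[a]] <- offs * fixed@spacing[a]
  shifts <- as.matrix(expand.grid(x = grid[[1]], y = grid[[2]],
                                  z = grid[[3]]))
  ncc <- cpp_ncc_shifts(moving@values, moving@coverage, dim(moving@values),
                        moving@spacing, moving@origin,
                        fixed@values, fixed@coverage, dim(fixed@values),
                        fixed@spacing, fixed@origin, shifts)
  if (all(is.na(ncc)))
    stop("correlation undefined: degenerate (constant) or empty overlap")
  # overlap check at the unshifted position
  ov <- overlapFraction(moving, fixed)
  if (ov < minOverlap)
    stop(sprintf("volumes overlap on %.1f%% of voxels (< %.0f%%)",
                 100 * ov, 100 * minOverlap))
  best <- which.max(ncc)
  if (!is.null(minNcc) && ncc[best] < minNcc)
    stop(sprintf("best correlation %.3f below floor %.3f", ncc[best], minNcc))
  out <- rigidTransform(diag(3), -shifts[best, ])
  attr(out, "ncc") <- ncc[best]
  out
}

# Fraction of covered fixed voxels whose centers fall inside the moving
# volume's covered domain.
overlapFraction <- function(moving, fixed) {
  res <- cpp_resample_rigid(moving@values, moving@coverage,
                            dim(moving@values), moving@spacing,
                            moving@origin, diag(3), c(0, 0, 0),
                            dim(fixed@values), fixed@spacing, fixed@origin)
  fc <- fixed@coverage
  sum(res$coverage & fc) / max(1L, sum(fc))
}
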