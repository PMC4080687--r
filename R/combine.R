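#' Fuse co-registered volumes per voxel
#'
#' The core of the tilted-scan MAR method: given scans of the same object
#' co-registered onto one grid, compute the per-voxel mean or median over
#' the scans that cover each voxel. Because streak artifacts sit at
#' different places in differently tilted scans, a voxel is typically
#' corrupted in only a minority of them, and the median then restores the
#' uncorrupted value; the mean only dilutes the artifact.
#'
#' The median of an even number of samples is the midpoint of the two
#' central order statistics. Voxels covered by no scan are uncovered in the
#' result. Optional `weights` apply to the mean only (the default is the
#' uniform combination).
#'
#' @param volumes non-empty list of [CTVolume-class] objects on identical
#'   grids (spacing, shape, origin).
#' @param method `"median"` (default) or `"mean"`.
#' @param weights optional per-scan weights for the mean.
#' @return a [CombinedVolume-class].
#' @examples
#' v <- lapply(c(1, 2, 100), function(h) ctVolume(array(h, c(2, 2, 1))))
#' voxelData(combine(v, "median"))[1]  # 2
#' voxelData(combine(v, "mean"))[1]    # 34.33
#' @export
combine <- function(volumes, method = c("median", "mean"), weights = NULL) {
  method <- match.arg(method)
  if (length(volumes) < 1L) stop("need at least one volume")
  ref <- volumes[[1]]
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    d <- dim(v@values); dr <- dim(ref@values)
    ax <- c("x", "y", "z")
    if (any(d != dr))
      stop("grid mismatch on axis ", ax[which(d != dr)[1]],
           " (volume ", i, ")")
    if (max(abs(v@spacing - ref@spacing)) > 1e-9)
      stop("grid mismatch: spacing differs on axis ",
           ax[which.max(abs(v@spacing - ref@spacing))], " (volume ", i, ")")
    if (max(abs(v@origin - ref@origin)) > 1e-9)
      stop("grid mismatch: origin differs on axis ",
           ax[which.max(abs(v@origin - ref@origin))], " (volume ", i, ")")
  }
  if (!is.null(weights) && method == "mean") {
    stopifnot(length(weights) == length(volumes), all(weights > 0))
  } else weights <- numeric(0)
  vals <- lapply(volumes, function(v) {
    x <- v@values
    x[!v@coverage] <- 0  # never read where uncovered, but keep finite
    x
  })
  covs <- lapply(volumes, function(v) v@coverage)
  res <- cpp_combine_stack(vals, covs, if (method == "mean") 0L else 1L,
                           as.numeric(weights))
  d <- dim(ref@values)
  n <- array(res$n, d)
  new("CombinedVolume", values = array(res$values, d),
      spacing = ref@spacing, origin = ref@origin,
      coverage = array(n >= 1L, d), nSamples = n, method = method)
}

#' @rdname CombinedVolume-class
#' @export
setMethod("nSamples", "CombinedVolume", function(x) x@nSamples)

#' @rdname CombinedVolume-class
#' @export
setMethod("combineMethod", "CombinedVolume", function(x) x@method)

setMethod("show", "CombinedVolume", function(object) {
  callNextMethod()
  cat(sprintf("  fused by %s over up to %d scans\n", object@method,
              max(object@nSamples)))
})

#' Incremental combinations of a growing scan series
#'
#' Combines the first k volumes for k = 1..n — the computational substrate
#' for curves of metric versus number of scans.
#'
#' @inheritParams combine
#' @param volumes ordered list of co-registered [CTVolume-class] objects.
#' @return list of [CombinedVolume-class], element k combining the first k
#'   scans.
#' @export
incrementalSeries <- function(volumes, method = c("median", "mean")) {
  method <- match.arg(method)
  lapply(seq_along(volumes),
         function(k) combine(volumes[seq_len(k)], method))
}

#' Restrict a combined volume to well-covered voxels
#'
#' Returns a plain [CTVolume-class] whose coverage keeps only voxels with
#' at least `k` contributing scans, so downstream metrics can exclude
#' thinly covered regions.
#'
#' @param cv a [CombinedVolume-class].
#' @param k minimum number of contributing scans.
#' @return a [CTVolume-class].
#' @export
requireCoverage <- function(cv, k) {
  stopifnot(is(cv, "CombinedVolume"), k >= 1)
  cov <- cv@nSamples >= k
  vals <- cv@values
  vals[!cov] <- NA_real_
  ctVolume(vals, spacing = cv@spacing, origin = cv@origin, coverage = cov)
}
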