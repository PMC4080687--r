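# ---- virtual sinogram & metal segmentation -------------------------------

asSliceMatrix <- function(x) {
  if (is(x, "CTVolume")) {
    if (dim(x)[3] != 1L) stop("expected a single-slice volume")
    return(list(img = x@values[, , 1], px = x@spacing[1]))
  }
  stop("expected a CTVolume slice")
}

marGeometry <- function(n, px, nAngles = 360L) {
  nd <- as.integer(ceiling(n * sqrt(2))) + 1L
  list(angles = projectionAngleSet(nAngles), nDet = nd, detSpacing = px)
}

#' Virtual sinogram of a reconstructed slice
#'
#' Forward projection (Radon transform) of an already reconstructed image:
#' HU values are mapped back to linear attenuation (negative attenuation is
#' clipped to zero) and integrated along parallel rays. This is the input
#' the sinogram-domain MAR baselines operate on when raw scanner data is
#' unavailable.
#'
#' @param slice a single-slice [CTVolume-class] (square).
#' @param nAngles number of projection angles over the half turn.
#' @param geometry optional geometry list from an earlier call, to reuse
#'   identical angles/detector layout.
#' @param stepFrac ray-marching step as a fraction of the pixel size.
#' @return a [Sinogram-class].
#' @export
virtualSinogram <- function(slice, nAngles = 360L, geometry = NULL,
                            stepFrac = 0.5) {
  s <- asSliceMatrix(slice)
  if (nrow(s$img) != ncol(s$img)) stop("virtual sinogram expects a square slice")
  g <- geometry %||% marGeometry(nrow(s$img), s$px, nAngles)
  mu <- pmax(muFromHu(s$img), 0)
  dat <- cpp_radon(mu, s$px, g$angles * pi / 180, g$nDet, g$detSpacing,
                   stepFrac)
  new("Sinogram", data = pmax(dat, 0), angles = g$angles,
      detSpacing = g$detSpacing)
}

#' Segment metal in image space
#'
#' Strict HU threshold exceedance; 2000 HU is the conventional metal
#' threshold.
#'
#' @param slice a single-slice [CTVolume-class].
#' @param threshold HU threshold (strict `>`).
#' @return logical matrix, `TRUE` on metal.
#' @export
segmentMetal <- function(slice, threshold = 2000) {
  s <- asSliceMatrix(slice)
  s$img > threshold
}

#' Metal trace in sinogram space
#'
#' Forward projection of the metal mask; a sinogram bin is traced iff its
#' ray intersects metal (projected mask value above a small numerical
#' tolerance).
#'
#' @param mask logical matrix (image-space metal mask).
#' @param px pixel size of the mask in cm.
#' @param geometry geometry list as produced inside [virtualSinogram()];
#'   must match the sinogram the trace will be applied to.
#' @param stepFrac ray-marching step fraction.
#' @return logical matrix (angles x detector bins).
#' @export
metalTrace <- function(mask, px, geometry, stepFrac = 0.5) {
  proj <- cpp_radon(matrix(as.numeric(mask), nrow(mask)), px,
                    geometry$angles * pi / 180, geometry$nDet,
                    geometry$detSpacing, stepFrac)
  proj > 1e-9
}

# ---- in-painting algorithms ----------------------------------------------

#' Linear-interpolation MAR (LI-MAR)
#'
#' Per projection angle, each maximal run of traced detector bins is
#' replaced by 1D linear interpolation between the nearest untraced
#' neighbours (constant extension at row ends). Untraced bins are returned
#' bit-exactly unchanged.
#'
#' @param s a [Sinogram-class].
#' @param trace logical matrix matching `s@data`.
#' @return a [Sinogram-class].
#' @export
liMar <- function(s, trace) {
  stopifnot(identical(dim(trace), dim(s@data)))
  dat <- s@data
  for (a in seq_len(nrow(dat))) {
    tr <- trace[a, ]
    if (!any(tr)) next
    if (all(tr))
      stop("entire detector row traced at angle ", s@angles[a], " deg")
    keep <- which(!tr)
    dat[a, tr] <- approx(keep, dat[a, keep], xout = which(tr), rule = 2)$y
  }
  initialize(s, data = dat)
}

# For each position, index of nearest FALSE entry to the left/right along a
# logical vector; NA where none exists.
nearestFalse <- function(tr) {
  n <- length(tr)
  idx <- seq_len(n)
  left <- idx; left[tr] <- NA_integer_
  left <- cummax(ifelse(is.na(left), 0L, left))
  left[left == 0L] <- NA_integer_
  right <- idx; right[tr] <- NA_integer_
  right <- rev(cummin(ifelse(is.na(rev(right)), n + 1L, rev(right))))
  right[right == n + 1L] <- NA_integer_
  list(left = left, right = right)
}

#' Bidirectional inverse-distance MAR (BI-MAR)
#'
#' Each traced bin is filled with the inverse-distance-weighted combination
#' of the nearest untraced values along *both* the detector axis (same
#' angle) and the angle axis (same detector bin) — up to four neighbours,
#' weights `1/distance`, normalized. A traced bin with no untraced
#' neighbour in either direction is a hard error.
#'
#' @inheritParams liMar
#' @return a [Sinogram-class].
#' @export
biMar <- function(s, trace) {
  stopifnot(identical(dim(trace), dim(s@data)))
  dat <- s@data
  na <- nrow(dat); nd <- ncol(dat)
  rowNb <- lapply(seq_len(na), function(a) nearestFalse(trace[a, ]))
  colNb <- lapply(seq_len(nd), function(d) nearestFalse(trace[, d]))
  out <- dat
  for (a in seq_len(na)) {
    tr <- which(trace[a, ])
    for (d in tr) {
      cand <- c(rowNb[[a]]$left[d], rowNb[[a]]$right[d],
                colNb[[d]]$left[a], colNb[[d]]$right[a])
      vals <- c(dat[a, cand[1]], dat[a, cand[2]],
                dat[cand[3], d], dat[cand[4], d])
      dist <- abs(c(d - cand[1], cand[2] - d, a - cand[3], cand[4] - a))
      ok <- !is.na(cand)
      if (!any(ok))
        stop("traced bin (", a, ", ", d, ") has no untraced neighbour")
      w <- 1 / dist[ok]
      out[a, d] <- sum(w * vals[ok]) / sum(w)
    }
  }
  initialize(s, data = out)
}

#' Tissue-class prior for NMAR
#'
#' Segments the uncorrected slice into air / soft tissue / bone by HU
#' thresholds: air pixels are set to -1000 HU, soft-tissue pixels to the
#' mean HU of the soft-tissue class, bone keeps its value, and metal
#' (above `metalThreshold`) is replaced by soft tissue.
#'
#' @param slice a single-slice [CTVolume-class].
#' @param airBelow,boneAbove class thresholds in HU.
#' @param metalThreshold metal threshold in HU.
#' @return a single-slice [CTVolume-class] (the prior image).
#' @export
nmarPrior <- function(slice, airBelow = -500, boneAbove = 500,
                      metalThreshold = 2000) {
  s <- asSliceMatrix(slice)
  img <- s$img
  soft <- img >= airBelow & img < boneAbove
  metal <- img > metalThreshold
  softVal <- if (any(soft)) mean(img[soft]) else 0
  out <- img
  out[img < airBelow] <- -1000
  out[soft] <- softVal
  out[metal] <- softVal
  ctVolume(out, spacing = spacing(slice))
}

#' Normalized MAR (NMAR)
#'
#' The sinogram is divided bin-wise by the virtual sinogram of a prior
#' image, the metal trace is in-painted by [liMar()] in the normalized
#' domain, and the result is de-normalized. With a flat prior this reduces
#' exactly to LI-MAR. Untraced bins are returned bit-exactly unchanged.
#'
#' @inheritParams liMar
#' @param prior a single-slice [CTVolume-class], typically from
#'   [nmarPrior()].
#' @param geometry geometry list matching `s` (angles, detector layout).
#' @param priorFloor lower floor applied to the prior sinogram before the
#'   division.
#' @return a [Sinogram-class].
#' @export
nmar <- function(s, trace, prior, geometry, priorFloor = 1e-6) {
  stopifnot(identical(dim(trace), dim(s@data)))
  ps <- virtualSinogram(prior, geometry = geometry)@data
  ps <- pmax(ps, priorFloor)
  if (any(ps <= 0)) stop("prior sinogram non-positive after flooring")
  norm <- initialize(s, data = pmax(s@data / ps, 0))
  filled <- liMar(norm, trace)@data * ps
  dat <- s@data
  dat[trace] <- pmax(filled[trace], 0)
  initialize(s, data = dat)
}

#' Frequency-split MAR blending (FSMAR)
#'
#' Combines the high frequencies of the original reconstruction (sharp
#' edges) with the low frequencies of a MAR-corrected image, blended near
#' metal only: `low(x)` is a Gaussian blur of radius `rLow` pixels,
#' `high(x) = x - low(x)`, the weight `w` is a Gaussian blur of the metal
#' mask with radius `rHigh` rescaled to [0, 1], and the output is
#' `w * (low(mar) + high(orig)) + (1 - w) * mar`. "Radius" is interpreted
#' as the Gaussian standard deviation in pixels.
#'
#' @param original,marImage single-slice [CTVolume-class] objects on the
#'   same grid.
#' @param mask logical metal mask matrix.
#' @param rLow,rHigh Gaussian radii (sd, pixels) of the frequency split and
#'   of the blending weight.
#' @return a single-slice [CTVolume-class].
#' @export
fsMar <- function(original, marImage, mask, rLow = 3, rHigh = 30) {
  o <- asSliceMatrix(original); m <- asSliceMatrix(marImage)
  stopifnot(identical(dim(o$img), dim(m$img)),
            identical(dim(mask), dim(o$img)))
  if (!any(mask))
    return(ctVolume(m$img, spacing = spacing(marImage)))
  blur <- function(x, r) {
    rad <- min(2L * ceiling(3 * r) + 1L, 2L * ((min(dim(x)) - 1L) %/% 2L) + 1L)
    y <- EBImage::gblur(x, sigma = r, radius = rad, boundary = "replicate")
    matrix(as.numeric(y), nrow(x))
  }
  w <- blur(matrix(as.numeric(mask), nrow(mask)), rHigh)
  w <- pmin(pmax(w / max(w), 0), 1)
  # suppress metal before the frequency split: otherwise the blurred tail
  # of the (several-thousand-HU) metal leaks a large negative halo into
  # the high-pass band around the implant
  o2 <- o$img
  o2[mask] <- m$img[mask]
  lowMar <- blur(m$img, rLow)
  highOrig <- o2 - blur(o2, rLow)
  out <- w * (lowMar + highOrig) + (1 - w) * m$img
  ctVolume(out, spacing = spacing(marImage))
}

# ---- end-to-end pipeline --------------------------------------------------

#' Run a sinogram-domain MAR baseline on one slice
#'
#' The full virtual-sinogram pipeline: segment metal in image space,
#' forward-project image and metal map, in-paint the metal trace with the
#' chosen algorithm, reconstruct by FBP, and re-insert the original metal
#' voxels inside the mask (FSMAR additionally blends frequencies before
#' re-insertion; its in-painting base is NMAR).
#'
#' @param slice a square single-slice [CTVolume-class].
#' @param algorithm one of `"li"`, `"bi"`, `"nmar"`, `"fsmar"`.
#' @param threshold metal threshold in HU.
#' @param nAngles projection angles of the virtual sinogram.
#' @param rLow,rHigh FSMAR Gaussian radii (pixels).
#' @return the corrected single-slice [CTVolume-class].
#' @export
runMar <- function(slice, algorithm = c("li", "bi", "nmar", "fsmar"),
                   threshold = 2000, nAngles = 360L, rLow = 3, rHigh = 30) {
  algorithm <- match.arg(algorithm)
  s0 <- asSliceMatrix(slice)
  g <- marGeometry(nrow(s0$img), s0$px, nAngles)
  mask <- segmentMetal(slice, threshold)
  sin0 <- virtualSinogram(slice, geometry = g)
  trace <- metalTrace(mask, s0$px, g)
  corrected <- switch(algorithm,
    li = liMar(sin0, trace),
    bi = biMar(sin0, trace),
    nmar = ,
    fsmar = nmar(sin0, trace, nmarPrior(slice, metalThreshold = threshold),
                 geometry = g))
  rec <- fbpReconstruct(corrected, outSpacing = s0$px,
                        outDim = nrow(s0$img),
                        sliceSpacing = spacing(slice)[3])
  if (algorithm == "fsmar")
    rec <- fsMar(slice, rec, mask, rLow = rLow, rHigh = rHigh)
  img <- rec@values[, , 1]
  img[mask] <- s0$img[mask]  # metal re-insertion
  ctVolume(img, spacing = spacing(slice), origin = origin(slice))
}
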