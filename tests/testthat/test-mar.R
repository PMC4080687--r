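# Shared small reconstruction for the MAR baselines (computed once).
marFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gammexSlice(n = 160, spacing = 0.208,
                                              seed = 13L)
    cache
  }
})

test_that("virtual sinogram basics: emptiness, symmetry, round trip", {
  air <- ctVolume(matrix(-1000, 64, 64), spacing = 0.2)
  s <- virtualSinogram(air, nAngles = 48L)
  expect_true(all(sinogramData(s) == 0))

  # centered disc: every projection row identical (rotational symmetry)
  disc <- idealRendering(waterDiscPhantom(n = 64, spacing = 0.2, radius = 4))
  sd_ <- virtualSinogram(disc, nAngles = 48L)
  rows <- sinogramData(sd_)
  expect_lt(max(apply(rows, 2, function(cc) diff(range(cc)))),
            0.05 * max(rows))

  # round trip: reconstruct the virtual sinogram back to the image
  img <- idealRendering(makeGammexPhantom(insertSpec = list(), n = 128,
                                          spacing = 0.26))
  s2 <- virtualSinogram(img, nAngles = 360L)
  rec <- fbpReconstruct(s2, outSpacing = 0.26, outDim = 128)
  a <- axialSlice(img); b <- axialSlice(rec)
  n <- 128
  r <- sqrt(outer((seq_len(n) - (n + 1) / 2)^2,
                  (seq_len(n) - (n + 1) / 2)^2, "+")) * 0.26
  interior <- r < 14  # away from the disc edge
  edge <- abs(r - 16.5) < 1
  rms <- sqrt(mean((a[interior & !edge] - b[interior & !edge])^2))
  expect_lt(rms, 20)
})

test_that("metal segmentation and traces", {
  f <- marFixture()
  expect_false(any(segmentMetal(ctVolume(matrix(1500, 8, 8), spacing = 0.1))))
  mask <- segmentMetal(f$ideal)
  expect_equal(max(EBImage::bwlabel(mask)), 1)
  # mask is co-located with the phantom's titanium insert
  ti <- which(vapply(f$phantom@materials, function(m) m@name, "") == "titanium")
  expect_gt(sum(mask & (f$phantom@labels == ti)) / sum(mask), 0.95)
  # six components on the dental slice
  dent <- idealRendering(makeDentalPhantom(n = 256, spacing = 0.13))
  expect_equal(max(EBImage::bwlabel(segmentMetal(dent))), 6)
  # the trace flags exactly the rays meeting the mask support
  g <- tiltmar:::marGeometry(160, 0.208, 90L)
  tr <- metalTrace(mask, 0.208, g)
  s <- virtualSinogram(ctVolume(matrix(as.numeric(mask) * 4000 - 1000,
                                       160, 160), spacing = 0.208),
                       geometry = g)
  expect_true(all(tr[sinogramData(s) > 0.05]))
})

test_that("LI-MAR: identity off-trace, exact on affine rows", {
  f <- marFixture()
  g <- tiltmar:::marGeometry(160, 0.208, 60L)
  s <- virtualSinogram(f$volume, geometry = g)
  empty <- matrix(FALSE, nrow(sinogramData(s)), ncol(sinogramData(s)))
  expect_identical(sinogramData(liMar(s, empty)), sinogramData(s))

  # affine row with a gap: linear interpolation restores it exactly
  nd <- 40
  dat <- matrix(rep(2 + 0.3 * seq_len(nd), each = 30), 30, nd)
  sa <- new("Sinogram", data = dat,
            angles = seq(0, 180, length.out = 31)[1:30], detSpacing = 0.1)
  tr <- matrix(FALSE, 30, nd); tr[, 15:22] <- TRUE
  out <- liMar(sa, tr)
  expect_equal(sinogramData(out), dat, tolerance = 1e-12)
  expect_identical(sinogramData(out)[!tr], dat[!tr])
  # a fully traced row is a hard error naming the angle
  trAll <- tr; trAll[3, ] <- TRUE
  expect_error(liMar(sa, trAll), "angle 12")

  # interpolation error is bounded by the row's curvature on real data
  tr2 <- matrix(FALSE, nrow(sinogramData(s)), ncol(sinogramData(s)))
  tr2[, 100:106] <- TRUE
  fixed <- liMar(s, tr2)
  err <- abs(sinogramData(fixed) - sinogramData(s))[tr2]
  d2 <- abs(diff(t(sinogramData(s)[, 95:112]), differences = 2))
  expect_lt(max(err), 8^2 / 8 * max(d2) + 1e-9)
})

test_that("BI-MAR: identity, constancy, and beating LI on cross-structure", {
  nd <- 30; na <- 24
  angles <- seq(0, 180, length.out = na + 1)[1:na]
  const <- new("Sinogram", data = matrix(5, na, nd), angles = angles,
               detSpacing = 0.1)
  tr <- matrix(FALSE, na, nd); tr[10:14, 12:18] <- TRUE
  expect_identical(sinogramData(biMar(const, matrix(FALSE, na, nd))),
                   sinogramData(const))
  filled <- biMar(const, tr)
  expect_equal(sinogramData(filled)[tr], rep(5, sum(tr)))
  expect_identical(sinogramData(filled)[!tr], sinogramData(const)[!tr])

  # affine along the detector axis, constant along angle: the normalized
  # inverse-distance fill is exact (row neighbours interpolate the affine
  # trend, column neighbours contribute the same affine value)
  dat <- matrix(rep(seq_len(nd), each = na), na, nd)
  sa <- new("Sinogram", data = dat, angles = angles, detSpacing = 0.1)
  tr2 <- matrix(FALSE, na, nd); tr2[8:12, 10:20] <- TRUE
  bi <- sinogramData(biMar(sa, tr2))
  expect_equal(bi[tr2], dat[tr2], tolerance = 1e-12)
  # a bin with no untraced neighbour anywhere errors
  trBad <- matrix(TRUE, na, nd)
  expect_error(biMar(sa, trBad), "no untraced neighbour")
})

test_that("NMAR: flat prior reduces to LI; empty trace is identity", {
  f <- marFixture()
  g <- tiltmar:::marGeometry(160, 0.208, 60L)
  s <- virtualSinogram(f$volume, geometry = g)
  mask <- segmentMetal(f$volume)
  tr <- metalTrace(mask, 0.208, g)
  # an all-air prior floors to a constant sinogram -> exact LI behaviour
  flat <- ctVolume(matrix(-1000, 160, 160), spacing = 0.208)
  expect_equal(sinogramData(nmar(s, tr, flat, g, priorFloor = 1)),
               sinogramData(liMar(s, tr)), tolerance = 1e-12)
  empty <- matrix(FALSE, nrow(tr), ncol(tr))
  expect_identical(sinogramData(nmar(s, empty, nmarPrior(f$volume), g)),
                   sinogramData(s))
  # untraced bins never change
  out <- nmar(s, tr, nmarPrior(f$volume), g)
  expect_identical(sinogramData(out)[!tr], sinogramData(s)[!tr])
})

test_that("NMAR with the true object as prior restores the trace", {
  # metal-free truth: the prior equal to the object makes the normalized
  # sinogram ~1, so in-painting is near-exact on the trace
  p0 <- makeGammexPhantom(insertSpec = list(), n = 128, spacing = 0.26)
  truth <- idealRendering(p0)
  g <- tiltmar:::marGeometry(128, 0.26, 90L)
  s <- virtualSinogram(truth, geometry = g)
  tr <- matrix(FALSE, 90, g$nDet); tr[, 60:75] <- TRUE
  out <- nmar(s, tr, truth, g)
  expect_equal(sinogramData(out)[tr], sinogramData(s)[tr], tolerance = 0.02)
})

test_that("FSMAR blending identities and edge preservation", {
  f <- marFixture()
  img <- f$volume
  other <- ctVolume(axialSlice(img) + 50, spacing = spacing(img))
  # no metal -> exactly the MAR image
  expect_identical(axialSlice(fsMar(img, other, matrix(FALSE, 160, 160))),
                   axialSlice(other))
  # full-mask blend of an image with itself is the image
  full <- matrix(TRUE, 160, 160)
  out <- fsMar(img, img, full)
  expect_equal(axialSlice(out), axialSlice(img), tolerance = 1e-8)

  # a sharp edge blurred away in the MAR image is restored near metal
  n <- 96
  edge <- matrix(0, n, n); edge[, 49:n] <- 400
  orig <- ctVolume(edge, spacing = 0.1)
  blurred <- ctVolume(matrix(as.numeric(EBImage::gblur(edge, sigma = 4,
                                                       radius = 25)), n),
                      spacing = 0.1)
  mask <- matrix(FALSE, n, n); mask[44:52, 44:52] <- TRUE
  out2 <- axialSlice(fsMar(orig, blurred, mask))
  gradAt <- function(m) max(abs(m[, 49] - m[, 48]))
  expect_gt(gradAt(out2), 0.8 * gradAt(edge))
})

test_that("end-to-end pipeline: identity without metal, improvement with", {
  f <- marFixture()
  # metal-free slice passes through within round-trip tolerance
  p0 <- makeGammexPhantom(insertSpec = list(), n = 160, spacing = 0.208)
  clean <- idealRendering(p0)
  out0 <- runMar(clean, "li", nAngles = 360L)
  n <- 160
  r <- sqrt(outer((seq_len(n) - (n + 1) / 2)^2,
                  (seq_len(n) - (n + 1) / 2)^2, "+")) * 0.208
  sel <- r < 14
  expect_lt(sqrt(mean((axialSlice(out0)[sel] - axialSlice(clean)[sel])^2)),
            20)

  roi <- ringRoi(f$volume, center = c(10, 0, 0), rInner = 1.8, rOuter = 2.6,
                 slab = 0.2)
  before <- evaluateRoi(f$volume, roi, c = 11)
  ti <- which(vapply(f$phantom@materials, function(m) m@name, "") ==
                "titanium")
  tiPix <- f$phantom@labels == ti
  for (alg in c("li", "bi", "nmar", "fsmar")) {
    out <- runMar(f$volume, alg)
    after <- evaluateRoi(out, roi, c = 11)
    expect_lt(after$error, before$error)
    # metal re-insertion keeps titanium the brightest structure
    expect_equal(axialSlice(out)[tiPix], axialSlice(f$volume)[tiPix])
    expect_gt(min(axialSlice(out)[tiPix]),
              max(axialSlice(out)[r < 14 & !tiPix]))
  }
})
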