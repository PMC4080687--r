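test_that("identity resample reproduces the volume exactly", {
  v <- randomVolume(c(7, 6, 5), seed = 4)
  out <- resample(v, rigidTransform())
  expect_identical(voxelData(out)[coverage(out)], voxelData(v)[coverage(v)])
  expect_identical(coverage(out), coverage(v))
})

test_that("lattice-preserving 90-degree rotation is an exact permutation", {
  v <- ctVolume(array(rnorm(6^3), c(6, 6, 6)), spacing = 0.2)
  out <- resample(v, axisAngleTransform(c(0, 0, 1), 90))
  a <- voxelData(v); b <- voxelData(out)
  # rotating the volume by +90 deg about z maps voxel (i, j) -> (-j, i),
  # so the output pulls from a[j, n+1-i]
  for (k in 1:6)
    expect_equal(b[, , k], t(a[, , k][, 6:1]), tolerance = 1e-12)
  expect_true(all(coverage(out)))
})

test_that("tri-linear resampling is exact on affine fields", {
  d <- c(12, 11, 10)
  sp <- c(0.12, 0.1, 0.15)
  coef <- c(7, 40, -25, 12)
  mk <- function(dim, spacing) {
    g <- gridSpec(dim, spacing)
    idx <- as.matrix(expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                                 z = seq_len(dim[3])))
    pts <- sweep(sweep(idx - 1, 2, spacing, "*"), 2, g$origin, "+")
    list(grid = g, pts = pts)
  }
  src <- mk(d, sp)
  f <- function(p) coef[1] + p[, 1] * coef[2] + p[, 2] * coef[3] +
    p[, 3] * coef[4]
  v <- ctVolume(array(f(src$pts), d), spacing = sp)
  t <- axisAngleTransform(c(1, -2, 0.7), 33, translation = c(0.21, -0.08, 0.13))
  tgt <- mk(c(10, 10, 9), c(0.11, 0.13, 0.12))
  out <- resample(v, t, gridSpec(c(10, 10, 9), c(0.11, 0.13, 0.12)))
  # where covered, values equal the affine field transported by t
  truth <- f(applyTransform(invertTransform(t), tgt$pts))
  cov <- as.vector(coverage(out))
  expect_gt(sum(cov), 100)
  expect_equal(as.vector(voxelData(out))[cov], truth[cov], tolerance = 1e-10)
})

test_that("tri-linear kernel matches the 8-corner brute-force oracle", {
  set.seed(9)
  for (rep in 1:4) {
    v <- randomVolume(c(5, 6, 4), seed = 30 + rep,
                      coverProb = if (rep > 2) 0.85 else 1)
    shift <- runif(3, -0.9, 0.9) * spacing(v)
    t <- rigidTransform(diag(3), shift)
    out <- resample(v, t)
    d <- dim(v)
    for (probe in 1:25) {
      idx <- c(sample(d[1], 1), sample(d[2], 1), sample(d[3], 1))
      # source fractional index of this target voxel under the inverse map,
      # computed from world coordinates exactly as the contract states
      w <- origin(v) + (idx - 1) * spacing(v)
      frac <- ((w - shift) - origin(v)) / spacing(v)
      expected <- trilinearOracle(voxelData(v), coverage(v),
                                  frac[1], frac[2], frac[3])
      got <- voxelData(out)[idx[1], idx[2], idx[3]]
      if (is.na(expected)) {
        expect_false(coverage(out)[idx[1], idx[2], idx[3]])
      } else {
        expect_identical(got, expected)
      }
    }
  }
})

test_that("forward/backward resampling round trip is tight on smooth data", {
  n <- 16
  g <- seq(-1.5, 1.5, length.out = n)
  f <- outer(g, g, function(x, y) 100 * exp(-(x^2 + y^2)))
  v <- ctVolume(array(rep(f, 8), c(n, n, 8)), spacing = 0.2)
  t <- axisAngleTransform(c(0, 0, 1), 23, translation = c(0.07, -0.03, 0.04))
  fwd <- resample(v, t)
  back <- resample(fwd, invertTransform(t))
  both <- coverage(back) & coverage(v)
  rms <- sqrt(mean((voxelData(back)[both] - voxelData(v)[both])^2))
  expect_lt(rms, 1.5)  # interpolation error of a smooth field
  # coverage is conservative: nothing outside the source support is covered
  expect_true(all(both | !coverage(back)))
})

test_that("sub-voxel translation refinement recovers a known shift", {
  n <- 24
  g <- seq(-2, 2, length.out = n)
  base <- outer(g, g, function(x, y) 200 * sin(2 * x) * cos(3 * y))
  v <- ctVolume(array(rep(base, 6), c(n, n, 6)), spacing = 0.1)
  expect_equal(translation(refineTranslation(v, v, axes = 1:2)), c(0, 0, 0))

  shift <- c(0.3, 0, 0) * 0.1  # 0.3 voxel along x
  fixed <- resample(v, rigidTransform(diag(3), shift))
  est <- refineTranslation(v, fixed, axes = 1)
  expect_equal(translation(est)[1], shift[1], tolerance = 0.1 * 0.1)
  expect_gt(attr(est, "ncc"), 0.99)
})

test_that("degenerate refinement inputs raise errors", {
  flat <- ctVolume(array(5, c(6, 6, 3)))
  expect_error(refineTranslation(flat, flat), "degenerate|undefined")
  noiseA <- randomVolume(c(6, 6, 3), seed = 1)
  noiseB <- randomVolume(c(6, 6, 3), seed = 2)
  expect_error(refineTranslation(noiseA, noiseB, minNcc = 0.9),
               "below floor")
})
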