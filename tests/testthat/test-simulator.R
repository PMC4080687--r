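test_that("monochromatic noiseless projection matches analytic chords", {
  p <- waterDiscPhantom(n = 96, spacing = 0.1, radius = 4)
  cfg <- smallAcquisition(p)
  s <- forwardProject(p, spect = monoSpectrum(80), cfg = cfg)
  muw <- linearAttenuation(materialTable()$water, 80)
  # central ray crosses the full 8 cm diameter
  mid <- (cfg@nDetectors + 1) / 2
  expect_equal(max(sinogramData(s)[, mid]), muw * 8, tolerance = 0.02)
  # rays fully outside the disc integrate to ~0 (air is ~vacuum here)
  expect_lt(max(sinogramData(s)[, 1]), 1e-3)
  # off-center ray at offset t has chord 2*sqrt(r^2 - t^2)
  t <- 2.6
  d <- round(mid + t / cfg@detSpacing)
  toff <- (d - mid) * cfg@detSpacing
  expect_equal(sinogramData(s)[1, d], muw * 2 * sqrt(16 - toff^2),
               tolerance = 0.04)
})

test_that("projection agrees with an independent ray-marching oracle", {
  p <- makeGammexPhantom(n = 48, spacing = 0.7)  # coarse, <=64^2 grid
  cfg <- smallAcquisition(p, nAngles = 8L)
  s <- forwardProject(p, spect = monoSpectrum(80), cfg = cfg,
                      stepFrac = 0.1)
  mu <- vapply(p@materials, linearAttenuation, 0, energy = 80)
  mid <- (cfg@nDetectors + 1) / 2
  for (a in c(1, 3, 6)) for (d in seq(5, cfg@nDetectors - 4, by = 11)) {
    oracle <- rayIntegralOracle(p@labels, mu, p@spacing,
                                projectionAngles(s)[a],
                                (d - mid) * cfg@detSpacing)
    expect_equal(sinogramData(s)[a, d], oracle,
                 tolerance = max(0.04, 0.3 / max(oracle, 1)))
  }
})

test_that("empty phantom projects to zero and reconstructs to air", {
  p <- phantomImage(list(), n = 32, spacing = 0.4)
  cfg <- smallAcquisition(p, nAngles = 48L)
  s <- forwardProject(p, spect = monoSpectrum(80), cfg = cfg)
  # nothing but ambient air: line integrals are a few 1e-3 at most
  expect_lt(max(abs(sinogramData(s))), 0.01)
  rec <- fbpReconstruct(s, outSpacing = 0.4, outDim = 32)
  expect_lt(max(abs(voxelData(rec) + 1000)), 2.5)
})

test_that("beam hardening: effective attenuation drops with path length", {
  # closed-form two-bin Beer-Lambert through titanium
  ti <- materialTable()$titanium
  sp <- spectrum(c(60, 100), c(0.5, 0.5))
  mu <- linearAttenuation(ti, sp@energies)
  effMu <- function(L) -log(sum(sp@weights * exp(-mu * L))) / L
  expect_lt(effMu(2), effMu(0.5))
  expect_lt(effMu(4), effMu(2))

  # and the simulator reproduces the closed form
  p <- phantomImage(list(tiltmar:::shapeDisc("titanium", c(0, 0), 1)),
                    n = 40, spacing = 0.2)
  cfg <- smallAcquisition(p, nAngles = 4L)
  s <- forwardProject(p, spect = sp, cfg = cfg)
  mid <- (cfg@nDetectors + 1) / 2
  got <- sinogramData(s)[1, mid]
  expect_equal(got, effMu(2) * 2, tolerance = 0.03)
})

test_that("FBP calibration: water disc reconstructs to ~0 HU", {
  p <- waterDiscPhantom(n = 128, spacing = 0.1, radius = 5)
  cfg <- acquisitionConfig(mAs = Inf, nAngles = 360L, nDetectors = 183L,
                           detSpacing = 0.1)
  rec <- fbpReconstruct(forwardProject(p, spect = monoSpectrum(80),
                                       cfg = cfg),
                        outSpacing = 0.1, outDim = 128)
  img <- axialSlice(rec)
  r <- sqrt(outer((seq_len(128) - 64.5)^2, (seq_len(128) - 64.5)^2, "+")) * 0.1
  expect_lt(abs(mean(img[r < 4])), 15)
  expect_equal(mean(img[r > 6.4]), -1000, tolerance = 0.02)
  # all-zero sinogram reconstructs to uniform air
  s0 <- new("Sinogram", data = matrix(0, 90, 64),
            angles = seq(0, 180, length.out = 91)[1:90], detSpacing = 0.1)
  expect_lt(max(abs(voxelData(fbpReconstruct(s0, outDim = 32)) + 1000)),
            1e-9)
})

test_that("severe angular undersampling warns", {
  p <- waterDiscPhantom(n = 24, spacing = 0.4, radius = 3)
  cfg <- smallAcquisition(p, nAngles = 8L)
  s <- forwardProject(p, spect = monoSpectrum(80), cfg = cfg)
  expect_warning(fbpReconstruct(s, outDim = 24), "undersampling")
})

test_that("water precorrection flattens polychromatic cupping", {
  p <- waterDiscPhantom(n = 128, spacing = 0.26, radius = 14)
  cfg <- acquisitionConfig(mAs = Inf, nAngles = 240L, nDetectors = 187L,
                           detSpacing = 0.26)
  s <- forwardProject(p, cfg = cfg)  # polychromatic default spectrum
  raw <- axialSlice(fbpReconstruct(s, outSpacing = 0.26, outDim = 128))
  cor <- axialSlice(fbpReconstruct(waterPrecorrect(s), outSpacing = 0.26,
                                   outDim = 128))
  r <- sqrt(outer((seq_len(128) - 64.5)^2, (seq_len(128) - 64.5)^2, "+")) * 0.26
  # uncorrected: center depressed relative to rim (cupping) and the whole
  # disc offset from 0 HU; corrected: flat and on-scale
  cup <- function(img) mean(img[r < 3]) - mean(img[r > 10 & r < 13])
  expect_lt(abs(cup(cor)), 0.5 * abs(cup(raw)))
  expect_lt(abs(mean(cor[r < 10])), 0.5 * abs(mean(raw[r < 10])))
  expect_lt(abs(mean(cor[r < 10])), 6)
})

test_that("Poisson noise is seeded, deterministic and dose-scaled", {
  p <- waterDiscPhantom(n = 48, spacing = 0.3, radius = 5)
  cfg <- smallAcquisition(p, mAs = 100, nAngles = 60L, seed = 42L)
  s1 <- forwardProject(p, cfg = cfg)
  s2 <- forwardProject(p, cfg = cfg)
  expect_identical(sinogramData(s1), sinogramData(s2))
  cfg2 <- cfg; cfg2@noiseSeed <- 43L
  expect_false(identical(sinogramData(s1),
                         sinogramData(forwardProject(p, cfg = cfg2))))
})

test_that("reconstructed noise scales as 1/sqrt(N0)", {
  p <- waterDiscPhantom(n = 64, spacing = 0.3, radius = 7)
  # deterministic structure (edge ripple, discretization) is removed by
  # subtracting the noiseless reconstruction, isolating the Poisson part
  det <- fbpReconstruct(forwardProject(p, cfg = smallAcquisition(
    p, mAs = Inf, nAngles = 120L)), outSpacing = 0.3, outDim = 64)
  noiseAt <- function(mAs, seeds) {
    mean(vapply(seeds, function(sd) {
      cfg <- smallAcquisition(p, mAs = mAs, nAngles = 120L,
                              seed = as.integer(sd))
      rec <- fbpReconstruct(forwardProject(p, cfg = cfg),
                            outSpacing = 0.3, outDim = 64)
      stoch <- ctVolume(voxelData(rec) - voxelData(det), spacing = 0.3)
      evaluateRoi(stoch, ringRoi(stoch, rInner = 0.5, rOuter = 1.6,
                                 slab = 0.3), c = 0)$noise
    }, 0))
  }
  lo <- noiseAt(20, 1:6)
  hi <- noiseAt(200, 1:6)
  expect_equal(lo / hi, sqrt(10), tolerance = 0.10)
})

test_that("metal insert triples ring error over the metal-free scan", {
  withMetal <- gammexSlice(seed = 3L)
  p0 <- makeGammexPhantom(insertSpec = list(), n = 160, spacing = 0.208)
  cfg <- acquisitionConfig(nAngles = 240L,
                           nDetectors = as.integer(ceiling(160 * sqrt(2))) + 1L,
                           detSpacing = 0.208, noiseSeed = 3L)
  rec0 <- fbpReconstruct(forwardProject(p0, cfg = cfg), outSpacing = 0.208,
                         outDim = 160)
  roi <- ringRoi(withMetal$volume, center = c(10, 0, 0), rInner = 1.8,
                 rOuter = 2.6, slab = 0.2)
  mWith <- evaluateRoi(withMetal$volume, roi, c = 11)
  mWithout <- evaluateRoi(rec0, roi, c = 11)
  expect_gt(mWith$error, 3 * mWithout$error)
  expect_gt(mWith$noise, 3 * mWithout$noise)
})

test_that("tilted series geometry, transforms and dose splitting", {
  p <- makeGammexPhantom(n = 64, spacing = 0.52)
  cfg <- smallAcquisition(p, mAs = 80, nAngles = 60L, seed = 9L)
  ser <- simulateTiltedSeries(p, c(0, 45), cfg, nSlices = 3L,
                              focus = c(10, 0, 0), outDim = 64)
  expect_length(ser, 2)
  expect_equal(ser[[1]]$tiltAngle, 0)
  expect_equal(rotation(ser[[2]]$transform),
               rotation(axisAngleTransform(c(0, 1, 0), -45)))
  # split dose over n scans is bit-identical to full mode at mAs/n
  sSplit <- simulateTiltedSeries(p, c(0, 45), cfg, nSlices = 1L,
                                 doseMode = "split", outDim = 64)
  cfgHalf <- cfg; cfgHalf@mAs <- cfg@mAs / 2
  sHalf <- simulateTiltedSeries(p, c(0, 45), cfgHalf, nSlices = 1L,
                                doseMode = "full", outDim = 64)
  expect_identical(voxelData(sSplit[[1]]$volume),
                   voxelData(sHalf[[1]]$volume))
  expect_identical(voxelData(sSplit[[2]]$volume),
                   voxelData(sHalf[[2]]$volume))
  expect_error(simulateTiltedSeries(p, c(0, 0), cfg), "distinct")
})

test_that("tilted scans carry complementary artifacts after registration", {
  # two tilts of the standard phantom: artifact-only images should agree
  # far less between scans than the underlying anatomy does
  p <- makeGammexPhantom(n = 96, spacing = 0.35)
  cfg <- smallAcquisition(p, mAs = 200, nAngles = 120L, seed = 21L)
  ser <- simulateTiltedSeries(p, c(0, 60), cfg, focus = c(10, 0, 0),
                              coverRadius = 2.8, coverHalfZ = 0.3,
                              outDim = 96)
  tgt <- gridSpec(c(96, 96, 3), c(0.35, 0.35, 0.2),
                  origin = c(-(95) / 2 * 0.35, -(95) / 2 * 0.35, -0.2))
  reg <- lapply(ser, function(s) resample(s$volume, s$transform, tgt))
  ideal <- axialSlice(idealRendering(p))
  roi <- ringRoi(reg[[1]], center = c(10, 0, 0), rInner = 1.2, rOuter = 2.4,
                 slab = 0.5)
  art <- lapply(reg, function(v) voxelData(v)[roi@indices] -
                  rep(ideal, 3)[roi@indices])
  img <- lapply(reg, function(v) voxelData(v)[roi@indices])
  # the artifact-only images agree far less across scans than the
  # reconstructions themselves (whose correlation is anatomy-dominated)
  expect_lt(cor(art[[1]], art[[2]]), 0.95 * cor(img[[1]], img[[2]]))
})
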