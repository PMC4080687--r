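# A deliberately small experiment so the full driver runs in seconds.
tinyConfig <- function(seed = 3, angles = c(0, 60), dose = "full") {
  list(version = 1,
       phantom = list(type = "gammex", n = 96, spacing = 0.35),
       angles = angles,
       dose = list(mode = dose),
       mAs = 200, seed = seed,
       combine = list("median", "mean"),
       roi = list(type = "ring", center = c(10, 0, 0), rInner = 1.4,
                  rOuter = 2.4, slab = 0.3, c = 11))
}

test_that("config validation reports the offending field", {
  expect_error(readExperimentConfig(list(version = 1)), "phantom.type")
  bad <- tinyConfig(); bad$angles <- c(0, 0)
  expect_error(readExperimentConfig(bad), "angles")
  bad2 <- tinyConfig(); bad2$roi$c <- NULL
  expect_error(readExperimentConfig(bad2), "roi.c")
  bad3 <- tinyConfig(); bad3$combine <- list("max")
  expect_error(readExperimentConfig(bad3), "combine")
  bad4 <- tinyConfig(); bad4$tiltAxis <- "diagonal"
  expect_error(readExperimentConfig(bad4), "tiltAxis")
  # YAML round trip
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(tinyConfig(), f)
  cfg <- readExperimentConfig(f)
  expect_equal(cfg$phantom$n, 96)
})

test_that("cmdSimulate writes one deterministic series per angle", {
  cfg <- tinyConfig(angles = c(0, 45, 90))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cmdSimulate(cfg, d1)
  expect_setequal(basename(list.dirs(d1, recursive = FALSE)),
                  c("scan_01", "scan_02", "scan_03"))
  expect_length(list.files(d1, pattern = "transform_\\d+\\.txt"), 3)
  # determinism: identical config + seed give bit-identical outputs
  cmdSimulate(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readBin(f1[i], raw(), file.size(f1[i])),
                     readBin(f2[i], raw(), file.size(f2[i])))
})

test_that("pipeline report structure and k=1 consistency", {
  cfg <- tinyConfig()
  series <- runSimulation(cfg)
  res <- runPipeline(cfg, series)
  r <- res$report
  expect_true(all(c("method", "k", "bias", "error", "noise", "n", "c",
                    "seed") %in% names(r)))
  expect_setequal(unique(r$method), c("single", "median", "mean"))
  # k = 1 combination equals the first single scan
  for (m in c("median", "mean")) {
    expect_equal(r[r$method == m & r$k == 1, c("bias", "error", "noise")],
                 r[r$method == "single" & r$k == 1,
                   c("bias", "error", "noise")],
                 ignore_attr = TRUE)
  }
  expect_true(all(r$c == 11))
  expect_true(all(r$seed == 3))
  expect_s4_class(res$combined$median, "CombinedVolume")
})

test_that("cmdPipeline consumes cmdSimulate output end to end", {
  cfg <- tinyConfig(angles = c(0, 60))
  d <- withr::local_tempdir(); out <- withr::local_tempdir()
  cmdSimulate(cfg, d)
  rep1 <- cmdPipeline(cfg, d, out)
  expect_true(file.exists(file.path(out, "report.csv")))
  expect_true(dir.exists(file.path(out, "combined_median")))
  got <- read.csv(file.path(out, "report.csv"))
  expect_equal(nrow(got), 2 + 2 * 2)  # singles + 2 methods x k=1..2
  # the written combined volume reads back as the in-memory result
  # (up to the 16-bit DICOM quantization step)
  series <- runSimulation(cfg)
  res <- runPipeline(cfg, series)
  back <- readDicomSeries(file.path(out, "combined_median"))
  mem <- res$combined$median
  cov <- coverage(mem)
  expect_lt(max(abs(voxelData(back)[cov] - voxelData(mem)[cov])), 1.01)
})

test_that("split-dose config produces per-scan dose mAs/n", {
  cfg <- tinyConfig(angles = c(0, 45), dose = "split")
  sSplit <- runSimulation(cfg)
  cfgHalf <- cfg; cfgHalf$dose$mode <- "full"; cfgHalf$mAs <- cfg$mAs / 2
  sHalf <- runSimulation(cfgHalf)
  expect_identical(voxelData(sSplit[[1]]$volume),
                   voxelData(sHalf[[1]]$volume))
})
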