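# Shared fixtures and independent brute-force oracles.

# Deterministic random volume on a given grid.
randomVolume <- function(dim = c(6, 5, 4), spacing = 0.1, seed = 1,
                         coverProb = 1) {
  set.seed(seed)
  vals <- array(rnorm(prod(dim), 50, 120), dim)
  cov <- array(runif(prod(dim)) <= coverProb, dim)
  vals[!cov] <- NA_real_
  ctVolume(vals, spacing = spacing, coverage = cov)
}

# Brute-force tri-linear sampling oracle: explicit 8-corner weighted sum at
# one source-grid fractional index, NA if any corner carrying weight is out
# of grid or uncovered. Shares the contract's conventions (near-integer
# indices snap onto the lattice; zero-weight corners are outside the
# stencil) but is written independently of the package's kernel.
trilinearOracle <- function(vals, cov, fx, fy, fz) {
  snap <- function(f) if (abs(f - round(f)) < 1e-9) round(f) else f
  fx <- snap(fx); fy <- snap(fy); fz <- snap(fz)
  d <- dim(vals)
  if (fx < 0 || fy < 0 || fz < 0 ||
      fx > d[1] - 1 || fy > d[2] - 1 || fz > d[3] - 1) return(NA_real_)
  x0 <- min(floor(fx), d[1] - 2); y0 <- min(floor(fy), max(d[2] - 2, 0))
  z0 <- min(floor(fz), max(d[3] - 2, 0))
  ax <- fx - x0; ay <- fy - y0; az <- fz - z0
  acc <- 0
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    xi <- x0 + cx + 1; yi <- min(y0 + cy + 1, d[2]); zi <- min(z0 + cz + 1, d[3])
    w <- (if (cx) ax else 1 - ax) * (if (cy) ay else 1 - ay) *
         (if (cz) az else 1 - az)
    if (w == 0) next
    if (!cov[xi, yi, zi]) return(NA_real_)
    acc <- acc + w * vals[xi, yi, zi]
  }
  acc
}

# Per-voxel sort-based median oracle over a list of volumes with coverage.
medianStackOracle <- function(vols) {
  d <- dim(vols[[1]]@values)
  out <- array(NA_real_, d)
  n <- array(0L, d)
  for (i in seq_len(prod(d))) {
    xs <- unlist(lapply(vols, function(v)
      if (v@coverage[i]) v@values[i] else NULL))
    n[i] <- length(xs)
    if (length(xs) > 0) {
      s <- sort(xs)
      m <- length(s)
      out[i] <- if (m %% 2 == 1) s[(m + 1) / 2]
                else (s[m / 2] + s[m / 2 + 1]) / 2
    }
  }
  list(values = out, n = n)
}

# Two-pass textbook sample standard deviation.
sdTwoPass <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Independent ray-marching line integral through a label image (R loop,
# fine step, nearest-neighbour lookup) for one parallel ray.
rayIntegralOracle <- function(labels, mu, px, angleDeg, tOffset,
                              step = px / 20) {
  n <- nrow(labels)
  th <- angleDeg * pi / 180
  half <- n * px
  ss <- seq(-half, half, by = step)
  wx <- tOffset * cos(th) - ss * sin(th)
  wy <- tOffset * sin(th) + ss * cos(th)
  ix <- round(wx / px + (n - 1) / 2) + 1
  iy <- round(wy / px + (n - 1) / 2) + 1
  ok <- ix >= 1 & ix <= n & iy >= 1 & iy <= n
  sum(mu[labels[cbind(ix[ok], iy[ok])]]) * step
}

# Small water-disc phantom for projector tests.
waterDiscPhantom <- function(n = 64, spacing = 0.2, radius = 4) {
  phantomImage(list(tiltmar:::shapeDisc("water", c(0, 0), radius)),
               n = n, spacing = spacing)
}

# Fast acquisition settings matched to a small phantom raster.
smallAcquisition <- function(p, mAs = Inf, nAngles = 180L, seed = 1L) {
  acquisitionConfig(mAs = mAs, nAngles = nAngles,
                    nDetectors = as.integer(ceiling(nrow(p@labels) * 1.45)),
                    detSpacing = p@spacing, noiseSeed = seed)
}

# Ring-ROI metrics of one simulated Gammex-like slice (shared by simulator
# and MAR tests); idealHU gives the matching ground truth.
gammexSlice <- function(n = 160, spacing = 0.208, mAs = 200, seed = 7L,
                        nAngles = 240L) {
  p <- makeGammexPhantom(n = n, spacing = spacing)
  cfg <- acquisitionConfig(mAs = mAs, nAngles = nAngles,
                           nDetectors = as.integer(ceiling(n * sqrt(2))) + 1L,
                           detSpacing = spacing, noiseSeed = seed)
  rec <- fbpReconstruct(forwardProject(p, cfg = cfg), outSpacing = spacing,
                        outDim = n)
  list(phantom = p, volume = rec, ideal = idealRendering(p))
}
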