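test_that("toy densities are deterministic, class-distinct and nonnegative", {
  a <- makeToyDensity("sphere", n = 16, seed = 1)
  b <- makeToyDensity("sphere", n = 16, seed = 1)
  expect_identical(volumeData(a), volumeData(b))
  expect_true(all(volumeData(a) >= 0))
  d <- makeToyDensity("dumbbell", n = 16, seed = 1)
  expect_false(identical(volumeData(a), volumeData(d)))
  # second moments about the center of mass differ between classes
  mom2 <- function(v) {
    x <- volumeData(v); n <- dim(x)[1]
    g <- seq_len(n)
    w <- x / sum(x)
    m <- c(sum(w * slice.index(x, 1)), sum(w * slice.index(x, 2)),
           sum(w * slice.index(x, 3)))
    sum(w * ((slice.index(x, 1) - m[1])^2 + (slice.index(x, 2) - m[2])^2 +
             (slice.index(x, 3) - m[3])^2))
  }
  expect_gt(abs(mom2(a) - mom2(d)), 0.5)
  expect_error(makeToyDensity("octopus", 16), "unknown class")
  expect_true(all(volumeData(makeToyDensity("rod", 16, amplitude = 0)) == 0))
})

test_that("identity pose leaves a volume unchanged", {
  v <- structuredVolume()
  r <- rotateTranslate(v, c(0, 0, 0), c(0, 0, 0))
  expect_equal(volumeData(r), volumeData(v), tolerance = 1e-12)
})

test_that("90-degree z-rotation of an x-aligned rod gives the y-aligned rod", {
  n <- 16
  c0 <- (n + 1) / 2
  g <- seq_len(n) - c0
  X <- array(rep(g, times = n * n), c(n, n, n))
  Y <- array(rep(rep(g, each = n), times = n), c(n, n, n))
  Z <- array(rep(g, each = n * n), c(n, n, n))
  rodX <- TomoVolume((abs(X) < 5) * (abs(Y) < 1.4) * (abs(Z) < 1.4) * 1.0)
  rodY <- (abs(Y) < 5) * (abs(X) < 1.4) * (abs(Z) < 1.4) * 1.0
  rot <- rotateTranslate(rodX, c(90, 0, 0), c(0, 0, 0))
  expect_equal(volumeData(rot), rodY, tolerance = 1e-9)
})

test_that("rotation followed by its inverse restores the volume", {
  # smooth test volume: trilinear resampling error scales with curvature, so
  # the composition bound is stated for band-limited content
  n <- 24
  g <- seq_len(n) - (n + 1) / 2
  X <- array(rep(g, times = n * n), c(n, n, n))
  Y <- array(rep(rep(g, each = n), times = n), c(n, n, n))
  Z <- array(rep(g, each = n * n), c(n, n, n))
  v <- TomoVolume(exp(-(X^2 / 24 + Y^2 / 36 + Z^2 / 24)) +
                  0.5 * exp(-((X - 2)^2 + (Y + 2)^2 + Z^2) / 36))
  ang <- c(31, 22, -14)
  r1 <- rotateTranslate(v, ang, c(0, 0, 0))
  # inverse of intrinsic ZYZ(a, b, g) is ZYZ(-g, -b, -a)
  r2 <- rotateTranslate(r1, c(-ang[3], -ang[2], -ang[1]), c(0, 0, 0))
  dr <- diff(range(volumeData(v)))
  expect_lt(max(abs(volumeData(r2) - volumeData(v))), 0.05 * dr)
})

test_that("random poses are seed-reproducible and differ across seeds", {
  v <- structuredVolume()
  a <- rotateTranslate(v, "random", "random", seed = 5)
  b <- rotateTranslate(v, "random", "random", seed = 5)
  c <- rotateTranslate(v, "random", "random", seed = 6)
  expect_identical(volumeData(a), volumeData(b))
  expect_false(identical(volumeData(a), volumeData(c)))
})

test_that("MTF is a linear radial low-pass: spectra attenuate with frequency", {
  set.seed(2)
  n <- 32
  white <- TomoVolume(array(rnorm(n^3), c(n, n, n)))
  out <- applyMTF(white, 0.2)
  # radially averaged power ratio must decay monotonically across coarse bins
  f <- tomogan:::fftfreq(n)
  F2 <- outer(outer(f^2, f^2, "+"), f^2, "+")
  r <- sqrt(F2)
  p0 <- abs(fft(volumeData(white)))^2
  p1 <- abs(fft(volumeData(out)))^2
  bins <- cut(as.numeric(r), breaks = seq(0, 0.9, by = 0.15), include.lowest = TRUE)
  ratio <- tapply(as.numeric(p1) / pmax(as.numeric(p0), 1e-30), bins, mean)
  expect_true(all(diff(ratio) < 0))
  # identity when unset, linear otherwise
  expect_identical(volumeData(applyMTF(white, NULL)), volumeData(white))
  a <- structuredVolume(seed = 1); b <- structuredVolume(seed = 2)
  lhs <- applyMTF(TomoVolume(volumeData(a) + volumeData(b)), 0.25)
  rhs <- volumeData(applyMTF(a, 0.25)) + volumeData(applyMTF(b, 0.25))
  expect_equal(volumeData(lhs), rhs, tolerance = 1e-10)
})

test_that("missing wedge zeroes in-wedge coefficients and is idempotent", {
  v <- structuredVolume(n = 16)
  w <- applyMissingWedge(v, 30)
  Fw <- fft(volumeData(w))
  mask <- tomogan:::missingWedgeMask(16, 30)
  expect_lt(max(abs(Fw[mask == 1])), 1e-6 * max(abs(Fw)))
  # idempotent projection
  w2 <- applyMissingWedge(w, 30)
  expect_equal(volumeData(w2), volumeData(w), tolerance = 1e-10)
  # angle 0 is the identity
  expect_identical(volumeData(applyMissingWedge(v, 0)), volumeData(v))
})

test_that("noise addition hits the requested SNR and errors on flat input", {
  v <- structuredVolume(n = 32)
  for (snr in c(0.1, 0.5, 2)) {
    noisy <- addNoiseToSNR(v, snr, seed = 11)
    realized <- var(as.numeric(volumeData(v))) /
      var(as.numeric(volumeData(noisy) - volumeData(v)))
    expect_lt(abs(realized - snr) / snr, 0.1)
  }
  expect_identical(volumeData(addNoiseToSNR(v, NULL)), volumeData(v))
  expect_identical(volumeData(addNoiseToSNR(v, 0.5, seed = 3)),
                   volumeData(addNoiseToSNR(v, 0.5, seed = 3)))
  expect_error(addNoiseToSNR(TomoVolume(array(1, c(8, 8, 8))), 0.5),
               "SNR is undefined")
})

test_that("the composed simulator is pure, bounded and degrades correlation", {
  v <- makeToyDensity("shell", n = 16, seed = 4)
  p <- simulationParams(seed = 9)
  s1 <- simulateSubtomogram(v, p)
  s2 <- simulateSubtomogram(v, p)
  expect_identical(volumeData(s1), volumeData(s2))
  expect_equal(range(volumeData(s1)), c(-1, 1))
  clean <- simulateSubtomogram(
    v, simulationParams(snr = NULL, wedgeAngle = 0, mtfSigma = NULL,
                        rotation = c(0, 0, 0), translation = c(0, 0, 0)))
  expect_equal(volumeData(clean), volumeData(normalizeVolume(v)), tolerance = 1e-12)
  rho <- cor(as.numeric(volumeData(s1)), as.numeric(volumeData(clean)))
  expect_gt(rho, 0)
  expect_lt(rho, 1)
})

test_that("fixture domains are unpaired, class-balanced and labeled", {
  fx <- tinyFixture()
  expect_equal(length(volumes(fx$D)), 12)
  expect_equal(length(volumes(fx$S)), 12)
  expect_equal(as.numeric(table(volumeLabels(fx$D))), rep(3, 4))
  expect_equal(as.numeric(table(volumeLabels(fx$S))), rep(3, 4))
  # matched-class D and S items are different volumes (unpaired domains)
  rho <- cor(as.numeric(volumeData(volumes(fx$D)[[1]])),
             as.numeric(volumeData(volumes(fx$S)[[1]])))
  expect_lt(rho, 0.999)
  # degradation operators preserve shape and realness
  for (v in list(volumes(fx$S)[[1]], volumes(fx$S)[[12]])) {
    expect_equal(dim(volumeData(v)), c(16, 16, 16))
    expect_true(all(is.finite(volumeData(v))))
  }
})

test_that("clean toy classes are separable by the pooled-feature classifier", {
  ds <- embFixture()
  emb <- trainEmbedder(ds, seed = 2)
  acc <- classificationAccuracy(emb, ds)
  expect_gt(acc, 0.9)
})
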