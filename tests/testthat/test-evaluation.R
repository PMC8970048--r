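test_that("k-NN radii match hand computation and reject bad k", {
  X <- matrix(c(0, 1), ncol = 1)
  r <- knnRadii(X, 1)
  expect_equal(r$radii, c(1, 1))
  expect_error(knnRadii(X, 2), "k must satisfy")
  expect_warning(knnRadii(matrix(c(1, 1, 1), ncol = 1), 1), "duplicate")
  set.seed(1)
  X <- matrix(rnorm(50 * 4), 50, 4)
  r <- knnRadii(X, 3)
  # brute-force oracle
  brute <- sapply(1:50, function(i) {
    sort(sqrt(colSums((t(X[-i, , drop = FALSE]) - X[i, ])^2)))[3]
  })
  expect_equal(r$radii, brute)
})

test_that("manifold metrics reproduce the hand-computed instance", {
  X <- matrix(c(0, 1), ncol = 1)
  Y <- matrix(c(0.5, 3), ncol = 1)
  expect_equal(manifoldPrecision(X, Y, 1), 0.5)
  expect_equal(manifoldRecall(X, Y, 1), 1.0)
  expect_equal(manifoldDensity(X, Y, 1), 1.0)
  expect_equal(manifoldCoverage(X, Y, 1), 1.0)
})

test_that("manifold metrics agree exactly with the brute-force oracle", {
  set.seed(7)
  for (rep in 1:60) {
    N <- sample(6:30, 1); M <- sample(6:30, 1); d <- sample(1:8, 1)
    k <- sample(c(1, 3, 5), 1)
    if (k >= min(N, M)) k <- 1
    X <- matrix(rnorm(N * d), N, d)
    Y <- matrix(rnorm(M * d, mean = 0.3), M, d)
    o <- bruteManifold(X, Y, k)
    expect_identical(manifoldPrecision(X, Y, k), o$precision)
    expect_identical(manifoldRecall(X, Y, k), o$recall)
    expect_identical(manifoldDensity(X, Y, k), o$density)
    expect_identical(manifoldCoverage(X, Y, k), o$coverage)
  }
})

test_that("identical and disjoint sets give the boundary metric values", {
  set.seed(3)
  X <- matrix(rnorm(10 * 3), 10, 3)
  expect_equal(manifoldPrecision(X, X, 1), 1)
  expect_equal(manifoldRecall(X, X, 1), 1)
  expect_equal(manifoldCoverage(X, X, 1), 1)
  far <- X + 1e6
  expect_equal(manifoldPrecision(X, far, 1), 0)
  expect_equal(manifoldDensity(X, far, 1), 0)
  expect_equal(manifoldCoverage(X, far, 1), 0)
})

test_that("inception score spans [1, C] with its closed-form endpoints", {
  p <- matrix(rep(c(0.25, 0.25, 0.25, 0.25), 8), ncol = 4, byrow = TRUE)
  expect_equal(inceptionScore(p), 1)
  onehot <- diag(4)[rep(1:4, each = 3), ]
  expect_equal(inceptionScore(onehot), 4)
  set.seed(5)
  for (i in 1:200) {
    C <- sample(2:6, 1)
    raw <- matrix(rexp(12 * C), 12, C)
    probs <- raw / rowSums(raw)
    v <- inceptionScore(probs)
    expect_gte(v, 1 - 1e-12)
    expect_lte(v, C + 1e-12)
  }
  expect_error(inceptionScore(matrix(c(0.5, 0.2), 1)), "probability")
})

test_that("FID matches diagonal closed forms, is symmetric and zero at identity", {
  m1 <- list(mu = 0, sigma = matrix(1))
  m2 <- list(mu = 1, sigma = matrix(1))
  expect_equal(fidScore(m1, m2), 1, tolerance = 1e-8)
  expect_equal(fidScore(m1, m1), 0, tolerance = 1e-12)
  set.seed(2)
  mu1 <- rnorm(5); mu2 <- rnorm(5)
  s1 <- diag(rexp(5)); s2 <- diag(rexp(5))
  expected <- sum((mu1 - mu2)^2) + sum((sqrt(diag(s1)) - sqrt(diag(s2)))^2)
  a <- list(mu = mu1, sigma = s1); b <- list(mu = mu2, sigma = s2)
  expect_equal(fidScore(a, b), expected, tolerance = 1e-8)
  expect_equal(fidScore(b, a), fidScore(a, b), tolerance = 1e-8)
  # full-covariance case stays nonnegative
  X <- matrix(rnorm(40 * 5), 40, 5); Y <- matrix(rnorm(40 * 5, 0.2), 40, 5)
  expect_gte(fidScore(gaussianMoments(X), gaussianMoments(Y)), 0)
})

test_that("3D SSIM has its identity, anticorrelation and shift behavior", {
  set.seed(4)
  a <- array(rnorm(12^3), c(12, 12, 12))
  a <- a - mean(a)
  expect_identical(ssim3d(a, a), 1)
  expect_lt(ssim3d(a, -a), 0)
  s <- ssim3d(a, a + 0.1 * sd(a))
  expect_lt(s, 1)
  expect_gt(s, 0)
  expect_error(ssim3d(a, array(0, c(10, 10, 10))), "equal shapes")
  # window sums agree with a naive reference implementation
  ns <- asNamespace("tomogan")
  b <- array(rnorm(6^3), c(6, 6, 6))
  bs <- ns$boxSum3d(b, 3L)
  naive <- array(0, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (l in 1:4) {
    naive[i, j, l] <- sum(b[i:(i + 2), j:(j + 2), l:(l + 2)])
  }
  expect_equal(bs, naive, tolerance = 1e-10)
})

test_that("classification accuracy counts matches and needs labels", {
  ds <- embFixture()
  emb <- trainEmbedder(ds, seed = 2)
  # oracle hand count on a small labeled subset
  sub <- DomainDataset(volumes(ds)[1:8], "D", volumeLabels(ds)[1:8])
  pred <- sapply(volumes(sub), function(v) emb$classes[which.max(emb$classProb(v))])
  expect_equal(classificationAccuracy(emb, sub), mean(pred == volumeLabels(sub)))
  expect_error(classificationAccuracy(emb, DomainDataset(list(), "D")), "empty")
  # a random classifier on balanced classes sits near chance
  rnd <- list(classes = emb$classes,
              classProb = local({
                i <- 0
                function(v) { i <<- i + 1; set.seed(i); p <- rexp(4); p / sum(p) }
              }))
  big <- embFixture()
  acc <- classificationAccuracy(rnd, big)
  expect_lt(abs(acc - 0.25), 3 * sqrt(0.25 * 0.75 / length(volumes(big))) + 0.05)
})

test_that("the suite report has the eight metrics and identity behavior", {
  ds <- embFixture()
  emb <- trainEmbedder(ds, seed = 2)
  rep1 <- evaluateSuite(ds, ds, embedder = emb, k = 3)
  expect_named(rep1, c("ssim", "precision", "recall", "density", "coverage",
                       "classification_acc", "inception_score", "fid"))
  expect_equal(rep1$precision, 1)
  expect_equal(rep1$recall, 1)
  expect_equal(rep1$coverage, 1)
  expect_equal(rep1$fid, 0, tolerance = 1e-8)
  expect_equal(rep1$ssim, 1)
  # pure noise generated data collapses precision and coverage
  set.seed(9)
  noise <- DomainDataset(lapply(1:12, function(i) {
    TomoVolume(array(runif(16^3, -1, 1), c(16, 16, 16)))
  }), "D", rep(emb$classes, 3))
  rep2 <- evaluateSuite(ds, noise, embedder = emb, k = 3)
  expect_lt(rep2$precision, 0.2)
  expect_lt(rep2$coverage, 0.2)
  expect_gt(rep2$fid, rep1$fid)
})

test_that("embedding dimension mismatches are reported by name", {
  expect_error(tomogan:::checkEmbPair(matrix(0, 3, 4), matrix(0, 3, 5)),
               "real d = 4, generated d = 5")
})
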