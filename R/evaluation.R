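# Generative-model evaluation suite: k-NN manifold precision / recall /
# density / coverage, inception score, Frechet distance between embedding
# Gaussians, 3D SSIM, and a downstream classification harness with a
# pluggable embedder.

#' k-nearest-neighbour manifold radii
#'
#' For each point \code{X_i}, the Euclidean distance to its k-th nearest
#' neighbour (a point is not its own neighbour). These radii define the balls
#' whose union is the estimated data manifold.
#'
#' @param X numeric N x d matrix (or \linkS4class{EmbeddingSet}).
#' @param k neighbour order, \code{1 <= k < N}.
#' @return \code{list(centers, radii, k)}.
#' @export
knnRadii <- function(X, k) {
  X <- embMatrix(X)
  N <- nrow(X)
  if (k < 1 || k >= N) stop("k must satisfy 1 <= k < N; got k = ", k, ", N = ", N)
  Dm <- as.matrix(dist(X))
  radii <- vapply(seq_len(N), function(i) sort(Dm[i, -i], partial = k)[k], numeric(1))
  if (any(radii == 0)) {
    warning("duplicate points give zero k-NN radii; affected balls are degenerate")
  }
  list(centers = X, radii = radii, k = k)
}

embMatrix <- function(X) {
  if (is(X, "EmbeddingSet")) X <- X@vectors
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  as.matrix(X)
}

# exact squared... no: exact Euclidean distances from each row of Y to all rows
# of X, computed as sqrt(sum of squared differences) so that results agree
# bitwise with a naive double loop.
crossDistances <- function(X, Y) {
  Xt <- t(X)
  t(vapply(seq_len(nrow(Y)), function(j) {
    sqrt(colSums((Xt - Y[j, ])^2))
  }, numeric(nrow(X))))  # M x N
}

#' Manifold precision
#'
#' Fraction of generated points \code{Y_j} lying inside the union of balls
#' \code{B(X_i, NND_k(X_i))} around the real points (distance equal to the
#' radius counts as inside).
#'
#' @param X real embeddings (N x d matrix or \linkS4class{EmbeddingSet}).
#' @param Y generated embeddings (M x d).
#' @param k neighbour order for the manifold radii.
#' @return A value in [0, 1].
#' @export
manifoldPrecision <- function(X, Y, k = 5) {
  X <- embMatrix(X); Y <- embMatrix(Y)
  checkEmbPair(X, Y)
  r <- knnRadiiQuiet(X, k)
  Dc <- crossDistances(X, Y)                    # M x N
  mean(apply(sweep(Dc, 2, r, "<="), 1, any))
}

#' Manifold recall
#'
#' Symmetric form of \code{\link{manifoldPrecision}}: fraction of real points
#' \code{X_i} inside the manifold built on the generated points.
#'
#' @inheritParams manifoldPrecision
#' @return A value in [0, 1].
#' @export
manifoldRecall <- function(X, Y, k = 5) {
  manifoldPrecision(Y, X, k)
}

#' Manifold density
#'
#' \code{(1/(kM)) sum_j sum_i 1[Y_j in B(X_i, NND_k(X_i))]}: counts how many
#' real-sample neighbourhoods contain each generated sample, so values above
#' 1 are possible.
#'
#' @inheritParams manifoldPrecision
#' @return A nonnegative value.
#' @export
manifoldDensity <- function(X, Y, k = 5) {
  X <- embMatrix(X); Y <- embMatrix(Y)
  checkEmbPair(X, Y)
  r <- knnRadiiQuiet(X, k)
  Dc <- crossDistances(X, Y)
  sum(sweep(Dc, 2, r, "<=")) / (k * nrow(Y))
}

#' Manifold coverage
#'
#' Fraction of real points whose k-NN ball contains at least one generated
#' sample; a recall-type metric built on the real manifold, more robust to
#' generated-set outliers.
#'
#' @inheritParams manifoldPrecision
#' @return A value in [0, 1].
#' @export
manifoldCoverage <- function(X, Y, k = 5) {
  X <- embMatrix(X); Y <- embMatrix(Y)
  checkEmbPair(X, Y)
  r <- knnRadiiQuiet(X, k)
  Dc <- crossDistances(X, Y)
  mean(apply(Dc, 2, min) <= r)
}

knnRadiiQuiet <- function(X, k) suppressWarnings(knnRadii(X, k))$radii

checkEmbPair <- function(X, Y) {
  if (nrow(X) == 0 || nrow(Y) == 0) stop("empty embedding set")
  if (ncol(X) != ncol(Y)) {
    stop(sprintf("embedding dimensions differ: real d = %d, generated d = %d",
                 ncol(X), ncol(Y)))
  }
  invisible(TRUE)
}

#' Inception score from class probabilities
#'
#' \code{exp(E_x KL(p(y|x) || p(y)))} with the marginal \code{p(y)} taken as
#' the mean of the rows; \code{0 log 0 = 0}. Bounded by [1, C] for C classes.
#'
#' @param probs matrix of per-sample class probabilities (rows sum to 1).
#' @return The score.
#' @export
inceptionScore <- function(probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) == 0) stop("empty probability table")
  if (any(probs < -1e-12) || any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("rows must be probability vectors (nonnegative, summing to 1)")
  }
  probs <- pmax(probs, 0)
  py <- colMeans(probs)
  kl <- vapply(seq_len(nrow(probs)), function(i) {
    p <- probs[i, ]
    nz <- p > 0
    sum(p[nz] * (log(p[nz]) - log(py[nz])))
  }, numeric(1))
  exp(mean(kl))
}

#' Gaussian moments of an embedding set
#'
#' @param X N x d matrix or \linkS4class{EmbeddingSet}.
#' @return \code{list(mu, sigma)} (mean vector, covariance matrix).
#' @export
gaussianMoments <- function(X) {
  X <- embMatrix(X)
  if (nrow(X) < 2) stop("need at least two samples for covariance moments")
  list(mu = colMeans(X), sigma = cov(X))
}

#' Frechet distance between two embedding Gaussians
#'
#' \code{||mu_r - mu_g||^2 + Tr(S_r + S_g - 2 (S_r S_g)^{1/2})}. The matrix
#' square root is taken by eigendecomposition of the symmetrized product
#' \code{S_g^{1/2} S_r S_g^{1/2}}; small negative eigenvalues are clipped at
#' zero with a warning.
#'
#' @param momentsReal,momentsFake \code{list(mu, sigma)} as returned by
#'   \code{\link{gaussianMoments}}.
#' @return A nonnegative, symmetric distance (0 for identical moments).
#' @export
fidScore <- function(momentsReal, momentsFake) {
  mu1 <- momentsReal$mu; s1 <- as.matrix(momentsReal$sigma)
  mu2 <- momentsFake$mu; s2 <- as.matrix(momentsFake$sigma)
  stopifnot(length(mu1) == length(mu2), all(dim(s1) == dim(s2)))
  sqrtmSym <- function(m) {
    e <- eigen((m + t(m)) / 2, symmetric = TRUE)
    vals <- e$values
    if (any(vals < -1e-8 * max(abs(vals), 1))) {
      warning("covariance product has notable negative eigenvalues; clipping at 0")
    }
    e$vectors %*% (sqrt(pmax(vals, 0)) * t(e$vectors))
  }
  s2half <- sqrtmSym(s2)
  covMean <- sqrtmSym(s2half %*% s1 %*% s2half)
  d <- sum((mu1 - mu2)^2) + sum(diag(s1)) + sum(diag(s2)) - 2 * sum(diag(covMean))
  max(d, 0)
}

#' 3D structural similarity index
#'
#' Mean local SSIM over all fully interior sliding cubic windows, with the
#' standard stabilizers \code{C1 = (0.01 L)^2}, \code{C2 = (0.03 L)^2} for
#' data range \code{L}.
#'
#' @param a,b numeric arrays of equal shape (or \linkS4class{TomoVolume}s).
#' @param window odd window side (default 7, reduced if the volume is small).
#' @param dataRange value range L; default \code{diff(range(a, b))}.
#' @return A value in [-1, 1]; exactly 1 when \code{a == b}.
#' @export
ssim3d <- function(a, b, window = 7L, dataRange = NULL) {
  a <- if (is(a, "TomoVolume")) a@data else a
  b <- if (is(b, "TomoVolume")) b@data else b
  if (!all(dim(a) == dim(b))) stop("ssim3d requires equal shapes")
  n <- dim(a)[1]
  w <- min(window, n)
  if (w %% 2 == 0) w <- w - 1L
  if (is.null(dataRange)) dataRange <- diff(range(c(a, b)))
  if (dataRange == 0) dataRange <- 1
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  nw <- w^3
  mA <- boxSum3d(a, w) / nw
  mB <- boxSum3d(b, w) / nw
  vA <- boxSum3d(a * a, w) / nw - mA^2
  vB <- boxSum3d(b * b, w) / nw - mB^2
  cAB <- boxSum3d(a * b, w) / nw - mA * mB
  s <- ((2 * mA * mB + C1) * (2 * cAB + C2)) /
       ((mA^2 + mB^2 + C1) * (vA + vB + C2))
  mean(s)
}

# sums over all w^3 windows fully inside the volume (valid positions), via
# cumulative sums along each axis
boxSum3d <- function(a, w) {
  run <- function(x, axis) {
    cs <- apply(x, setdiff(1:3, axis), cumsum)
    # apply returns with the summed axis first; restore order
    cs <- aperm(cs, order(c(axis, setdiff(1:3, axis))))
    n <- dim(x)[axis]
    idxHi <- seq(w, n)
    hi <- slice3(cs, axis, idxHi)
    lo <- slice3(cs, axis, seq(0, n - w))
    hi - lo
  }
  run(run(run(a, 1), 2), 3)
}

slice3 <- function(a, axis, idx) {
  # idx may contain 0 meaning "zero slab"
  d <- dim(a)
  out <- switch(axis,
    a[pmax(idx, 1), , , drop = FALSE],
    a[, pmax(idx, 1), , drop = FALSE],
    a[, , pmax(idx, 1), drop = FALSE])
  if (any(idx == 0)) {
    z <- which(idx == 0)
    switch(axis,
      out[z, , ] <- 0,
      out[, z, ] <- 0,
      out[, , z] <- 0)
  }
  out
}

# ---- embedder / classifier harness ------------------------------------------

#' Train the default volume embedder
#'
#' A lightweight stand-in for a deep 3D classification network: volumes are
#' average-pooled to \code{poolSide^3} feature vectors and a single-hidden-
#' layer softmax network (\pkg{nnet}) is fit on the labeled real data. The
#' embedder exposes both a feature map (the pooled vector) and class
#' probabilities, and is deterministic at prediction time. Any user object
#' with the same \code{$embed} / \code{$classProb} interface can be used in
#' its place.
#'
#' @param dataset a labeled \linkS4class{DomainDataset} of real volumes.
#' @param poolSide pooled grid side (feature dimension poolSide^3, default 4).
#' @param hidden hidden units (default 16).
#' @param seed RNG seed for the nnet fit.
#' @return A \code{TomoEmbedder} object.
#' @export
trainEmbedder <- function(dataset, poolSide = 4L, hidden = 16L, seed = 1) {
  labels <- volumeLabels(dataset)
  if (length(labels) == 0) stop("embedder training needs a labeled dataset")
  feats <- t(vapply(volumes(dataset), function(v) poolFeatures(v@data, poolSide),
                    numeric(poolSide^3)))
  classes <- sort(unique(labels))
  y <- nnet::class.ind(factor(labels, levels = classes))
  fit <- withSeed(deriveSeed(seed, 51L),
    nnet::nnet(feats, y, size = hidden, softmax = TRUE, decay = 5e-4,
               maxit = 300, trace = FALSE, MaxNWts = 100000))
  structure(list(poolSide = as.integer(poolSide), d = as.integer(poolSide^3),
                 classes = classes, fit = fit,
                 embed = function(vol) poolFeatures(volArray(vol), poolSide),
                 classProb = function(vol) {
                   p <- predict(fit, matrix(poolFeatures(volArray(vol), poolSide), 1))
                   as.numeric(p)
                 }),
            class = "TomoEmbedder")
}

volArray <- function(v) if (is(v, "TomoVolume")) v@data else v

poolFeatures <- function(a, poolSide) {
  n <- dim(a)[1]
  bins <- ceiling(seq_len(n) / (n / poolSide))
  bins <- pmin(bins, poolSide)
  # average over 3D blocks
  s <- rowsum(matrix(a, n, n * n), bins)                  # pool axis 1
  s <- array(s, c(poolSide, n, n))
  s <- aperm(s, c(2, 1, 3))
  s <- rowsum(matrix(s, n, poolSide * n), bins)
  s <- array(s, c(poolSide, poolSide, n))
  s <- aperm(s, c(3, 1, 2))
  s <- rowsum(matrix(s, n, poolSide * poolSide), bins)
  s <- aperm(array(s, c(poolSide, poolSide, poolSide)), c(2, 3, 1))
  as.numeric(s) / (n / poolSide)^3
}

#' Embed every volume of a dataset
#'
#' @param embedder a \code{TomoEmbedder} (or compatible object).
#' @param dataset a \linkS4class{DomainDataset}.
#' @return An \linkS4class{EmbeddingSet}.
#' @export
embedDataset <- function(embedder, dataset) {
  vecs <- t(vapply(volumes(dataset), embedder$embed, numeric(embedder$d)))
  EmbeddingSet(vecs, source = domainTag(dataset))
}

#' Class probabilities for every volume of a dataset
#'
#' @inheritParams embedDataset
#' @return Matrix of probabilities, one row per volume, columns named by class.
#' @export
classProbabilities <- function(embedder, dataset) {
  p <- t(vapply(volumes(dataset), embedder$classProb,
                numeric(length(embedder$classes))))
  colnames(p) <- embedder$classes
  p
}

#' Downstream classification accuracy of generated volumes
#'
#' Fraction of generated volumes whose predicted class (from a classifier
#' trained on real labeled data) matches the class of the density map they
#' were generated from.
#'
#' @param classifier a \code{TomoEmbedder} (or any object with
#'   \code{$classProb} and \code{$classes}).
#' @param generated a labeled \linkS4class{DomainDataset} of generated volumes.
#' @return Accuracy in [0, 1].
#' @export
classificationAccuracy <- function(classifier, generated) {
  if (length(volumes(generated)) == 0) stop("empty generated dataset")
  labels <- volumeLabels(generated)
  if (length(labels) == 0) stop("generated dataset must carry source-class labels")
  pred <- vapply(volumes(generated), function(v) {
    classifier$classes[which.max(classifier$classProb(v))]
  }, character(1))
  mean(pred == labels)
}

#' Run the full evaluation suite
#'
#' Computes the eight-metric report comparing a generated dataset with a real
#' one: 3D SSIM (each generated volume against its nearest same-class real
#' exemplar in embedding space), manifold precision/recall/density/coverage,
#' downstream classification accuracy, inception score and Frechet distance.
#'
#' @param realDataset labeled real volumes.
#' @param generatedDataset generated volumes (labeled with source classes for
#'   SSIM pairing and classification accuracy; unlabeled gives NA there).
#' @param embedder a trained \code{TomoEmbedder}; default trains one on
#'   \code{realDataset}.
#' @param k neighbour order for manifold metrics (default 5).
#' @param seed seed for the default embedder fit.
#' @return Named list with entries \code{ssim}, \code{precision},
#'   \code{recall}, \code{density}, \code{coverage},
#'   \code{classification_acc}, \code{inception_score}, \code{fid}.
#' @export
evaluateSuite <- function(realDataset, generatedDataset, embedder = NULL,
                          k = 5, seed = 1) {
  if (is.null(embedder)) embedder <- trainEmbedder(realDataset, seed = seed)
  X <- embedDataset(embedder, realDataset)
  Y <- embedDataset(embedder, generatedDataset)
  checkEmbPair(X@vectors, Y@vectors)
  kEff <- min(k, nrow(X@vectors) - 1, nrow(Y@vectors) - 1)
  probs <- classProbabilities(embedder, generatedDataset)
  rl <- volumeLabels(realDataset)
  gl <- volumeLabels(generatedDataset)
  ssim <- pairedSSIM(realDataset, generatedDataset, X@vectors, Y@vectors, rl, gl)
  acc <- if (length(gl)) classificationAccuracy(embedder, generatedDataset) else NA_real_
  list(
    ssim = ssim,
    precision = manifoldPrecision(X, Y, kEff),
    recall = manifoldRecall(X, Y, kEff),
    density = manifoldDensity(X, Y, kEff),
    coverage = manifoldCoverage(X, Y, kEff),
    classification_acc = acc,
    inception_score = inceptionScore(probs),
    fid = fidScore(gaussianMoments(X), gaussianMoments(Y))
  )
}

# each generated volume vs its nearest real exemplar (same class when labels
# are available) in embedding space
pairedSSIM <- function(realDataset, generatedDataset, X, Y, rl, gl) {
  rv <- volumes(realDataset); gv <- volumes(generatedDataset)
  vals <- vapply(seq_along(gv), function(j) {
    cand <- seq_along(rv)
    if (length(rl) && length(gl)) {
      same <- which(rl == gl[j])
      if (length(same)) cand <- same
    }
    dists <- crossDistances(X[cand, , drop = FALSE], Y[j, , drop = FALSE])
    best <- cand[which.min(dists)]
    ssim3d(rv[[best]], gv[[j]])
  }, numeric(1))
  mean(vals)
}
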