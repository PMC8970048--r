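# Model construction and stochastic generation: the two generators
# (encoder - residual trunk - noise-channel concat - decoder, tanh head) and
# the two spectrally normalized critics.

#' Build a translation model (two generators + two critics)
#'
#' The generator follows the plan c7s1-32, d64, d128, six R128 residual
#' blocks, a one-channel Gaussian noise concat (so the first upsampling layer
#' consumes 129 channels at the paper-scale width), u64, u32, c7s1-1 with a
#' tanh head and no normalization on the output layer. The critic stacks
#' three 4x4x4 stride-1 convolutions (64, 128, 256 filters) with instance
#' norm and leaky ReLU (slope 0.2), spectral normalization on every critic
#' convolution, then a 1-filter projection and a spatial mean producing the
#' scalar critic score. \code{baseFilters} scales all widths together
#' (32 reproduces the paper-scale plan; smaller values give desk-scale
#' models for CPU experiments).
#'
#' @param n input side length in voxels; must be divisible by 4 (two stride-2
#'   stages).
#' @param seed RNG seed for deterministic initialization.
#' @param dropoutRate dropout probability inside generator residual blocks
#'   (present in the graph; inactive unless sampling with dropout on).
#' @param baseFilters width of the first generator stage (default 32).
#' @param spectralNorm apply spectral normalization to critic convolutions.
#' @return A \linkS4class{TranslationModel}.
#' @examples
#' m <- buildModel(16, seed = 1, baseFilters = 4)
#' m
#' @export
buildModel <- function(n, seed = 1, dropoutRate = 0, baseFilters = 32L,
                       spectralNorm = TRUE) {
  if (n %% 4 != 0) {
    stop("n must be divisible by 4 (two stride-2 downsampling stages); got ", n)
  }
  if (n < 8) stop("n must be at least 8")
  b <- as.integer(baseFilters)
  withSeed(deriveSeed(seed, 11L), {
    gds <- buildGenerator(b)
    gsd <- buildGenerator(b)
    da <- buildCritic(2L * b)
    db <- buildCritic(2L * b)
    new("TranslationModel", gds = gds, gsd = gsd, da = da, db = db,
        n = as.integer(n), baseFilters = b, dropoutRate = as.numeric(dropoutRate),
        spectralNorm = isTRUE(spectralNorm))
  })
}

buildGenerator <- function(b) {
  list(kind = "generator",
       layers = list(
         nnConv(7L, 1L, 3L, 1L, b, reflect = TRUE), nnINorm(), nnAct("relu"),
         nnConv(3L, 2L, 1L, b, 2L * b), nnINorm(), nnAct("relu"),
         nnConv(3L, 2L, 1L, 2L * b, 4L * b), nnINorm(), nnAct("relu"),
         nnRes(4L * b), nnRes(4L * b), nnRes(4L * b),
         nnRes(4L * b), nnRes(4L * b), nnRes(4L * b),
         nnNoiseCat(),
         nnTConv(4L * b + 1L, 2L * b), nnINorm(), nnAct("relu"),
         nnTConv(2L * b, b), nnINorm(), nnAct("relu"),
         nnConv(7L, 1L, 3L, b, 1L, reflect = TRUE), nnAct("tanh")))
}

buildCritic <- function(b) {
  list(kind = "critic",
       layers = list(
         nnConv(4L, 1L, 1L, 1L, b, sn = TRUE), nnINorm(), nnAct("lrelu"),
         nnConv(4L, 1L, 1L, b, 2L * b, sn = TRUE), nnINorm(), nnAct("lrelu"),
         nnConv(4L, 1L, 1L, 2L * b, 4L * b, sn = TRUE), nnINorm(), nnAct("lrelu"),
         nnConv(1L, 1L, 0L, 4L * b, 1L, sn = TRUE),
         nnGMean()))
}

genCtx <- function(model, train = FALSE, dropoutOn = FALSE) {
  list(train = train, dropoutOn = dropoutOn, dropoutRate = model@dropoutRate,
       spectralNorm = model@spectralNorm, snIters = 6L)
}

asNetInput <- function(volume, n) {
  x <- if (is(volume, "TomoVolume")) volume@data else volume
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  if (!all(dim(x)[1:3] == n)) {
    stop(sprintf("volume side %d does not match model input side %d", dim(x)[1], n))
  }
  x
}

#' Translate a volume through one generator
#'
#' Runs a forward pass of \code{G_ds} (direction \code{"ds"}: density map to
#' subtomogram) or \code{G_sd} (\code{"sd"}: subtomogram to density map).
#' The injected Gaussian noise channel is drawn from \code{noiseSeed}, so a
#' fixed seed with dropout off is fully deterministic; different seeds can
#' produce different outputs (the mode-collapse countermeasure).
#'
#' @param model a \linkS4class{TranslationModel}.
#' @param direction \code{"ds"} or \code{"sd"}.
#' @param volume input \linkS4class{TomoVolume} (values in [-1, 1]) or array.
#' @param noiseSeed seed for the injected noise channel.
#' @param dropoutOn sample the generator's dropout layers (uncertainty mode).
#' @return The translated \linkS4class{TomoVolume} with values in (-1, 1).
#' @export
generateVolume <- function(model, direction = c("ds", "sd"), volume,
                           noiseSeed = 1, dropoutOn = FALSE) {
  direction <- match.arg(direction)
  x <- asNetInput(volume, model@n)
  net <- if (direction == "ds") model@gds else model@gsd
  y <- withSeed(deriveSeed(noiseSeed, 21L),
                seqForward(net, x, genCtx(model, dropoutOn = dropoutOn))$y)
  sp <- if (is(volume, "TomoVolume")) volume@voxelSpacing else 1.0
  TomoVolume(array(y, dim(y)[1:3]), voxelSpacing = sp,
             provenance = sprintf("generated:%s", direction))
}

#' Spectrally normalize a weight matrix
#'
#' Divides a matrix by its largest singular value, estimated by power
#' iteration, so the result has spectral norm 1 (Lipschitz-1 linear map).
#'
#' @param w a nonzero numeric matrix.
#' @param nPowerIters minimum power-iteration steps (>= 1). Standalone calls
#'   have no persistent vectors to warm-start from, so iteration continues
#'   past this minimum until the estimate stabilizes (matrices with a narrow
#'   spectral gap converge slowly).
#' @return The normalized matrix, with the estimated \code{sigma} attached as
#'   attribute \code{"sigma"}.
#' @examples
#' w <- diag(c(3, 1))
#' spectralNormalize(w)
#' @export
spectralNormalize <- function(w, nPowerIters = 50L) {
  stopifnot(is.matrix(w), nPowerIters >= 1)
  if (all(w == 0)) stop("cannot spectrally normalize an all-zero matrix")
  u <- rep(1 / sqrt(ncol(w)), ncol(w))
  # deterministic start; perturb if u is (numerically) in the null space
  if (l2(w %*% u) < 1e-12) u <- seq_len(ncol(w)) / l2(seq_len(ncol(w)))
  pi <- powerIterSigma(w, u, nPowerIters)
  for (i in seq_len(20000L)) {
    nxt <- powerIterSigma(w, pi$u, 1L)
    done <- abs(nxt$sigma - pi$sigma) < 1e-12 * nxt$sigma
    pi <- nxt
    if (done) break
  }
  out <- w / pi$sigma
  attr(out, "sigma") <- pi$sigma
  out
}

#' Corrupt an input volume with Gaussian noise
#'
#' Adds zero-mean Gaussian noise with standard deviation
#' \code{noiseStd * dynamic range} of the volume (the training-time input
#' corruption applied to density maps). \code{noiseStd = 0} is the identity.
#'
#' @param volume a \linkS4class{TomoVolume}.
#' @param noiseStd noise standard deviation as a fraction of the dynamic range.
#' @param seed RNG seed.
#' @return The corrupted \linkS4class{TomoVolume}.
#' @export
corruptInput <- function(volume, noiseStd = 0.2, seed = 1) {
  stopifnot(noiseStd >= 0)
  if (noiseStd == 0) return(volume)
  dr <- diff(range(volume@data))
  if (dr == 0) dr <- 1
  withSeed(deriveSeed(seed, 31L), {
    TomoVolume(volume@data + array(rnorm(length(volume@data), sd = noiseStd * dr),
                                   dim(volume@data)),
               voxelSpacing = volume@voxelSpacing,
               provenance = paste0(volume@provenance, "|corrupt"))
  })
}

#' Report layer-wise spectral norms of a critic
#'
#' Computes the exact largest singular value (full SVD) of every
#' spectrally normalized critic convolution, using the same effective
#' weights the forward pass uses.
#'
#' @param model a \linkS4class{TranslationModel}.
#' @param critic \code{"da"} or \code{"db"}.
#' @return Numeric vector of sigma_max values, one per normalized layer.
#' @export
criticSpectralNorms <- function(model, critic = c("da", "db")) {
  critic <- match.arg(critic)
  net <- if (critic == "da") model@da else model@db
  out <- numeric(0)
  for (l in net$layers) {
    if (l$type == "conv" && isTRUE(l$sn)) {
      M <- matrix(l$params$w, ncol = l$cout)
      pi <- powerIterSigma(M, l$sn_u, 6L)
      out <- c(out, max(svd(M / pi$sigma)$d))
    }
  }
  out
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive holding the four networks'
#' parameters, the architecture metadata and the RNG state.
#'
#' @param model a \linkS4class{TranslationModel}.
#' @param path checkpoint file.
#' @return \code{saveCheckpoint}: \code{path}, invisibly;
#'   \code{loadCheckpoint}: the restored \linkS4class{TranslationModel}.
#' @export
saveCheckpoint <- function(model, path) {
  rng <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  saveRDS(list(gds = model@gds, gsd = model@gsd, da = model@da, db = model@db,
               n = model@n, baseFilters = model@baseFilters,
               dropoutRate = model@dropoutRate, spectralNorm = model@spectralNorm,
               rngState = rng, version = "1"),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  new("TranslationModel", gds = ck$gds, gsd = ck$gsd, da = ck$da, db = ck$db,
      n = ck$n, baseFilters = ck$baseFilters, dropoutRate = ck$dropoutRate,
      spectralNorm = ck$spectralNorm)
}

#' Parameter counts of the four networks
#' @param model a \linkS4class{TranslationModel}.
#' @return Named numeric vector of parameter counts.
#' @export
modelParameterCounts <- function(model) {
  c(gds = countParams(model@gds), gsd = countParams(model@gsd),
    da = countParams(model@da), db = countParams(model@db))
}
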