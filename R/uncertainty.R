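# Monte-Carlo-dropout uncertainty maps: repeated stochastic generator passes
# on one density map, per-voxel standard deviation across the draws.

#' Monte-Carlo dropout uncertainty map
#'
#' Samples the generator \code{G_ds} \code{nSamples} times on the same
#' density map with dropout active and computes the per-voxel standard
#' deviation (population convention: divide by the number of draws) across
#' the generated volumes. With \code{noiseMode = "fixed"} the injected noise
#' channel is held constant across draws so the variance isolates dropout;
#' \code{"resample"} redraws it each time and measures total stochastic
#' variance.
#'
#' @param model a \linkS4class{TranslationModel}.
#' @param density input \linkS4class{TomoVolume} (values in [-1, 1]).
#' @param nSamples number of draws, >= 2 (default 20).
#' @param dropoutRate dropout probability; default the model's configured rate.
#' @param noiseMode \code{"fixed"} or \code{"resample"}.
#' @param seed RNG seed; fixed seed gives a deterministic map.
#' @param returnDraws also return the individual generated volumes.
#' @return An \linkS4class{UncertaintyMap}, or \code{list(map, draws)} when
#'   \code{returnDraws = TRUE}.
#' @export
mcUncertaintyMap <- function(model, density, nSamples = 20L, dropoutRate = NULL,
                             noiseMode = c("fixed", "resample"), seed = 1,
                             returnDraws = FALSE) {
  noiseMode <- match.arg(noiseMode)
  if (nSamples < 2) stop("nSamples must be >= 2")
  x <- asNetInput(density, model@n)
  rate <- if (is.null(dropoutRate)) model@dropoutRate else dropoutRate
  ctx <- genCtx(model, dropoutOn = rate > 0)
  ctx$dropoutRate <- rate
  draws <- vector("list", nSamples)
  for (t in seq_len(nSamples)) {
    ctx$noiseSeed <- if (noiseMode == "fixed") deriveSeed(seed, 61L)
                     else deriveSeed(seed, 61L, t)
    draws[[t]] <- withSeed(deriveSeed(seed, 62L, t),
                           seqForward(model@gds, x, ctx)$y)
  }
  nvox <- length(draws[[1]])
  M <- vapply(draws, as.numeric, numeric(nvox))
  mu <- rowMeans(M)
  stdv <- sqrt(pmax(rowMeans(M^2) - mu^2, 0))
  m <- new("UncertaintyMap",
           stdMap = array(stdv, dim(x)[1:3]),
           nSamples = as.integer(nSamples),
           source = if (is(density, "TomoVolume")) density@provenance else "array")
  if (returnDraws) list(map = m, draws = draws) else m
}

#' Compare uncertainty across dropout settings
#'
#' Runs \code{\link{mcUncertaintyMap}} once per dropout rate (same seed and
#' noise handling) and reports per-setting summary statistics alongside the
#' maps.
#'
#' @param model a \linkS4class{TranslationModel}.
#' @param density input density map.
#' @param rates numeric vector of dropout rates to compare.
#' @param nSamples draws per setting (default 20).
#' @param noiseMode passed to \code{\link{mcUncertaintyMap}} (default
#'   \code{"fixed"}).
#' @param seed RNG seed shared across settings.
#' @return \code{list(summary = data.frame(rate, mean_std, max_std),
#'   maps = list of UncertaintyMap)}. The summary serializes losslessly to
#'   JSON via \code{jsonlite}.
#' @export
compareDropoutSettings <- function(model, density, rates = c(0, 0.5),
                                   nSamples = 20L, noiseMode = "fixed", seed = 1) {
  maps <- lapply(rates, function(r) {
    mcUncertaintyMap(model, density, nSamples = nSamples, dropoutRate = r,
                     noiseMode = noiseMode, seed = seed)
  })
  summary <- data.frame(
    rate = rates,
    mean_std = vapply(maps, function(m) mean(m@stdMap), numeric(1)),
    max_std = vapply(maps, function(m) max(m@stdMap), numeric(1)))
  list(summary = summary, maps = maps)
}
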