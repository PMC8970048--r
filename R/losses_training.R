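# Training objectives (adversarial in logistic and Wasserstein form, cycle
# consistency), critic weight clipping, RMSProp, and the unpaired two-domain
# training loop.

#' Training configuration
#'
#' @param lambdaCyc weight of the cycle-consistency term (default 10).
#' @param lr RMSProp learning rate alpha (default 0.0005).
#' @param clipValue critic weight-clipping bound c (default 0.01).
#' @param nCritic critic updates per generator update (default 5).
#' @param batchSize volumes per update (default 8).
#' @param epochs passes over the smaller domain (default 100).
#' @param advMode \code{"wasserstein"} (critic scores, weight clipping) or
#'   \code{"logistic"} (cross-entropy discriminator) -- the ablation axis.
#' @param inputNoiseStd std of Gaussian corruption applied to density-map
#'   inputs, as a fraction of dynamic range (default 0.2).
#' @param maxSteps optional cap on generator updates (overrides epochs).
#' @param seed global training seed.
#' @return A \code{TrainingConfig} list.
#' @export
trainingConfig <- function(lambdaCyc = 10, lr = 5e-4, clipValue = 0.01,
                           nCritic = 5L, batchSize = 8L, epochs = 100L,
                           advMode = c("wasserstein", "logistic"),
                           inputNoiseStd = 0.2, maxSteps = NULL, seed = 1L) {
  advMode <- match.arg(advMode)
  stopifnot(lr > 0, clipValue > 0, lambdaCyc >= 0, nCritic >= 1, batchSize >= 1)
  structure(list(lambdaCyc = lambdaCyc, lr = lr, clipValue = clipValue,
                 nCritic = as.integer(nCritic), batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), advMode = advMode,
                 inputNoiseStd = inputNoiseStd, maxSteps = maxSteps,
                 seed = as.integer(seed)),
            class = "TrainingConfig")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Logistic (cross-entropy) adversarial losses
#'
#' Discriminator loss \code{-mean(log sigmoid(real)) - mean(log(1 -
#' sigmoid(fake)))} and the non-saturating generator loss
#' \code{-mean(log sigmoid(fake))}, on raw logits.
#'
#' @param real,fake numeric vectors of discriminator logits.
#' @return \code{list(dLoss, gLoss)}.
#' @examples
#' logisticAdversarialLoss(0, 0)  # dLoss = 2 log 2
#' @export
logisticAdversarialLoss <- function(real, fake) {
  if (length(real) == 0 || length(fake) == 0) stop("empty score batch")
  list(dLoss = mean(softplus(-real)) + mean(softplus(fake)),
       gLoss = mean(softplus(-fake)))
}

#' Wasserstein critic and generator losses
#'
#' \code{criticLoss = mean(fake) - mean(real)} (minimized by the critic;
#' its negation estimates the Earth-Mover distance) and
#' \code{genLoss = -mean(fake)}.
#'
#' @param real,fake numeric vectors of raw critic scores.
#' @return \code{list(criticLoss, genLoss)}.
#' @examples
#' wassersteinLosses(c(1, 3), c(0, 2))  # criticLoss -1, genLoss -1
#' @export
wassersteinLosses <- function(real, fake) {
  if (length(real) == 0 || length(fake) == 0) stop("empty score batch")
  list(criticLoss = mean(fake) - mean(real), genLoss = -mean(fake))
}

#' Cycle-consistency loss
#'
#' Mean absolute error of the density-map cycle plus that of the subtomogram
#' cycle: volumes translated to the other domain and back should reproduce
#' the originals.
#'
#' @param d,dRec original and reconstructed density-map batch (arrays or
#'   lists of arrays).
#' @param s,sRec original and reconstructed subtomogram batch.
#' @return The scalar loss.
#' @export
cycleLoss <- function(d, dRec, s, sRec) {
  mae <- function(a, b) {
    a <- if (is.list(a)) a else list(a)
    b <- if (is.list(b)) b else list(b)
    stopifnot(length(a) == length(b))
    mean(vapply(seq_along(a), function(i) {
      ai <- as.numeric(if (is(a[[i]], "TomoVolume")) a[[i]]@data else a[[i]])
      bi <- as.numeric(if (is(b[[i]], "TomoVolume")) b[[i]]@data else b[[i]])
      if (length(ai) != length(bi)) stop("shape mismatch in cycle loss")
      mean(abs(ai - bi))
    }, numeric(1)))
  }
  mae(d, dRec) + mae(s, sRec)
}

clipNet <- function(net, c) {
  net$layers <- mapParams(net$layers, NULL, function(p, g) pmin(pmax(p, -c), c))
  net
}

#' Clip critic weights into [-c, c]
#'
#' The Lipschitz device of Wasserstein training: every parameter of both
#' critics is clamped elementwise.
#'
#' @param model a \linkS4class{TranslationModel}.
#' @param c positive clipping bound.
#' @return The model with clipped critics.
#' @export
clipCriticWeights <- function(model, c = 0.01) {
  stopifnot(c > 0)
  model@da <- clipNet(model@da, c)
  model@db <- clipNet(model@db, c)
  model
}

maxAbsParam <- function(net) {
  max(vapply(collectParams(net$layers), function(p) max(abs(p)), numeric(1)))
}

# ---- grad arithmetic and RMSProp --------------------------------------------

addGradTrees <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) return(mapply(addGradTrees, a, b, SIMPLIFY = FALSE))
  a + b
}

scaleGradTree <- function(a, s) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) return(lapply(a, scaleGradTree, s = s))
  a * s
}

rmspropUpdate <- function(layers, grads, state, lr, rho = 0.99, eps = 1e-8) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "res") {
      r <- rmspropUpdate(l$sub, grads[[i]]$sub, state[[i]], lr, rho, eps)
      l$sub <- r$layers; state[[i]] <- r$state
    } else if (length(l$params) && !is.null(grads[[i]])) {
      for (pn in names(l$params)) {
        g <- grads[[i]][[pn]]
        ms <- state[[i]][[pn]]
        if (is.null(ms)) ms <- g * 0
        ms <- rho * ms + (1 - rho) * g * g
        l$params[[pn]] <- l$params[[pn]] - lr * g / (sqrt(ms) + eps)
        state[[i]][[pn]] <- ms
      }
    }
    layers[[i]] <- l
  }
  list(layers = layers, state = state)
}

emptyOptState <- function(layers) {
  lapply(layers, function(l) {
    if (l$type == "res") emptyOptState(l$sub) else list()
  })
}

# ---- training loop ----------------------------------------------------------

#' Train the translation model on two unpaired domains
#'
#' Alternates \code{nCritic} critic updates (with weight clipping in
#' Wasserstein mode) with one generator update on
#' \code{adv_ds + adv_sd + lambda * cycle}, using RMSProp at learning rate
#' \code{lr}. Density-map inputs are corrupted with Gaussian noise of
#' standard deviation \code{inputNoiseStd} x dynamic range before entering
#' \code{G_ds}; the cycle target stays the clean map. Fully deterministic for
#' a fixed config seed.
#'
#' @param model a \linkS4class{TranslationModel}.
#' @param datasetD density-map domain (a \linkS4class{DomainDataset}).
#' @param datasetS subtomogram domain.
#' @param config a \code{\link{trainingConfig}}.
#' @param outDir if non-NULL, writes \code{history.csv}, a final checkpoint
#'   and the resolved config there.
#' @param verbose print a per-epoch loss summary.
#' @return \code{list(model, history)}; \code{history} has one row per
#'   generator step with columns step, adv_ds, adv_sd, cycle, critic_a,
#'   critic_b, total.
#' @export
trainTranslation <- function(model, datasetD, datasetS, config = trainingConfig(),
                             outDir = NULL, verbose = FALSE) {
  stopifnot(is(model, "TranslationModel"))
  n <- model@n
  if (sideLength(datasetD) != n || sideLength(datasetS) != n) {
    stop("dataset side length does not match model n = ", n)
  }
  dArr <- lapply(volumes(datasetD), function(v) asNetInput(v, n))
  sArr <- lapply(volumes(datasetS), function(v) asNetInput(v, n))
  nd <- length(dArr); ns <- length(sArr)
  stepsPerEpoch <- max(1L, floor(min(nd, ns) / config$batchSize))
  totalSteps <- config$epochs * stepsPerEpoch
  if (!is.null(config$maxSteps)) totalSteps <- min(totalSteps, config$maxSteps)

  wass <- config$advMode == "wasserstein"
  ctx <- genCtx(model)
  opt <- list(gds = emptyOptState(model@gds$layers),
              gsd = emptyOptState(model@gsd$layers),
              da = emptyOptState(model@da$layers),
              db = emptyOptState(model@db$layers))
  hist <- vector("list", totalSteps)

  runCritic <- function(net, state, realX, fakeX) {
    # one critic update on a batch of real and fake volumes
    m <- length(realX)
    scoresR <- numeric(m); scoresF <- numeric(m)
    cachesR <- vector("list", m); cachesF <- vector("list", m)
    for (i in seq_len(m)) {
      r <- seqForward(net, realX[[i]], ctx); net <- r$net
      scoresR[i] <- r$y; cachesR[[i]] <- r$caches
      f <- seqForward(net, fakeX[[i]], ctx); net <- f$net
      scoresF[i] <- f$y; cachesF[[i]] <- f$caches
    }
    if (wass) {
      loss <- wassersteinLosses(scoresR, scoresF)$criticLoss
      gR <- rep(-1 / m, m); gF <- rep(1 / m, m)
    } else {
      loss <- logisticAdversarialLoss(scoresR, scoresF)$dLoss
      gR <- (sigmoid(scoresR) - 1) / m
      gF <- sigmoid(scoresF) / m
    }
    grads <- NULL
    for (i in seq_len(m)) {
      grads <- addGradTrees(grads, seqBackward(net, cachesR[[i]], gR[i])$grads)
      grads <- addGradTrees(grads, seqBackward(net, cachesF[[i]], gF[i])$grads)
    }
    up <- rmspropUpdate(net$layers, grads, state, config$lr)
    net$layers <- up$layers
    if (wass) net <- clipNet(net, config$clipValue)
    list(net = net, state = up$state, loss = loss)
  }

  withSeed(deriveSeed(config$seed, 41L), {
    for (step in seq_len(totalSteps)) {
      cA <- numeric(config$nCritic); cB <- numeric(config$nCritic)
      for (ci in seq_len(config$nCritic)) {
        di <- sample.int(nd, config$batchSize, replace = nd < config$batchSize)
        si <- sample.int(ns, config$batchSize, replace = ns < config$batchSize)
        fakeS <- list(); fakeD <- list()
        for (b in seq_along(di)) {
          dIn <- corruptArray(dArr[[di[b]]], config$inputNoiseStd)
          r <- seqForward(model@gds, dIn, ctx); model@gds <- r$net
          fakeS[[b]] <- r$y
          r <- seqForward(model@gsd, sArr[[si[b]]], ctx); model@gsd <- r$net
          fakeD[[b]] <- r$y
        }
        ra <- runCritic(model@da, opt$da, sArr[si], fakeS)
        model@da <- ra$net; opt$da <- ra$state; cA[ci] <- ra$loss
        rb <- runCritic(model@db, opt$db, dArr[di], fakeD)
        model@db <- rb$net; opt$db <- rb$state; cB[ci] <- rb$loss
      }

      # generator update
      di <- sample.int(nd, config$batchSize, replace = nd < config$batchSize)
      si <- sample.int(ns, config$batchSize, replace = ns < config$batchSize)
      m <- config$batchSize
      gGds <- NULL; gGsd <- NULL
      scA <- numeric(m); scB <- numeric(m)
      cycD <- numeric(m); cycS <- numeric(m)
      for (b in seq_len(m)) {
        d0 <- dArr[[di[b]]]; s0 <- sArr[[si[b]]]
        dIn <- corruptArray(d0, config$inputNoiseStd)
        f1 <- seqForward(model@gds, dIn, ctx); model@gds <- f1$net     # fake S
        a1 <- seqForward(model@da, f1$y, ctx); model@da <- a1$net      # critic score
        r1 <- seqForward(model@gsd, f1$y, ctx); model@gsd <- r1$net    # rec D
        f2 <- seqForward(model@gsd, s0, ctx); model@gsd <- f2$net      # fake D
        a2 <- seqForward(model@db, f2$y, ctx); model@db <- a2$net
        r2 <- seqForward(model@gds, f2$y, ctx); model@gds <- r2$net    # rec S
        scA[b] <- a1$y; scB[b] <- a2$y
        cycD[b] <- mean(abs(r1$y - d0)); cycS[b] <- mean(abs(r2$y - s0))

        # adversarial gradient into fake volumes via the critics
        gAdvA <- if (wass) -1 / m else (sigmoid(scA[b]) - 1) / m
        gAdvB <- if (wass) -1 / m else (sigmoid(scB[b]) - 1) / m
        gFakeS <- seqBackward(model@da, a1$caches, gAdvA)$gx
        gFakeD <- seqBackward(model@db, a2$caches, gAdvB)$gx

        lam <- config$lambdaCyc
        if (lam > 0) {
          gRecD <- array(lam * sign(r1$y - d0) / (length(d0) * m), dim(r1$y))
          bb <- seqBackward(model@gsd, r1$caches, gRecD)
          gGsd <- addGradTrees(gGsd, bb$grads)
          gFakeS <- gFakeS + bb$gx
          gRecS <- array(lam * sign(r2$y - s0) / (length(s0) * m), dim(r2$y))
          bb <- seqBackward(model@gds, r2$caches, gRecS)
          gGds <- addGradTrees(gGds, bb$grads)
          gFakeD <- gFakeD + bb$gx
        }
        gGds <- addGradTrees(gGds, seqBackward(model@gds, f1$caches, gFakeS)$grads)
        gGsd <- addGradTrees(gGsd, seqBackward(model@gsd, f2$caches, gFakeD)$grads)
      }
      advDS <- if (wass) wassersteinLosses(0, scA)$genLoss
               else logisticAdversarialLoss(0, scA)$gLoss
      advSD <- if (wass) wassersteinLosses(0, scB)$genLoss
               else logisticAdversarialLoss(0, scB)$gLoss
      cyc <- mean(cycD) + mean(cycS)
      total <- advDS + advSD + config$lambdaCyc * cyc
      if (!all(is.finite(c(advDS, advSD, cyc, cA, cB)))) {
        stop(sprintf("non-finite loss at generator step %d (adv_ds=%g adv_sd=%g cycle=%g)",
                     step, advDS, advSD, cyc))
      }
      up <- rmspropUpdate(model@gds$layers, gGds, opt$gds, config$lr)
      model@gds$layers <- up$layers; opt$gds <- up$state
      up <- rmspropUpdate(model@gsd$layers, gGsd, opt$gsd, config$lr)
      model@gsd$layers <- up$layers; opt$gsd <- up$state

      hist[[step]] <- data.frame(step = step, adv_ds = advDS, adv_sd = advSD,
                                 cycle = cyc, critic_a = mean(cA),
                                 critic_b = mean(cB), total = total)
      if (verbose && (step %% stepsPerEpoch == 0)) {
        message(sprintf("step %d/%d: adv_ds %.4f adv_sd %.4f cycle %.4f",
                        step, totalSteps, advDS, advSD, cyc))
      }
    }
  })
  history <- do.call(rbind, hist)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    write.csv(history, file.path(outDir, "history.csv"), row.names = FALSE)
    saveCheckpoint(model, file.path(outDir, "checkpoint.rds"))
    yaml::write_yaml(unclass(config), file.path(outDir, "config.yaml"))
  }
  list(model = model, history = history)
}

corruptArray <- function(x, noiseStd) {
  if (noiseStd <= 0) return(x)
  dr <- diff(range(x)); if (dr == 0) dr <- 1
  x + array(rnorm(length(x), sd = noiseStd * dr), dim(x))
}
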