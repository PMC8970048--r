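# Minimal dense 3D conv-net engine: explicit forward/backward passes over a
# small set of layer types (conv, fractional-stride conv, instance norm,
# activations, dropout, residual blocks, noise-channel concat, global mean).
# Volumes flow through as (n, n, n, channels) arrays. All randomness uses the
# ambient R RNG stream so callers control determinism with set.seed().

NN_EPS <- 1e-5

initW <- function(k, cin, cout) array(rnorm(k^3 * cin * cout, sd = 0.02), c(k, k, k, cin, cout))

nnConv <- function(k, stride, pad, cin, cout, reflect = FALSE, sn = FALSE) {
  list(type = "conv", k = k, stride = stride, pad = pad, cin = cin, cout = cout,
       reflect = reflect, sn = sn,
       params = list(w = initW(k, cin, cout), b = numeric(cout)),
       sn_u = if (sn) {u <- rnorm(cout); u / l2(u)} else NULL)
}

# fractional-stride (x2 upsampling) convolution; weight stored in the layout
# of its adjoint stride-2 convolution: (k, k, k, cout, cin)
nnTConv <- function(cin, cout) {
  list(type = "tconv", k = 3L, stride = 2L, pad = 1L, cin = cin, cout = cout,
       params = list(w = initW(3L, cout, cin), b = numeric(cout)))
}

nnINorm <- function() list(type = "inorm", params = list())
nnAct <- function(f) list(type = "act", f = f, params = list())
nnDropout <- function() list(type = "dropout", params = list())  # rate from ctx
nnNoiseCat <- function() list(type = "noise_cat", params = list())
nnGMean <- function() list(type = "gmean", params = list())

nnRes <- function(c) {
  list(type = "res", params = list(),
       sub = list(nnConv(3L, 1L, 1L, c, c), nnINorm(), nnAct("relu"),
                  nnConv(3L, 1L, 1L, c, c), nnINorm(), nnDropout()))
}

reflectIdx <- function(n, p) {
  j <- seq_len(n + 2 * p) - p
  j <- ifelse(j < 1, 2 - j, j)
  ifelse(j > n, 2 * n - j, j)
}

padReflect <- function(x, p) {
  d <- dim(x)
  ii <- reflectIdx(d[1], p)
  x[ii, ii, ii, , drop = FALSE]
}

foldReflect <- function(gxp, n, p, cin) {
  ii <- reflectIdx(n, p)
  np <- n + 2 * p
  lin <- array(0, c(np, np, np))
  src <- as.integer(ii)
  lin[] <- src[slice.index(lin, 1)] +
    n * (src[slice.index(lin, 2)] - 1) +
    n * n * (src[slice.index(lin, 3)] - 1)
  gx <- array(0, c(n, n, n, cin))
  for (c in seq_len(cin)) {
    acc <- rowsum(as.numeric(gxp[, , , c]), group = as.integer(lin), reorder = TRUE)
    g <- numeric(n^3)
    g[as.integer(rownames(acc))] <- acc[, 1]
    gx[, , , c] <- g
  }
  gx
}

# power iteration on M (rest x cout); returns sigma and updated vectors
powerIterSigma <- function(M, u, iters) {
  for (i in seq_len(iters)) {
    v <- M %*% u; v <- v / max(l2(v), 1e-12)
    u <- crossprod(M, v); u <- u / max(l2(u), 1e-12)
  }
  v <- M %*% u; nv <- max(l2(v), 1e-12)
  list(sigma = as.numeric(nv), u = as.numeric(u), v = as.numeric(v / nv))
}

addBias <- function(y, b) {
  d <- dim(y)
  y + rep(b, each = prod(d[1:3]))
}

chanSums <- function(g) {
  d <- dim(g)
  colSums(matrix(g, nrow = prod(d[1:3]), ncol = d[4]))
}

layerForward <- function(l, x, ctx) {
  switch(l$type,
    conv = {
      w <- l$params$w
      snc <- NULL
      if (isTRUE(l$sn) && isTRUE(ctx$spectralNorm)) {
        M <- matrix(w, ncol = l$cout)
        pi <- powerIterSigma(M, l$sn_u, ctx$snIters %||% 2L)
        l$sn_u <- pi$u
        snc <- list(sigma = pi$sigma, u = pi$u, v = pi$v)
        w <- w / pi$sigma
      }
      xin <- if (l$reflect) padReflect(x, l$pad) else x
      p <- if (l$reflect) 0L else l$pad
      y <- cg_conv3d_fwd(xin, dim(xin), w, dim(w), l$stride, p)
      y <- addBias(y, l$params$b)
      list(y = y, cache = list(xin = xin, xdim = dim(x), sn = snc, weff = if (is.null(snc)) NULL else w), layer = l)
    },
    tconv = {
      w <- l$params$w
      d <- dim(x)
      ydim <- c(d[1] * 2L, d[2] * 2L, d[3] * 2L, l$cout)
      y <- cg_conv3d_bwd_x(x, dim(x), w, dim(w), l$stride, l$pad, ydim)
      y <- addBias(y, l$params$b)
      list(y = y, cache = list(x = x, ydim = ydim), layer = l)
    },
    inorm = {
      d <- dim(x)
      m <- prod(d[1:3])
      xm <- matrix(x, m, d[4])
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      v <- colMeans(xc^2)
      istd <- 1 / sqrt(v + NN_EPS)
      xhat <- sweep(xc, 2, istd, "*")
      y <- array(xhat, d)
      list(y = y, cache = list(xhat = xhat, istd = istd, d = d), layer = l)
    },
    act = {
      y <- switch(l$f,
        relu = pmax(x, 0),
        lrelu = ifelse(x > 0, x, 0.2 * x),
        tanh = tanh(x))
      list(y = y, cache = list(x = x, y = y), layer = l)
    },
    dropout = {
      rate <- ctx$dropoutRate %||% 0
      if (isTRUE(ctx$dropoutOn) && rate > 0) {
        mask <- array((runif(length(x)) >= rate) / (1 - rate), dim(x))
        list(y = x * mask, cache = list(mask = mask), layer = l)
      } else {
        list(y = x, cache = list(mask = NULL), layer = l)
      }
    },
    noise_cat = {
      d <- dim(x)
      noise <- if (!is.null(ctx$noiseSeed)) {
        withSeed(deriveSeed(ctx$noiseSeed, 77L), array(rnorm(prod(d[1:3])), c(d[1:3], 1L)))
      } else {
        array(rnorm(prod(d[1:3])), c(d[1:3], 1L))
      }
      y <- array(c(x, noise), c(d[1:3], d[4] + 1L))
      list(y = y, cache = list(cin = d[4]), layer = l)
    },
    gmean = {
      list(y = mean(x), cache = list(d = dim(x)), layer = l)
    },
    res = {
      sub <- l$sub
      caches <- vector("list", length(sub))
      h <- x
      for (i in seq_along(sub)) {
        r <- layerForward(sub[[i]], h, ctx)
        h <- r$y; caches[[i]] <- r$cache; sub[[i]] <- r$layer
      }
      l$sub <- sub
      list(y = x + h, cache = list(sub = caches), layer = l)
    },
    stop("unknown layer type ", l$type))
}

layerBackward <- function(l, cache, gy) {
  switch(l$type,
    conv = {
      p <- if (l$reflect) 0L else l$pad
      w <- if (is.null(cache$sn)) l$params$w else cache$weff
      gw <- cg_conv3d_bwd_w(cache$xin, dim(cache$xin), gy, dim(gy), l$k, l$stride, p)
      gxp <- cg_conv3d_bwd_x(gy, dim(gy), w, dim(w), l$stride, p, dim(cache$xin))
      gx <- if (l$reflect) foldReflect(gxp, cache$xdim[1], l$pad, l$cin) else gxp
      gb <- chanSums(gy)
      if (!is.null(cache$sn)) {
        # w_eff = w / sigma; d sigma / d w = v u^T (as (rest x cout))
        s <- cache$sn$sigma
        inner <- sum(gw * l$params$w) / s^2
        gw <- gw / s - inner * array(outer(cache$sn$v, cache$sn$u), dim(gw))
      }
      list(gx = gx, grads = list(w = gw, b = gb))
    },
    tconv = {
      w <- l$params$w
      gx <- cg_conv3d_fwd(gy, dim(gy), w, dim(w), l$stride, l$pad)
      gw <- cg_conv3d_bwd_w(gy, dim(gy), cache$x, dim(cache$x), l$k, l$stride, l$pad)
      gb <- chanSums(gy)
      list(gx = gx, grads = list(w = gw, b = gb))
    },
    inorm = {
      d <- cache$d
      m <- prod(d[1:3])
      gym <- matrix(gy, m, d[4])
      mg <- colMeans(gym)
      mgx <- colMeans(gym * cache$xhat)
      gx <- sweep(gym, 2, mg) - sweep(cache$xhat, 2, mgx, "*")
      gx <- sweep(gx, 2, cache$istd, "*")
      list(gx = array(gx, d), grads = NULL)
    },
    act = {
      gx <- switch(l$f,
        relu = gy * (cache$x > 0),
        lrelu = gy * ifelse(cache$x > 0, 1, 0.2),
        tanh = gy * (1 - cache$y^2))
      list(gx = gx, grads = NULL)
    },
    dropout = {
      gx <- if (is.null(cache$mask)) gy else gy * cache$mask
      list(gx = gx, grads = NULL)
    },
    noise_cat = {
      cin <- cache$cin
      list(gx = gy[, , , seq_len(cin), drop = FALSE], grads = NULL)
    },
    gmean = {
      d <- cache$d
      list(gx = array(gy / prod(d), d), grads = NULL)
    },
    res = {
      sub <- l$sub
      g <- gy
      grads <- vector("list", length(sub))
      for (i in rev(seq_along(sub))) {
        r <- layerBackward(sub[[i]], cache$sub[[i]], g)
        g <- r$gx; grads[i] <- list(r$grads)
      }
      list(gx = gy + g, grads = list(sub = grads))
    },
    stop("unknown layer type ", l$type))
}

seqForward <- function(net, x, ctx) {
  caches <- vector("list", length(net$layers))
  h <- x
  for (i in seq_along(net$layers)) {
    r <- layerForward(net$layers[[i]], h, ctx)
    h <- r$y; caches[[i]] <- r$cache; net$layers[[i]] <- r$layer
  }
  list(y = h, caches = caches, net = net)
}

seqBackward <- function(net, caches, gy) {
  g <- gy
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    r <- layerBackward(net$layers[[i]], caches[[i]], g)
    g <- r$gx; grads[i] <- list(r$grads)
  }
  list(gx = g, grads = grads)
}

# ---- parameter traversal ----------------------------------------------------

mapParams <- function(layers, grads = NULL, f) {
  # applies f(param_array, grad_array_or_NULL, path) to every parameter,
  # returning layers with updated params
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "res") {
      l$sub <- mapParams(l$sub, if (is.null(grads)) NULL else grads[[i]]$sub, f)
    } else if (length(l$params)) {
      for (pn in names(l$params)) {
        g <- if (is.null(grads) || is.null(grads[[i]])) NULL else grads[[i]][[pn]]
        l$params[[pn]] <- f(l$params[[pn]], g)
      }
    }
    layers[[i]] <- l
  }
  layers
}

collectParams <- function(layers) {
  out <- list()
  walk <- function(ls, prefix) {
    for (i in seq_along(ls)) {
      l <- ls[[i]]
      if (l$type == "res") walk(l$sub, paste0(prefix, i, "."))
      else for (pn in names(l$params))
        out[[paste0(prefix, i, ".", pn)]] <<- l$params[[pn]]
    }
  }
  walk(layers, "")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
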