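# Internal helpers: seeding, FFT grids, parameter counting.

# Deterministic seed fan-out: one user-facing seed expands into independent
# per-component streams via a fixed polynomial hash modulo a Mersenne-ish
# prime below 2^31. Documented in the methods vignette.
deriveSeed <- function(seed, ...) {
  ix <- c(...)
  h <- as.double(seed %% 2147483629L)
  for (v in ix) {
    h <- (h * 48271 + (as.double(v) %% 2147483629)) %% 2147483629
  }
  as.integer(h)
}

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# DFT sample frequencies in cycles/voxel, matching the layout of stats::fft.
fftfreq <- function(n) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / n
}

countParams <- function(net) {
  sum(vapply(collectParams(net$layers), length, numeric(1)))
}

vmat <- function(x) as.numeric(x)  # flatten array

l2 <- function(x) sqrt(sum(x * x))
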