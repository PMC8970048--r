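# Classical physics-based subtomogram simulator: random pose, MTF blur,
# missing wedge, additive Gaussian noise at a target SNR; plus the toy
# structure factory and the two-domain fixture generator used throughout the
# test suite in place of archive-derived data.

TOY_CLASSES <- c("sphere", "shell", "dumbbell", "rod")

#' Simulation parameters for the classical subtomogram pipeline
#'
#' @param snr target signal-to-noise ratio, defined as var(signal)/var(noise);
#'   \code{NULL} or \code{Inf} disables noise. Default 0.5, typical of
#'   experimental subtomogram data.
#' @param wedgeAngle missing-wedge half-angle in degrees (\code{0 <= a < 90});
#'   default 30, the single-tilt convention for a +/-60 degree tilt range.
#'   \code{0} disables the wedge.
#' @param mtfSigma width (cycles/voxel) of the radial Gaussian modulation
#'   transfer function; \code{NULL} disables the blur. Default 0.25.
#' @param rotation numeric(3) intrinsic Z-Y-Z Euler angles in degrees, or
#'   \code{"random"} for a uniform rotation.
#' @param translation numeric(3) voxel offsets, or \code{"random"} (uniform in
#'   +/- n/10 voxels per axis).
#' @param seed RNG seed for pose and noise draws.
#' @return A \code{SimulationParams} list.
#' @export
simulationParams <- function(snr = 0.5, wedgeAngle = 30, mtfSigma = 0.25,
                             rotation = "random", translation = "random",
                             seed = NULL) {
  if (!is.null(snr) && !is.infinite(snr) && snr <= 0) stop("snr must be > 0 (or NULL/Inf for noise-free)")
  if (wedgeAngle < 0 || wedgeAngle >= 90) stop("wedgeAngle must be in [0, 90)")
  if (!is.null(mtfSigma) && mtfSigma <= 0) stop("mtfSigma must be > 0 or NULL")
  structure(list(snr = snr, wedgeAngle = wedgeAngle, mtfSigma = mtfSigma,
                 rotation = rotation, translation = translation, seed = seed),
            class = "SimulationParams")
}

#' Generate a toy macromolecule density map
#'
#' Four shape families with smooth (error-function-like) edges stand in for
#' distinct macromolecule classes: a solid sphere, a concentric shell, a
#' two-lobe dumbbell and an elongated rod. The seed drives small
#' within-class size/orientation jitter, so one class yields a population of
#' related but non-identical structures.
#'
#' @param classId one of \code{"sphere"}, \code{"shell"}, \code{"dumbbell"},
#'   \code{"rod"}.
#' @param n side length in voxels.
#' @param amplitude peak density value (0 gives an all-zero map).
#' @param seed RNG seed; fixed seed gives a deterministic volume.
#' @return A nonnegative \linkS4class{TomoVolume}.
#' @export
makeToyDensity <- function(classId, n = 16, amplitude = 1, seed = 1) {
  if (!classId %in% TOY_CLASSES) {
    stop("unknown class '", classId, "'; known classes: ",
         paste(TOY_CLASSES, collapse = ", "))
  }
  withSeed(deriveSeed(seed, 101L), {
    c0 <- (n + 1) / 2
    ax <- seq_len(n) - c0
    X <- array(rep(ax, times = n * n), c(n, n, n))
    Y <- array(rep(rep(ax, each = n), times = n), c(n, n, n))
    Z <- array(rep(ax, each = n * n), c(n, n, n))
    soft <- function(d) 1 / (1 + exp(4 * d))  # smooth inside/outside step, ~1 voxel edge
    jitter <- function(lo, hi) runif(1, lo, hi)
    vol <- switch(classId,
      sphere = {
        r <- n * jitter(0.24, 0.30)
        soft(sqrt(X^2 + Y^2 + Z^2) - r)
      },
      shell = {
        r <- n * jitter(0.30, 0.36); w <- n * jitter(0.05, 0.08)
        d <- abs(sqrt(X^2 + Y^2 + Z^2) - r)
        soft(d - w)
      },
      dumbbell = {
        sep <- n * jitter(0.16, 0.22); r <- n * jitter(0.13, 0.17)
        th <- runif(1, 0, pi); ph <- runif(1, 0, 2 * pi)
        u <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
        d1 <- sqrt((X - sep * u[1])^2 + (Y - sep * u[2])^2 + (Z - sep * u[3])^2)
        d2 <- sqrt((X + sep * u[1])^2 + (Y + sep * u[2])^2 + (Z + sep * u[3])^2)
        pmax(soft(d1 - r), soft(d2 - r))
      },
      rod = {
        len <- n * jitter(0.34, 0.42); r <- n * jitter(0.08, 0.11)
        # axis along x with small random tilt
        tilt <- runif(2, -0.2, 0.2)
        u <- c(1, tilt) / sqrt(1 + sum(tilt^2))
        proj <- X * u[1] + Y * u[2] + Z * u[3]
        perp <- sqrt(pmax(X^2 + Y^2 + Z^2 - proj^2, 0))
        ax_d <- pmax(abs(proj) - len, 0)
        soft(sqrt(perp^2 + ax_d^2) - r)
      })
    TomoVolume(amplitude * vol, provenance = sprintf("toy:%s(seed=%d)", classId, seed))
  })
}

eulerZYZ <- function(a, b, g) {
  # intrinsic Z-Y-Z rotation, angles in degrees
  d <- pi / 180
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  Rz(a * d) %*% Ry(b * d) %*% Rz(g * d)
}

randomRotationMatrix <- function() {
  # uniform over SO(3) via a random unit quaternion
  q <- rnorm(4); q <- q / l2(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

#' Rotate and translate a volume (trilinear interpolation)
#'
#' The volume is rotated about its centre and then shifted; voxels mapped
#' from outside the input support are filled with \code{fill}. With
#' \code{"random"} the rotation is uniform over SO(3) and the translation
#' uniform in +/- n/10 voxels per axis, both drawn from \code{seed}.
#'
#' @param volume a \linkS4class{TomoVolume}.
#' @param rotation numeric(3) intrinsic Z-Y-Z Euler angles (degrees) or
#'   \code{"random"}.
#' @param translation numeric(3) voxel offsets or \code{"random"}.
#' @param seed RNG seed used when either argument is \code{"random"}.
#' @param fill background value for unmapped voxels (default 0).
#' @return The transformed \linkS4class{TomoVolume}.
#' @export
rotateTranslate <- function(volume, rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            seed = 1, fill = 0) {
  n <- sideLength(volume)
  withSeed(deriveSeed(seed, 202L), {
    R <- if (identical(rotation, "random")) randomRotationMatrix()
         else eulerZYZ(rotation[1], rotation[2], rotation[3])
    tr <- if (identical(translation, "random")) runif(3, -n / 10, n / 10)
          else as.numeric(translation)
    c0 <- (n + 1) / 2
    g <- seq_len(n) - c0
    P <- cbind(rep(g, times = n * n),
               rep(rep(g, each = n), times = n),
               rep(g, each = n * n))
    # inverse map: source = R^-1 (target - t)
    Q <- sweep(P, 2, tr) %*% R  # (R^T) applied from the right == R^-1 %*% q
    sx <- Q[, 1] + c0; sy <- Q[, 2] + c0; sz <- Q[, 3] + c0
    out <- trilinear(volume@data, sx, sy, sz, fill)
    TomoVolume(array(out, c(n, n, n)), voxelSpacing = volume@voxelSpacing,
               provenance = paste0(volume@provenance, "|pose"))
  })
}

trilinear <- function(a, sx, sy, sz, fill) {
  n <- dim(a)
  x0 <- floor(sx); y0 <- floor(sy); z0 <- floor(sz)
  fx <- sx - x0; fy <- sy - y0; fz <- sz - z0
  val <- numeric(length(sx))
  at <- function(ix, iy, iz) {
    ok <- ix >= 1 & ix <= n[1] & iy >= 1 & iy <= n[2] & iz >= 1 & iz <= n[3]
    v <- rep(fill, length(ix))
    idx <- ix[ok] + n[1] * (iy[ok] - 1 + n[2] * (iz[ok] - 1))
    v[ok] <- a[idx]
    v
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) * (if (dz) fz else 1 - fz)
    val <- val + w * at(x0 + dx, y0 + dy, z0 + dz)
  }
  val
}

#' Apply a Gaussian modulation transfer function
#'
#' Multiplies the 3D Fourier transform by the radially symmetric low-pass
#' filter \code{exp(-f^2 / (2 sigma^2))}, with \code{f} the spatial frequency
#' in cycles/voxel; this emulates detector/optics attenuation of high
#' frequencies. \code{mtfSigma = NULL} is the identity.
#'
#' @param volume a \linkS4class{TomoVolume}.
#' @param mtfSigma Gaussian width in cycles/voxel (> 0), or \code{NULL}.
#' @return The filtered, real-valued \linkS4class{TomoVolume}.
#' @export
applyMTF <- function(volume, mtfSigma = 0.25) {
  if (is.null(mtfSigma)) return(volume)
  stopifnot(mtfSigma > 0)
  n <- sideLength(volume)
  f <- fftfreq(n)
  F2 <- outer(outer(f^2, f^2, "+"), f^2, "+")
  H <- exp(-F2 / (2 * mtfSigma^2))
  y <- Re(fft(fft(volume@data) * H, inverse = TRUE)) / n^3
  TomoVolume(y, voxelSpacing = volume@voxelSpacing,
             provenance = paste0(volume@provenance, "|mtf"))
}

#' Zero the missing wedge in Fourier space
#'
#' Single-tilt convention (tilt axis y): all Fourier coefficients whose
#' (k_x, k_z) direction lies within \code{wedgeAngle} degrees of the k_z axis
#' are set to zero; the line k_x = k_z = 0 (which contains the DC term) is
#' kept. An angle of 0 is the identity; the operator is an idempotent
#' orthogonal projection.
#'
#' @param volume a \linkS4class{TomoVolume}.
#' @param wedgeAngle half-angle in degrees, \code{0 <= a < 90}.
#' @return The wedge-filtered \linkS4class{TomoVolume}.
#' @export
applyMissingWedge <- function(volume, wedgeAngle = 30) {
  if (wedgeAngle < 0 || wedgeAngle >= 90) stop("wedgeAngle must be in [0, 90)")
  if (wedgeAngle == 0) return(volume)
  n <- sideLength(volume)
  mask <- 1 - missingWedgeMask(n, wedgeAngle)
  y <- Re(fft(fft(volume@data) * mask, inverse = TRUE)) / n^3
  TomoVolume(y, voxelSpacing = volume@voxelSpacing,
             provenance = paste0(volume@provenance, "|wedge"))
}

# 1 inside the missing wedge (coefficients to remove), 0 elsewhere.
missingWedgeMask <- function(n, wedgeAngle) {
  f <- fftfreq(n)
  kx <- array(rep(abs(f), times = n * n), c(n, n, n))
  kz <- array(rep(abs(f), each = n * n), c(n, n, n))
  ang <- atan2(kx, kz) * 180 / pi
  mask <- (ang < wedgeAngle) & !(kx == 0 & kz == 0)
  storage.mode(mask) <- "double"
  mask
}

#' Add Gaussian noise to reach a target SNR
#'
#' Adds zero-mean Gaussian noise with variance \code{var(signal)/snr}
#' (SNR as a variance ratio, the dominant cryo-ET convention).
#'
#' @param volume a \linkS4class{TomoVolume} with non-constant values.
#' @param snr target SNR (> 0); \code{NULL}/\code{Inf} returns the input.
#' @param seed RNG seed; fixed seed gives identical noise.
#' @return The noisy \linkS4class{TomoVolume}.
#' @export
addNoiseToSNR <- function(volume, snr = 0.5, seed = 1) {
  if (is.null(snr) || is.infinite(snr)) return(volume)
  stopifnot(snr > 0)
  v <- var(as.numeric(volume@data))
  if (v == 0) stop("signal variance is zero; SNR is undefined for a constant volume")
  withSeed(deriveSeed(seed, 303L), {
    noise <- array(rnorm(length(volume@data), sd = sqrt(v / snr)), dim(volume@data))
    TomoVolume(volume@data + noise, voxelSpacing = volume@voxelSpacing,
               provenance = paste0(volume@provenance, "|noise"))
  })
}

#' Simulate a subtomogram from a density map (classical baseline)
#'
#' Composes the classical degradation pipeline in physical acquisition order:
#' random pose (rotation + translation), MTF blur, missing wedge, additive
#' Gaussian noise at the target SNR, then symmetric min-max normalization to
#' [-1, 1].
#'
#' @param density a clean \linkS4class{TomoVolume} density map.
#' @param params a \code{\link{simulationParams}} object.
#' @return A normalized simulated subtomogram (\linkS4class{TomoVolume}).
#' @export
simulateSubtomogram <- function(density, params = simulationParams()) {
  seed <- if (is.null(params$seed)) 1L else params$seed
  v <- rotateTranslate(density, params$rotation, params$translation, seed = seed)
  v <- applyMTF(v, params$mtfSigma)
  if (params$wedgeAngle > 0) v <- applyMissingWedge(v, params$wedgeAngle)
  if (!is.null(params$snr) && !is.infinite(params$snr) &&
      var(as.numeric(v@data)) > 0) {
    v <- addNoiseToSNR(v, params$snr, seed = deriveSeed(seed, 7L))
  }
  normalizeVolume(v, "minmax_sym")
}

#' Generate the unpaired two-domain fixture datasets
#'
#' Builds domain D (clean, normalized toy density maps of the requested
#' classes) and domain S (classically degraded subtomograms of independently
#' drawn instances of the same classes). The two domains are unpaired: the S
#' volumes come from different structure seeds and poses than the D volumes.
#'
#' @param nPerClass volumes per class and domain.
#' @param classes character vector of toy class ids (default all four).
#' @param size side length in voxels.
#' @param params \code{\link{simulationParams}} controlling the degradation
#'   of domain S.
#' @param seed global seed for the fixture.
#' @param outDir if non-NULL, volumes + manifests are written there as MRC/CSV.
#' @return \code{list(D = , S = )} of \linkS4class{DomainDataset}s.
#' @export
generateFixtureDatasets <- function(nPerClass, classes = TOY_CLASSES, size = 16,
                                    params = simulationParams(), seed = 1,
                                    outDir = NULL) {
  stopifnot(nPerClass >= 1)
  mk <- function(domain) {
    vols <- list(); labels <- character(0); idx <- 0L
    domOff <- if (domain == "D") 0L else 500000L
    for (ci in seq_along(classes)) {
      for (j in seq_len(nPerClass)) {
        idx <- idx + 1L
        s <- deriveSeed(seed, domOff, ci * 1000L + j)
        d <- makeToyDensity(classes[ci], n = size, seed = s)
        vols[[idx]] <- if (domain == "D") {
          normalizeVolume(rotateTranslate(d, "random", "random", seed = s), "minmax_sym")
        } else {
          p <- params; p$seed <- s
          simulateSubtomogram(d, p)
        }
        labels[idx] <- classes[ci]
      }
    }
    DomainDataset(vols, domain = domain, labels = labels)
  }
  out <- list(D = mk("D"), S = mk("S"))
  if (!is.null(outDir)) {
    writeDataset(out$D, outDir, "d")
    writeDataset(out$S, outDir, "s")
  }
  out
}
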