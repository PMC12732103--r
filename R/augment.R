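#' Medically safe 3D augmentation policy
#'
#' Random axis flips, small rotations (<= 10 degrees by default), Gaussian
#' blur, multiplicative intensity jitter (+/- 10% by default), and random 3D
#' crops. The defaults stay in the clinically safe regime: geometry is
#' perturbed too little to change anatomy, intensity too little to mimic
#' pathology.
#'
#' @param flipAxes logical length-3: which axes may be flipped.
#' @param flipProb probability of flipping each allowed axis.
#' @param rotationLimit maximum rotation angle in degrees (<= 10 by default;
#'   0 disables rotation).
#' @param blurSigmaRange range of the Gaussian blur sigma in voxels;
#'   `c(0, 0)` disables blur.
#' @param jitter intensity jitter fraction j: a factor drawn uniformly from
#'   `[1 - j, 1 + j]` (0 disables).
#' @param cropSize crop edge length in voxels; the crop is zero-padded back
#'   to the source grid at a random offset, so tensor shape is preserved.
#'   Equal to the grid size disables cropping.
#' @return list of class `"augmentationPolicy"`.
#' @export
augmentationPolicy <- function(flipAxes = c(TRUE, FALSE, FALSE),
                               flipProb = 0.5, rotationLimit = 10,
                               blurSigmaRange = c(0, 0.8), jitter = 0.1,
                               cropSize = NULL) {
  if (rotationLimit < 0 || rotationLimit > 45)
    stop("rotationLimit must lie in [0, 45] degrees", call. = FALSE)
  if (jitter < 0 || jitter > 0.5)
    stop("jitter must lie in [0, 0.5]", call. = FALSE)
  p <- list(flipAxes = flipAxes, flipProb = flipProb,
            rotationLimit = rotationLimit,
            blurSigmaRange = sort(blurSigmaRange), jitter = jitter,
            cropSize = cropSize)
  class(p) <- "augmentationPolicy"
  p
}

flipArray <- function(a, axis) {
  n <- dim(a)[axis]
  idx <- rev(seq_len(n))
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# Rotate a cubic array about a random coordinate axis by `theta` radians,
# trilinear interpolation for intensities, nearest neighbour for masks.
rotateArray <- function(a, theta, axis, nearest = FALSE) {
  n <- dim(a)[1]
  ctr <- (n + 1) / 2
  g <- seq_len(n) - ctr
  co <- expand.grid(x = g, y = g, z = g)
  cs <- cos(-theta); sn <- sin(-theta)   # inverse map
  if (axis == 1L) {
    xs <- co$x; ys <- cs * co$y - sn * co$z; zs <- sn * co$y + cs * co$z
  } else if (axis == 2L) {
    xs <- cs * co$x + sn * co$z; ys <- co$y; zs <- -sn * co$x + cs * co$z
  } else {
    xs <- cs * co$x - sn * co$y; ys <- sn * co$x + cs * co$y; zs <- co$z
  }
  xs <- xs + ctr; ys <- ys + ctr; zs <- zs + ctr
  if (nearest) {
    xi <- round(xs); yi <- round(ys); zi <- round(zs)
    ok <- xi >= 1 & xi <= n & yi >= 1 & yi <= n & zi >= 1 & zi <= n
    out <- numeric(n^3)
    lin <- xi + (yi - 1) * n + (zi - 1) * n^2
    out[ok] <- a[lin[ok]]
    return(array(out, dim(a)))
  }
  x0 <- floor(xs); y0 <- floor(ys); z0 <- floor(zs)
  fx <- xs - x0; fy <- ys - y0; fz <- zs - z0
  out <- numeric(n^3)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
    w <- (dx * fx + (1 - dx) * (1 - fx)) *
         (dy * fy + (1 - dy) * (1 - fy)) *
         (dz * fz + (1 - dz) * (1 - fz))
    ok <- xi >= 1 & xi <= n & yi >= 1 & yi <= n & zi >= 1 & zi <= n
    lin <- xi + (yi - 1) * n + (zi - 1) * n^2
    out[ok] <- out[ok] + w[ok] * a[lin[ok]]
  }
  array(out, dim(a))
}

gaussKernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

blurArray <- function(a, sigma) {
  if (sigma <= 0) return(a)
  k <- gaussKernel1d(sigma)
  n <- dim(a)[1]
  conv1 <- function(m) {
    # m: n x (..) matrix, filter along rows with zero padding
    out <- m * k[(length(k) + 1) / 2]
    r <- (length(k) - 1) / 2
    for (s in seq_len(r)) {
      w <- k[(length(k) + 1) / 2 + s]
      out[seq_len(n - s), ] <- out[seq_len(n - s), ] +
        w * m[(s + 1):n, , drop = FALSE]
      out[(s + 1):n, ] <- out[(s + 1):n, ] +
        w * m[seq_len(n - s), , drop = FALSE]
    }
    out
  }
  d <- dim(a)
  # axis 1
  a <- array(conv1(matrix(a, n, n * n)), d)
  # axis 2
  a <- aperm(array(conv1(matrix(aperm(a, c(2, 1, 3)), n, n * n)),
                   c(n, n, n)), c(2, 1, 3))
  # axis 3
  a <- aperm(array(conv1(matrix(aperm(a, c(3, 2, 1)), n, n * n)),
                   c(n, n, n)), c(3, 2, 1))
  a
}

#' Apply a random augmentation to a volume
#'
#' Composition of flip, rotation, blur, multiplicative intensity jitter and
#' random crop per the policy; the mask is transformed identically
#' (geometric operations only). Deterministic given the RNG state: call
#' `set.seed()` beforehand to reproduce an augmentation.
#'
#' @param v a [BrainVolume-class].
#' @param policy an [augmentationPolicy()].
#' @return an augmented [BrainVolume-class].
#' @export
augmentVolume <- function(v, policy = augmentationPolicy()) {
  stopifnot(is(v, "BrainVolume"), inherits(policy, "augmentationPolicy"))
  n <- dim(v@data)[1]
  crop <- policy$cropSize %||% n
  if (crop > n)
    stop("crop size larger than the volume grid", call. = FALSE)
  dat <- v@data
  msk <- v@mask * 1
  for (ax in 1:3) {
    if (policy$flipAxes[ax] && runif(1) < policy$flipProb) {
      dat <- flipArray(dat, ax)
      msk <- flipArray(msk, ax)
    }
  }
  if (policy$rotationLimit > 0) {
    theta <- runif(1, -policy$rotationLimit, policy$rotationLimit) * pi / 180
    axis <- sample.int(3L, 1L)
    if (abs(theta) > 1e-12) {
      dat <- rotateArray(dat, theta, axis)
      msk <- rotateArray(msk, theta, axis, nearest = TRUE)
    }
  }
  sigma <- runif(1, policy$blurSigmaRange[1], policy$blurSigmaRange[2])
  if (sigma > 0) dat <- blurArray(dat, sigma)
  if (policy$jitter > 0) {
    fac <- runif(1, 1 - policy$jitter, 1 + policy$jitter)
    dat <- dat * fac
  }
  if (crop < n) {
    lo <- sapply(1:3, function(i) sample.int(n - crop + 1L, 1L))
    sel <- lapply(lo, function(s) s:(s + crop - 1L))
    sub <- dat[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
    subM <- msk[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
    off <- sapply(1:3, function(i) sample.int(n - crop + 1L, 1L))
    dat <- array(0, dim(v@data)); mskN <- array(0, dim(v@data))
    dat[off[1]:(off[1] + crop - 1L), off[2]:(off[2] + crop - 1L),
        off[3]:(off[3] + crop - 1L)] <- sub
    mskN[off[1]:(off[1] + crop - 1L), off[2]:(off[2] + crop - 1L),
         off[3]:(off[3] + crop - 1L)] <- subM
    msk <- mskN
  }
  mlog <- array(msk > 0.5, dim(v@data))
  if (!any(mlog)) mlog <- v@mask  # degenerate geometry: keep original mask
  initialize(v, data = dat, mask = mlog)
}
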