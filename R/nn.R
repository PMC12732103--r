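# Minimal dense 3D conv-net machinery with explicit forward/backward passes.
# Volumes travel as matrices with rows = voxels stacked sample-major
# ((sample-1)*V + voxel) and columns = channels, so every convolution is one
# im2col gather plus one BLAS GEMM; gradients are exact, which the
# stop-gradient and gradient-reversal contracts are tested against.

.nnCache <- new.env(parent = emptyenv())

# Neighborhood index map for a cubic grid: for each output voxel, the linear
# input indices of its kernel^3 neighborhood (NA -> zero padding sentinel).
convIndex <- function(n, stride = 1L, kernel = 3L) {
  key <- sprintf("idx_%d_%d_%d", n, stride, kernel)
  if (!is.null(.nnCache[[key]])) return(.nnCache[[key]])
  no <- n %/% stride
  centers <- (seq_len(no) - 1L) * stride + 1L + (stride - 1L)  # 1 or 2i-1
  if (stride == 1L) centers <- seq_len(no)
  offs <- if (kernel == 3L) -1L:1L else 0L
  co <- as.matrix(expand.grid(x = seq_len(no), y = seq_len(no),
                              z = seq_len(no)))
  idx <- matrix(NA_integer_, no^3, kernel^3)
  k <- 0L
  for (dz in offs) for (dy in offs) for (dx in offs) {
    k <- k + 1L
    xx <- centers[co[, 1]] + dx
    yy <- centers[co[, 2]] + dy
    zz <- centers[co[, 3]] + dz
    ok <- xx >= 1L & xx <= n & yy >= 1L & yy <= n & zz >= 1L & zz <= n
    lin <- xx + (yy - 1L) * n + (zz - 1L) * n^2
    lin[!ok] <- NA_integer_
    idx[, k] <- lin
  }
  out <- list(no = no, idx = idx, kernel = kernel)
  .nnCache[[key]] <- out
  out
}

# Batched index: sample-major row offsets, NA -> sentinel row (all-zero).
batchIndex <- function(n, stride, kernel, N) {
  key <- sprintf("bidx_%d_%d_%d_%d", n, stride, kernel, N)
  if (!is.null(.nnCache[[key]])) return(.nnCache[[key]])
  ci <- convIndex(n, stride, kernel)
  V <- n^3; Vo <- ci$no^3; K <- kernel^3
  sentinel <- N * V + 1L
  base <- ci$idx
  big <- matrix(0L, N * Vo, K)
  for (q in seq_len(N)) {
    blk <- base + (q - 1L) * V
    blk[is.na(base)] <- sentinel
    big[((q - 1L) * Vo + 1L):(q * Vo), ] <- blk
  }
  out <- list(no = ci$no, idxB = big, idxVec = as.vector(big),
              sentinel = sentinel, V = V, Vo = Vo, K = K)
  .nnCache[[key]] <- out
  out
}

convForward <- function(X, layer, n, stride, kernel, N) {
  bi <- batchIndex(n, stride, kernel, N)
  Cin <- ncol(X)
  Xp <- rbind(X, matrix(0, 1L, Cin))
  Xcol <- Xp[bi$idxVec, , drop = FALSE]            # (M*K) x Cin
  M <- N * bi$Vo
  # column-major layout of ((M*K) x Cin) equals (M x (K*Cin)) with columns
  # ordered (k fast, cin slow) -- reinterpret dims, no copy
  dim(Xcol) <- c(M, bi$K * Cin)
  Y <- Xcol %*% layer$W
  if (any(layer$b != 0)) Y <- Y + rep(layer$b, each = M)
  list(Y = Y, cache = list(Xcol = Xcol, n = n, stride = stride,
                           kernel = kernel, N = N, Cin = Cin))
}

convBackward <- function(dY, layer, cache) {
  bi <- batchIndex(cache$n, cache$stride, cache$kernel, cache$N)
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(layer$W)                       # M x (K*Cin)
  NV <- cache$N * bi$V
  # scatter-add: per kernel offset the voxel map is injective, so plain
  # indexed addition is exact; padding collisions all land in the sentinel
  # row, which is dropped
  dXp <- matrix(0, NV + 1L, cache$Cin)
  for (k in seq_len(bi$K)) {
    tgt <- bi$idxB[, k]
    cols <- k + (seq_len(cache$Cin) - 1L) * bi$K
    dXp[tgt, ] <- dXp[tgt, , drop = FALSE] + dXcol[, cols, drop = FALSE]
  }
  list(dX = dXp[-(NV + 1L), , drop = FALSE], grads = list(W = dW, b = db))
}

# ---- GroupNorm over (voxels x channels-in-group) per sample ----------------

toGroups <- function(X, V, N, C, G) {
  a <- array(X, c(V, N, C))
  a <- aperm(a, c(1, 3, 2))                        # (V, C, N)
  dim(a) <- c(V * (C %/% G), G * N)
  a
}

fromGroups <- function(m, V, N, C, G) {
  dim(m) <- c(V, C, N)
  a <- aperm(m, c(1, 3, 2))                        # (V, N, C)
  dim(a) <- c(V * N, C)
  a
}

gnForward <- function(X, layer, V, N, G, eps = 1e-5) {
  C <- ncol(X)
  m <- toGroups(X, V, N, C, G)
  mu <- colMeans(m)
  vv <- colMeans(m^2) - mu^2
  istd <- 1 / sqrt(vv + eps)
  xhat <- sweep(sweep(m, 2, mu), 2, istd, "*")
  Xh <- fromGroups(xhat, V, N, C, G)
  Y <- sweep(sweep(Xh, 2, layer$gamma, "*"), 2, layer$beta, "+")
  list(Y = Y, cache = list(Xh = Xh, istd = istd, V = V, N = N, G = G))
}

gnBackward <- function(dY, layer, cache) {
  C <- ncol(dY); V <- cache$V; N <- cache$N; G <- cache$G
  dgamma <- colSums(dY * cache$Xh)
  dbeta <- colSums(dY)
  dXh <- sweep(dY, 2, layer$gamma, "*")
  dm <- toGroups(dXh, V, N, C, G)
  xh <- toGroups(cache$Xh, V, N, C, G)
  mean_d <- colMeans(dm)
  mean_dx <- colMeans(dm * xh)
  dX <- sweep(sweep(dm, 2, mean_d) - sweep(xh, 2, mean_dx, "*"),
              2, cache$istd, "*")
  dX <- fromGroups(dX, V, N, C, G)
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- Domain-specific batch normalization (per-site batch stats) ------------

dsbnForward <- function(X, layer, V, N, siteIdx, train = TRUE, eps = 1e-5,
                        momentum = 0.9) {
  C <- ncol(X)
  Y <- X
  caches <- vector("list", nrow(layer$gamma))
  rows <- rep(seq_len(N), each = V)
  for (s in sort(unique(siteIdx))) {
    samp <- which(siteIdx == s)
    rr <- which(rows %in% samp)
    Xi <- X[rr, , drop = FALSE]
    useBatch <- train && length(samp) >= 2L
    if (useBatch) {
      mu <- colMeans(Xi)
      vv <- colMeans(Xi^2) - mu^2
      layer$runMean[s, ] <- momentum * layer$runMean[s, ] + (1 - momentum) * mu
      layer$runVar[s, ] <- momentum * layer$runVar[s, ] + (1 - momentum) * vv
    } else {
      mu <- layer$runMean[s, ]
      vv <- layer$runVar[s, ]
    }
    istd <- 1 / sqrt(vv + eps)
    xh <- sweep(sweep(Xi, 2, mu), 2, istd, "*")
    Y[rr, ] <- sweep(sweep(xh, 2, layer$gamma[s, ], "*"), 2,
                     layer$beta[s, ], "+")
    caches[[s]] <- list(rows = rr, xh = xh, istd = istd, batch = useBatch)
  }
  list(Y = Y, cache = caches, layer = layer)
}

dsbnBackward <- function(dY, layer, cache) {
  dX <- dY * 0
  dgamma <- layer$gamma * 0
  dbeta <- layer$beta * 0
  for (s in seq_along(cache)) {
    cc <- cache[[s]]
    if (is.null(cc)) next
    dYi <- dY[cc$rows, , drop = FALSE]
    dgamma[s, ] <- colSums(dYi * cc$xh)
    dbeta[s, ] <- colSums(dYi)
    dXh <- sweep(dYi, 2, layer$gamma[s, ], "*")
    if (cc$batch) {
      dX[cc$rows, ] <- sweep(
        sweep(dXh, 2, colMeans(dXh)) -
          sweep(cc$xh, 2, colMeans(dXh * cc$xh), "*"),
        2, cc$istd, "*")
    } else {
      dX[cc$rows, ] <- sweep(dXh, 2, cc$istd, "*")
    }
  }
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta,
                             runMean = layer$runMean * 0,
                             runVar = layer$runVar * 0))
}

# ---- dense layers ----------------------------------------------------------

linForward <- function(X, layer) {
  Y <- X %*% layer$W
  Y <- sweep(Y, 2, layer$b, "+")
  list(Y = Y, cache = X)
}

linBackward <- function(dY, layer, cache) {
  list(dX = dY %*% t(layer$W),
       grads = list(W = crossprod(cache, dY), b = colSums(dY)))
}

lnForward <- function(X, layer, eps = 1e-5) {
  mu <- rowMeans(X)
  vv <- rowMeans(X^2) - mu^2
  istd <- 1 / sqrt(vv + eps)
  xh <- (X - mu) * istd
  list(Y = sweep(sweep(xh, 2, layer$gamma, "*"), 2, layer$beta, "+"),
       cache = list(xh = xh, istd = istd))
}

lnBackward <- function(dY, layer, cache) {
  dgamma <- colSums(dY * cache$xh)
  dbeta <- colSums(dY)
  dXh <- sweep(dY, 2, layer$gamma, "*")
  dX <- (dXh - rowMeans(dXh) - cache$xh * rowMeans(dXh * cache$xh)) *
    cache$istd
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

l2Forward <- function(U) {
  nrm <- sqrt(rowSums(U^2))
  nrm <- pmax(nrm, 1e-12)
  list(Z = U / nrm, cache = list(Z = U / nrm, nrm = nrm))
}

l2Backward <- function(dZ, cache) {
  (dZ - cache$Z * rowSums(dZ * cache$Z)) / cache$nrm
}

# ---- parameter plumbing ----------------------------------------------------

isParamLeaf <- function(x) is.numeric(x)

mapParams <- function(f, a, b = NULL) {
  if (isParamLeaf(a)) {
    if (is.null(b)) f(a) else f(a, b)
  } else {
    out <- a
    for (nm in names(a))
      out[[nm]] <- mapParams(f, a[[nm]], if (is.null(b)) NULL else b[[nm]])
    out
  }
}

zeroLike <- function(p) mapParams(function(x) x * 0, p)

flattenParams <- function(p, prefix = "") {
  if (isParamLeaf(p)) return(setNames(list(p), prefix))
  out <- list()
  for (nm in names(p))
    out <- c(out, flattenParams(p[[nm]], paste0(prefix, "/", nm)))
  out
}

paramFingerprint <- function(p) {
  v <- unlist(flattenParams(p), use.names = FALSE)
  c(sum(v), sum(v^2), length(v))
}

#' AdamW optimizer state and step
#'
#' Decoupled weight decay Adam: moments per parameter leaf; weight decay is
#' applied to weight matrices (leaves named `W`) only, never to biases or
#' normalization parameters.
#'
#' @param params nested parameter list.
#' @return for `adamwInit`, an optimizer state; for `adamwStep`, the list
#'   `list(params, state)` after one update.
#' @keywords internal
adamwInit <- function(params) {
  list(m = zeroLike(params), v = zeroLike(params), t = 0L)
}

adamwStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weightDecay = 1e-4) {
  state$t <- state$t + 1L
  t <- state$t
  step <- function(p, g, m, v, decay) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p <- p - lr * (mhat / (sqrt(vhat) + eps) + decay * p)
    list(p = p, m = m, v = v)
  }
  walk <- function(p, g, m, v, name = "") {
    if (isParamLeaf(p)) {
      decay <- if (identical(name, "W")) weightDecay else 0
      return(step(p, g, m, v, decay))
    }
    for (nm in names(p)) {
      r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]], nm)
      if (isParamLeaf(p[[nm]])) {
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      } else {
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
    }
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

cosineLR <- function(base, step, total) {
  if (total <= 1) return(base)
  base * 0.5 * (1 + cos(pi * min(step, total) / total))
}
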