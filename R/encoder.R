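#' Describe the 3D residual CNN encoder architecture
#'
#' The desk-scale backbone: a stride-2 stem convolution followed by three
#' residual stages (default widths 16/32/64, stride-2 transitions), GroupNorm
#' or domain-specific batch normalization (DSBN), global average pooling, and
#' a Norm-ReLU-Linear projection head to an l2-normalized embedding of
#' dimension `dim`. Each modality (MRI, PET) gets its own disjoint parameter
#' set; DSBN additionally requires the site id at forward time.
#'
#' @param gridSize input voxels per axis (must be divisible by 8).
#' @param widths channel widths of the three stages.
#' @param dim embedding dimension d.
#' @param norm `"groupnorm"` (default) or `"dsbn"`.
#' @param groups GroupNorm group count (capped at the layer width).
#' @return a list of class `"encoderSpec"`.
#' @export
encoderSpec <- function(gridSize = 16L, widths = c(16L, 32L, 64L),
                        dim = 32L, norm = c("groupnorm", "dsbn"),
                        groups = 8L) {
  norm <- match.arg(norm)
  gridSize <- as.integer(gridSize)
  if (gridSize %% 8L != 0L)
    stop("gridSize must be divisible by 8", call. = FALSE)
  stopifnot(length(widths) == 3L, all(widths >= 1L), dim >= 2L)
  spec <- list(gridSize = gridSize, widths = as.integer(widths),
               dim = as.integer(dim), norm = norm, groups = as.integer(groups))
  class(spec) <- "encoderSpec"
  spec
}

heConv <- function(cin, cout, kernel = 3L) {
  k <- kernel^3
  list(W = matrix(rnorm(k * cin * cout, 0, sqrt(2 / (k * cin))),
                  k * cin, cout),
       b = rep(0, cout))
}

normInit <- function(width, spec, nSites) {
  if (spec$norm == "dsbn") {
    list(gamma = matrix(1, nSites, width), beta = matrix(0, nSites, width),
         runMean = matrix(0, nSites, width), runVar = matrix(1, nSites, width))
  } else {
    list(gamma = rep(1, width), beta = rep(0, width))
  }
}

initEncoderParams <- function(spec, nSites = 1L) {
  w <- spec$widths
  stage <- function(cin, cout) {
    list(conv1 = heConv(cin, cout), n1 = normInit(cout, spec, nSites),
         conv2 = heConv(cout, cout), n2 = normInit(cout, spec, nSites),
         proj = if (cin != cout) heConv(cin, cout, kernel = 1L) else NULL)
  }
  ps <- list(
    stem = heConv(1L, w[1]),
    stemNorm = normInit(w[1], spec, nSites),
    stage1 = stage(w[1], w[1]),
    stage2 = stage(w[1], w[2]),
    stage3 = stage(w[2], w[3]),
    projNorm = list(gamma = rep(1, w[3]), beta = rep(0, w[3])),
    projLin = list(W = matrix(rnorm(w[3] * spec$dim, 0, sqrt(1 / w[3])),
                              w[3], spec$dim),
                   b = rep(0, spec$dim))
  )
  Filter(Negate(is.null), ps)
}

normFwd <- function(X, layer, V, N, spec, siteIdx, train) {
  if (spec$norm == "dsbn") {
    if (is.null(siteIdx))
      stop("DSBN normalization requires site ids at forward time",
           call. = FALSE)
    dsbnForward(X, layer, V, N, siteIdx, train = train)
  } else {
    r <- gnForward(X, layer, V, N, min(spec$groups, ncol(X)))
    r$layer <- layer
    r
  }
}

normBwd <- function(dY, layer, cache, spec) {
  if (spec$norm == "dsbn") dsbnBackward(dY, layer, cache)
  else gnBackward(dY, layer, cache)
}

stageForward <- function(X, sp, n, stride, spec, V, Vo, N, siteIdx, train) {
  c1 <- convForward(X, sp$conv1, n, stride, 3L, N)
  n1 <- normFwd(c1$Y, sp$n1, Vo, N, spec, siteIdx, train)
  r1 <- pmax(n1$Y, 0)
  no <- n %/% stride
  c2 <- convForward(r1, sp$conv2, no, 1L, 3L, N)
  n2 <- normFwd(c2$Y, sp$n2, Vo, N, spec, siteIdx, train)
  short <- if (!is.null(sp$proj)) {
    convForward(X, sp$proj, n, stride, 1L, N)
  } else {
    list(Y = X, cache = NULL)
  }
  pre <- n2$Y + short$Y
  out <- pmax(pre, 0)
  list(Y = out,
       layer = list(n1 = n1$layer, n2 = n2$layer),
       cache = list(c1 = c1$cache, n1 = n1$cache, r1 = r1, c2 = c2$cache,
                    n2 = n2$cache, short = short$cache, pre = pre,
                    hasProj = !is.null(sp$proj), n = n, stride = stride))
}

stageBackward <- function(dY, sp, cache, spec) {
  dPre <- dY * (cache$pre > 0)
  g <- list()
  if (cache$hasProj) {
    bp <- convBackward(dPre, sp$proj, cache$short)
    dXshort <- bp$dX
    g$proj <- bp$grads
  } else {
    dXshort <- dPre
  }
  b2 <- normBwd(dPre, sp$n2, cache$n2, spec)
  g$n2 <- b2$grads
  bc2 <- convBackward(b2$dX, sp$conv2, cache$c2)
  g$conv2 <- bc2$grads
  dR1 <- bc2$dX * (cache$r1 > 0)
  b1 <- normBwd(dR1, sp$n1, cache$n1, spec)
  g$n1 <- b1$grads
  bc1 <- convBackward(b1$dX, sp$conv1, cache$c1)
  g$conv1 <- bc1$grads
  list(dX = bc1$dX + dXshort, grads = g)
}

# Full encoder forward: X is (N*V x 1), V = gridSize^3.
encoderForward <- function(X, params, spec, N, siteIdx = NULL, train = TRUE) {
  n0 <- spec$gridSize
  V0 <- n0^3
  n1 <- n0 %/% 2L
  cs <- convForward(X, params$stem, n0, 2L, 3L, N)
  ns <- normFwd(cs$Y, params$stemNorm, n1^3, N, spec, siteIdx, train)
  rs <- pmax(ns$Y, 0)
  s1 <- stageForward(rs, params$stage1, n1, 1L, spec, n1^3, n1^3, N,
                     siteIdx, train)
  n2g <- n1 %/% 2L
  s2 <- stageForward(s1$Y, params$stage2, n1, 2L, spec, n1^3, n2g^3, N,
                     siteIdx, train)
  n3g <- n2g %/% 2L
  s3 <- stageForward(s2$Y, params$stage3, n2g, 2L, spec, n2g^3, n3g^3, N,
                     siteIdx, train)
  V3 <- n3g^3
  grp <- rep(seq_len(N), each = V3)
  feat <- rowsum(s3$Y, grp) / V3                     # N x width3 (GAP)
  pn <- lnForward(feat, params$projNorm)
  pr <- pmax(pn$Y, 0)
  pl <- linForward(pr, params$projLin)
  l2 <- l2Forward(pl$Y)
  # updated normalization layers (DSBN running stats)
  params$stemNorm <- ns$layer
  params$stage1$n1 <- s1$layer$n1; params$stage1$n2 <- s1$layer$n2
  params$stage2$n1 <- s2$layer$n1; params$stage2$n2 <- s2$layer$n2
  params$stage3$n1 <- s3$layer$n1; params$stage3$n2 <- s3$layer$n2
  list(z = l2$Z, params = params,
       cache = list(cs = cs$cache, ns = ns$cache, rs = rs, s1 = s1$cache,
                    s2 = s2$cache, s3 = s3$cache, V3 = V3, N = N,
                    pn = pn$cache, pr = pr, pl = pl$cache, l2 = l2$cache,
                    feat = feat))
}

encoderBackward <- function(dz, params, spec, cache) {
  dU <- l2Backward(dz, cache$l2)
  bl <- linBackward(dU, params$projLin, cache$pl)
  g <- list(projLin = bl$grads)
  dPr <- bl$dX * (cache$pr > 0)
  bn <- lnBackward(dPr, params$projNorm, cache$pn)
  g$projNorm <- bn$grads
  dFeat <- bn$dX
  V3 <- cache$V3; N <- cache$N
  dS3 <- dFeat[rep(seq_len(N), each = V3), , drop = FALSE] / V3
  b3 <- stageBackward(dS3, params$stage3, cache$s3, spec)
  g$stage3 <- b3$grads
  b2 <- stageBackward(b3$dX, params$stage2, cache$s2, spec)
  g$stage2 <- b2$grads
  b1 <- stageBackward(b2$dX, params$stage1, cache$s1, spec)
  g$stage1 <- b1$grads
  dRs <- b1$dX * (cache$rs > 0)
  bns <- normBwd(dRs, params$stemNorm, cache$ns, spec)
  g$stemNorm <- bns$grads
  bcs <- convBackward(bns$dX, params$stem, cache$cs)
  g$stem <- bcs$grads
  # align grad structure with params (proj may be absent in stage1)
  g[names(params)] <- g[names(params)]
  g
}

volumesToMatrix <- function(volumes) {
  stopifnot(length(volumes) >= 1L)
  V <- length(volumes[[1]]@data)
  X <- matrix(0, length(volumes) * V, 1L)
  for (q in seq_along(volumes)) {
    if (!identical(length(volumes[[q]]@data), V))
      stop("all volumes in a batch must share the grid", call. = FALSE)
    X[((q - 1L) * V + 1L):(q * V), 1L] <- as.vector(volumes[[q]]@data)
  }
  X
}

#' Create an untrained SSL model
#'
#' Initializes two disjoint modality-specific encoder parameter sets, the BYOL
#' predictor, the site discriminator, momentum (key) copies of the encoders,
#' and empty per-modality MoCo queues.
#'
#' @param spec an [encoderSpec()].
#' @param sites character vector of site labels (discriminator classes).
#' @param queueSize MoCo queue capacity per modality.
#' @param seed integer seed for parameter initialization.
#' @return an [SSLModel-class].
#' @export
newSSLModel <- function(spec, sites, queueSize = 256L, seed = 1L) {
  stopifnot(inherits(spec, "encoderSpec"), length(sites) >= 1L)
  set.seed(seed)
  nS <- length(sites)
  d <- spec$dim
  params <- list(
    mri = initEncoderParams(spec, nS),
    pet = initEncoderParams(spec, nS),
    predictor = list(W = diag(d) + matrix(rnorm(d * d, 0, 0.01), d, d),
                     b = rep(0, d)),
    discriminator = list(W = matrix(rnorm(d * nS, 0, 0.1), d, nS),
                         b = rep(0, nS))
  )
  new("SSLModel", spec = unclass(spec), params = params,
      keyParams = list(mri = params$mri, pet = params$pet),
      queues = list(MRI = momentumQueue(queueSize, d),
                    PET = momentumQueue(queueSize, d)),
      sites = as.character(sites), config = list(seed = seed))
}

#' Encode volumes into unit-norm embeddings
#'
#' Routes each volume through its modality's encoder parameters and the
#' projection head; outputs are l2-normalized rows. Volumes whose modality has
#' no parameter set, or an explicit `modality` argument that contradicts a
#' volume's tag, are rejected.
#'
#' @param volumes a [BrainVolume-class] or list thereof (one modality per
#'   call).
#' @param model an [SSLModel-class] (or [FinetunedModel-class]).
#' @param modality optional override; must match the volumes' tag.
#' @param useKey if `TRUE`, use the momentum (key) encoder.
#' @return an [EmbeddingSet-class].
#' @export
encodeVolumes <- function(volumes, model, modality = NULL, useKey = FALSE) {
  if (is(volumes, "BrainVolume")) volumes <- list(volumes)
  mods <- unique(vapply(volumes, function(v) v@modality, ""))
  if (length(mods) != 1L)
    stop("one modality per encode call", call. = FALSE)
  if (!is.null(modality) && !identical(modality, mods))
    stop(sprintf("volumes are %s but were routed to the %s encoder",
                 mods, modality), call. = FALSE)
  pk <- tolower(mods)
  params <- if (useKey && is(model, "SSLModel")) model@keyParams[[pk]]
            else model@params[[pk]]
  if (is.null(params))
    stop(sprintf("model has no parameter set for modality '%s'", mods),
         call. = FALSE)
  spec <- model@spec
  class(spec) <- "encoderSpec"
  X <- volumesToMatrix(volumes)
  siteIdx <- NULL
  if (spec$norm == "dsbn") {
    siteIdx <- match(vapply(volumes, function(v) v@siteId, ""), modelSites(model))
    if (anyNA(siteIdx))
      stop("DSBN requires volumes carrying fitted site ids", call. = FALSE)
  }
  fw <- encoderForward(X, params, spec, length(volumes),
                       siteIdx = siteIdx, train = FALSE)
  info <- data.frame(
    subject_id = vapply(volumes, function(v) v@subjectId, ""),
    visit_time = vapply(volumes, function(v) v@visitTime, 0),
    modality = mods,
    site_id = vapply(volumes, function(v) v@siteId, ""),
    stringsAsFactors = FALSE
  )
  new("EmbeddingSet", z = fw$z, info = info)
}

modelSites <- function(model) {
  if (is(model, "SSLModel")) model@sites else model@config$sites
}
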