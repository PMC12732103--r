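# Stage-1 loss stack. Every loss returns its scalar value together with the
# exact gradients with respect to the embeddings (and any internal
# parameters), so the training loop can combine weighted gradients once and
# the stop-gradient / gradient-reversal contracts can be checked against
# finite differences.

checkUnitNorm <- function(z, what = "embeddings") {
  if (!is.matrix(z)) stop(sprintf("%s must be a matrix", what), call. = FALSE)
  if (nrow(z) && any(abs(sqrt(rowSums(z^2)) - 1) > 1e-5))
    stop(sprintf("%s must be unit-norm within 1e-5", what), call. = FALSE)
  invisible(TRUE)
}

softmaxRows <- function(L) {
  m <- apply(L, 1, max)
  E <- exp(L - m)
  E / rowSums(E)
}

#' Intra-modal InfoNCE loss
#'
#' Mean over anchors of the softmax cross-entropy that distinguishes each
#' anchor's positive from the candidate set: the positives of all anchors in
#' the batch plus the (optional) MoCo queue, at temperature `tau`. With every
#' pairwise similarity equal the loss is exactly `log(C)` for `C` candidates.
#'
#' @param anchors,positives aligned unit-norm embedding matrices (n x d).
#' @param queue optional queue keys (K x d) or a queue object from
#'   [momentumQueue()]; queue entries receive no gradient.
#' @param tau temperature, > 0.
#' @return list with `value`, `gradAnchors`, `gradPositives`.
#' @export
intraModalInfoNCE <- function(anchors, positives, queue = NULL, tau = 0.1) {
  if (tau <= 0) stop("temperature must be positive", call. = FALSE)
  checkUnitNorm(anchors, "anchors"); checkUnitNorm(positives, "positives")
  if (!identical(dim(anchors), dim(positives)))
    stop("anchors and positives must be aligned", call. = FALSE)
  Q <- queueAsMatrix(queue)
  if (!is.null(Q)) checkUnitNorm(Q, "queue keys")
  n <- nrow(anchors)
  cand <- rbind(positives, Q)
  L <- anchors %*% t(cand) / tau
  P <- softmaxRows(L)
  tgt <- seq_len(n)
  value <- -mean(log(pmax(P[cbind(tgt, tgt)], 1e-300)))
  dL <- P
  dL[cbind(tgt, tgt)] <- dL[cbind(tgt, tgt)] - 1
  dL <- dL / n
  gradAnchors <- dL %*% cand / tau
  gradCand <- t(dL) %*% anchors / tau
  list(value = value, gradAnchors = gradAnchors,
       gradPositives = gradCand[seq_len(n), , drop = FALSE])
}

#' Symmetric cross-modal InfoNCE loss
#'
#' Sum of the MRI-to-PET and PET-to-MRI InfoNCE terms over batches paired by
#' (subject, visit); each direction is the mean over anchors with candidates =
#' the paired batch of the other modality plus that modality's queue.
#' Swapping the modality arguments (with matched queues) leaves the value
#' unchanged.
#'
#' @param zMri,zPet aligned unit-norm embedding matrices (n x d).
#' @param queueMri,queuePet optional queues of MRI / PET keys.
#' @param tau temperature, > 0.
#' @return list with `value`, `gradMri`, `gradPet`.
#' @export
crossModalInfoNCE <- function(zMri, zPet, queueMri = NULL, queuePet = NULL,
                              tau = 0.1) {
  if (!identical(dim(zMri), dim(zPet)))
    stop("batches must be paired by (subject, visit)", call. = FALSE)
  a <- intraModalInfoNCE(zMri, zPet, queuePet, tau)   # MRI anchors vs PET
  b <- intraModalInfoNCE(zPet, zMri, queueMri, tau)   # PET anchors vs MRI
  list(value = a$value + b$value,
       gradMri = a$gradAnchors + b$gradPositives,
       gradPet = a$gradPositives + b$gradAnchors)
}

pairIndex <- function(k) {
  if (k < 2L) return(matrix(integer(0), 0, 2))
  t(combn(k, 2))
}

#' @importFrom utils combn
NULL

#' Longitudinal consistency loss
#'
#' Sum over subjects and over unordered visit pairs within each modality of
#' the squared distance between the two visits' embeddings. Subjects with
#' fewer than two visits in a modality contribute 0, so the term degrades
#' gracefully on cross-sectional data.
#'
#' @param z unit-norm embedding matrix (n x d).
#' @param subjectId,visitTime,modality aligned annotation vectors.
#' @return list with `value`, `grad` (n x d), and `nPairs`.
#' @export
longitudinalConsistency <- function(z, subjectId, visitTime, modality) {
  checkUnitNorm(z)
  grad <- z * 0
  value <- 0
  nPairs <- 0L
  for (grp in split(seq_len(nrow(z)),
                    list(subjectId, modality), drop = TRUE)) {
    tt <- visitTime[grp]
    ix <- grp[!duplicated(tt)]        # one embedding per distinct visit time
    if (length(ix) < 2L) next
    pr <- pairIndex(length(ix))
    for (r in seq_len(nrow(pr))) {
      i <- ix[pr[r, 1]]; j <- ix[pr[r, 2]]
      d <- z[i, ] - z[j, ]
      value <- value + sum(d^2)
      grad[i, ] <- grad[i, ] + 2 * d
      grad[j, ] <- grad[j, ] - 2 * d
      nPairs <- nPairs + 1L
    }
  }
  list(value = value, grad = grad, nPairs = nPairs)
}

#' Cross-time cross-modal coupling loss
#'
#' Sum over subjects of squared distances between an MRI embedding at one
#' visit and a PET embedding at a different visit (each MRI-visit/PET-visit
#' combination with distinct times counted once). Subjects lacking
#' cross-modal longitudinal pairs contribute 0.
#'
#' @inheritParams longitudinalConsistency
#' @return list with `value`, `grad`, `nPairs`.
#' @export
crossTimeCrossModal <- function(z, subjectId, visitTime, modality) {
  checkUnitNorm(z)
  grad <- z * 0
  value <- 0
  nPairs <- 0L
  for (grp in split(seq_len(nrow(z)), subjectId)) {
    im <- grp[modality[grp] == "MRI"]
    ip <- grp[modality[grp] == "PET"]
    if (!length(im) || !length(ip)) next
    for (i in im) for (j in ip) {
      if (visitTime[i] == visitTime[j]) next
      d <- z[i, ] - z[j, ]
      value <- value + sum(d^2)
      grad[i, ] <- grad[i, ] + 2 * d
      grad[j, ] <- grad[j, ] - 2 * d
      nPairs <- nPairs + 1L
    }
  }
  list(value = value, grad = grad, nPairs = nPairs)
}

#' BYOL-style regression loss with stop-gradient target
#'
#' Mean over the batch of the squared distance between the predicted online
#' embedding `q(z)` and the stop-gradient target `sg(z+)`. The target branch
#' receives exactly zero gradient (`gradTarget` is all zeros by construction);
#' the predictor is a linear map whose gradients are returned for the
#' optimizer.
#'
#' @param zOnline,zTarget aligned embedding matrices (n x d).
#' @param predictor list with `W` (d x d) and `b` (length d).
#' @return list with `value`, `gradOnline`, `gradTarget` (zeros),
#'   `gradPredictor`.
#' @export
byolLoss <- function(zOnline, zTarget, predictor) {
  if (!identical(dim(zOnline), dim(zTarget)))
    stop("online and target batches must be aligned", call. = FALSE)
  n <- nrow(zOnline)
  P <- sweep(zOnline %*% predictor$W, 2, predictor$b, "+")
  R <- P - zTarget
  value <- sum(R^2) / n
  dP <- 2 * R / n
  list(value = value,
       gradOnline = dP %*% t(predictor$W),
       gradTarget = zTarget * 0,
       gradPredictor = list(W = crossprod(zOnline, dP), b = colSums(dP)))
}

#' Site-adversarial loss with gradient reversal
#'
#' Cross-entropy of a linear site discriminator on the embeddings. The
#' discriminator parameters receive the ordinary CE gradient; the encoder
#' (embedding) gradient is the CE gradient negated and scaled by
#' `grlStrength` — the gradient-reversal layer that drives site information
#' out of the representation while the discriminator still learns to find it.
#'
#' @param z embedding matrix (n x d).
#' @param siteIdx integer site index per row, in `1..S`.
#' @param discriminator list with `W` (d x S) and `b` (length S).
#' @param grlStrength gradient-reversal scale, >= 0.
#' @return list with `value`, `gradDiscriminator`, `gradEncoder`
#'   (= -grlStrength x dCE/dz), `gradZ` (the unreversed dCE/dz), and the
#'   per-row predicted site probabilities.
#' @export
siteAdversarialLoss <- function(z, siteIdx, discriminator, grlStrength = 1) {
  S <- ncol(discriminator$W)
  siteIdx <- as.integer(siteIdx)
  if (any(siteIdx < 1L | siteIdx > S))
    stop(sprintf("site index outside the fitted site set (1..%d)", S),
         call. = FALSE)
  n <- nrow(z)
  L <- sweep(z %*% discriminator$W, 2, discriminator$b, "+")
  P <- softmaxRows(L)
  value <- -mean(log(pmax(P[cbind(seq_len(n), siteIdx)], 1e-300)))
  dL <- P
  dL[cbind(seq_len(n), siteIdx)] <- dL[cbind(seq_len(n), siteIdx)] - 1
  dL <- dL / n
  dz <- dL %*% t(discriminator$W)
  list(value = value,
       gradDiscriminator = list(W = crossprod(z, dL), b = colSums(dL)),
       gradEncoder = -grlStrength * dz,
       gradZ = dz,
       probs = P)
}

#' SSL loss weights
#'
#' The weighted-sum coefficients of the overall pretraining objective:
#' intra-modal InfoNCE, cross-modal InfoNCE, BYOL, longitudinal, cross-time
#' cross-modal, and the site-adversarial term, plus the shared temperature
#' and the gradient-reversal strength.
#'
#' @param intra,cross,byol,long,longx,site nonnegative weights.
#' @param tau temperature (default 0.1).
#' @param grlStrength gradient-reversal scale (default 1).
#' @return list of class `"sslWeights"`.
#' @export
sslWeights <- function(intra = 1, cross = 1, byol = 1, long = 0.1,
                       longx = 0.1, site = 1, tau = 0.1, grlStrength = 1) {
  w <- list(intra = intra, cross = cross, byol = byol, long = long,
            longx = longx, site = site, tau = tau,
            grlStrength = grlStrength)
  lam <- unlist(w[c("intra", "cross", "byol", "long", "longx", "site")])
  if (any(lam < 0)) stop("loss weights must be nonnegative", call. = FALSE)
  if (tau <= 0) stop("temperature must be positive", call. = FALSE)
  class(w) <- "sslWeights"
  w
}

#' Weighted total SSL loss
#'
#' @param components named numeric vector/list with any of `intra, cross,
#'   byol, long, longx, site` (missing components count as 0).
#' @param weights an [sslWeights()] object.
#' @return list of class `"sslLossReport"` with per-component values, the
#'   weights, and the weighted `total`.
#' @export
totalSslLoss <- function(components, weights) {
  stopifnot(inherits(weights, "sslWeights"))
  nm <- c("intra", "cross", "byol", "long", "longx", "site")
  comp <- setNames(numeric(6), nm)
  components <- unlist(components)
  comp[intersect(names(components), nm)] <-
    components[intersect(names(components), nm)]
  lam <- unlist(weights[nm])
  rep <- list(components = comp, weights = lam,
              total = sum(lam * comp))
  class(rep) <- "sslLossReport"
  rep
}

#' @export
print.sslLossReport <- function(x, ...) {
  cat("SSL loss report\n")
  for (nm in names(x$components))
    cat(sprintf("  %-6s %10.5f  (weight %.3g)\n", nm, x$components[nm],
                x$weights[nm]))
  cat(sprintf("  total  %10.5f\n", x$total))
  invisible(x)
}

# ---- MoCo queue and momentum update ----------------------------------------

#' Create a FIFO momentum queue of negative keys
#'
#' @param capacity maximum number of stored keys K.
#' @param dim embedding dimension.
#' @return a list of class `"momentumQueue"`.
#' @export
momentumQueue <- function(capacity, dim) {
  q <- list(buf = matrix(0, capacity, dim), capacity = as.integer(capacity),
            size = 0L, ptr = 0L)
  class(q) <- "momentumQueue"
  q
}

#' Push keys into a momentum queue (FIFO eviction)
#'
#' @param queue a [momentumQueue()].
#' @param keys unit-norm key matrix (rows are keys).
#' @return the updated queue.
#' @export
queuePush <- function(queue, keys) {
  stopifnot(inherits(queue, "momentumQueue"))
  checkUnitNorm(keys, "keys")
  for (r in seq_len(nrow(keys))) {
    queue$ptr <- (queue$ptr %% queue$capacity) + 1L
    queue$buf[queue$ptr, ] <- keys[r, ]
    queue$size <- min(queue$size + 1L, queue$capacity)
  }
  queue
}

#' Current keys held by a queue (oldest first)
#'
#' @param queue a [momentumQueue()].
#' @return matrix of stored keys (0 rows when empty).
#' @export
queueKeys <- function(queue) {
  stopifnot(inherits(queue, "momentumQueue"))
  if (queue$size == 0L) return(queue$buf[0, , drop = FALSE])
  if (queue$size < queue$capacity)
    return(queue$buf[seq_len(queue$size), , drop = FALSE])
  ord <- c(seq_len(queue$capacity)[-seq_len(queue$ptr)], seq_len(queue$ptr))
  queue$buf[ord, , drop = FALSE]
}

queueAsMatrix <- function(queue) {
  if (is.null(queue)) return(NULL)
  if (inherits(queue, "momentumQueue")) {
    k <- queueKeys(queue)
    if (!nrow(k)) return(NULL)
    return(k)
  }
  if (!nrow(queue)) return(NULL)
  queue
}

#' Momentum (EMA) update of the key encoder
#'
#' `key <- m * key + (1 - m) * online`, applied leaf-wise over the nested
#' parameter lists. `m = 1` leaves the key encoder unchanged; `m = 0` copies
#' the online encoder.
#'
#' @param keyParams,onlineParams nested parameter lists of identical shape.
#' @param m momentum coefficient in `[0, 1]`.
#' @return the updated key parameters.
#' @export
momentumUpdate <- function(keyParams, onlineParams, m) {
  if (m < 0 || m > 1) stop("momentum must lie in [0, 1]", call. = FALSE)
  mapParams(function(k, o) m * k + (1 - m) * o, keyParams, onlineParams)
}
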