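# Stage-2 heads: missing-aware gated fusion, class-weighted diagnosis CE,
# Cox partial likelihood (Breslow ties), PET->MRI distillation, temperature
# calibration, and the joint objective. Losses return exact gradients for the
# fine-tuning loop.

#' Missing-aware gated late fusion
#'
#' The availability-conditioned gate `alpha = sigmoid(w^T [1_MRI, 1_PET] + b)`
#' blends the two modality embeddings into
#' `e = [alpha * z_MRI || (1 - alpha) * z_PET || c]`. An absent modality's
#' embedding is replaced by the zero vector before scaling, so the missing
#' block of `e` is exactly zero and the representation keeps its fixed length
#' `2d + q`. The gate sees only the availability indicators, never the
#' embeddings.
#'
#' @param zMri,zPet unit-norm embedding matrices (n x d) or `NULL`/rows of
#'   zeros for missing visits.
#' @param indicators n x 2 binary matrix of (MRI, PET) availability; at least
#'   one modality present per row.
#' @param covariates n x q matrix of clinical covariates (may be 0-column).
#' @param gate list with `w` (length 2) and `b` (scalar).
#' @return list with `e` (n x (2d+q)), `alpha` (length n), and the pieces
#'   needed for backprop (`d`, `q`).
#' @export
gatedFusion <- function(zMri, zPet, indicators, covariates = NULL,
                        gate = list(w = c(0, 0), b = 0)) {
  indicators <- as.matrix(indicators)
  n <- nrow(indicators)
  if (any(rowSums(indicators) == 0))
    stop("at least one modality must be present for every visit",
         call. = FALSE)
  d <- if (!is.null(zMri)) ncol(zMri) else ncol(zPet)
  if (is.null(zMri)) zMri <- matrix(0, n, d)
  if (is.null(zPet)) zPet <- matrix(0, n, d)
  zMri <- zMri * indicators[, 1]
  zPet <- zPet * indicators[, 2]
  covariates <- if (is.null(covariates)) matrix(0, n, 0) else
    as.matrix(covariates)
  alpha <- plogis(indicators %*% gate$w + gate$b)[, 1]
  e <- cbind(zMri * alpha, zPet * (1 - alpha), covariates)
  list(e = e, alpha = alpha, d = d, q = ncol(covariates),
       zMri = zMri, zPet = zPet, indicators = indicators)
}

# gradient of a loss through the fusion: dE -> dzMri, dzPet, dGate
gatedFusionBackward <- function(dE, fusion) {
  d <- fusion$d
  a <- fusion$alpha
  dBlockM <- dE[, seq_len(d), drop = FALSE]
  dBlockP <- dE[, d + seq_len(d), drop = FALSE]
  dzMri <- dBlockM * a * fusion$indicators[, 1]
  dzPet <- dBlockP * (1 - a) * fusion$indicators[, 2]
  dAlpha <- rowSums(dBlockM * fusion$zMri) - rowSums(dBlockP * fusion$zPet)
  dPre <- dAlpha * a * (1 - a)
  list(dzMri = dzMri, dzPet = dzPet,
       gradGate = list(w = as.numeric(crossprod(fusion$indicators, dPre)),
                       b = sum(dPre)))
}

#' Class-weighted cross-entropy diagnosis loss
#'
#' `-(1/N) sum_n sum_k w_k 1[y_n = k] log softmax(l_n)_k`. Class weights
#' default to 1; the protocol layer supplies inverse-frequency weights
#' normalized to mean 1.
#'
#' @param logits n x K matrix.
#' @param labels integer labels in `0..K-1` (or a factor with K levels).
#' @param classWeights positive weights, length K.
#' @return list with `value` and `gradLogits`.
#' @export
diagnosisLoss <- function(logits, labels, classWeights = NULL) {
  K <- ncol(logits)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= K))
    stop(sprintf("labels must lie in 0..%d", K - 1L), call. = FALSE)
  classWeights <- classWeights %||% rep(1, K)
  if (any(classWeights <= 0))
    stop("class weights must be positive", call. = FALSE)
  n <- nrow(logits)
  P <- softmaxRows(logits)
  w <- classWeights[labels + 1L]
  value <- -sum(w * log(pmax(P[cbind(seq_len(n), labels + 1L)], 1e-300))) / n
  G <- P * w
  G[cbind(seq_len(n), labels + 1L)] <-
    G[cbind(seq_len(n), labels + 1L)] - w
  list(value = value, gradLogits = G / n)
}

#' Cox partial log-likelihood loss (Breslow ties)
#'
#' Negative partial log-likelihood
#' `-sum_{n: delta_n = 1} [r_n - log sum_{j: T_j >= T_n} exp(r_j)]` with risk
#' sets defined by `T_j >= T_n`; tied event times share the same risk set
#' (the Breslow approximation). Censored subjects enter only through risk
#' sets. With no events the loss is defined as 0 with a warning.
#'
#' @param risks numeric risk scores r.
#' @param times positive follow-up times T (months).
#' @param events 0/1 event indicators delta.
#' @return list with `value` and `grad` (d loss / d risk).
#' @export
coxPartialLoglik <- function(risks, times, events) {
  n <- length(risks)
  stopifnot(length(times) == n, length(events) == n)
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  events <- as.integer(events)
  if (!any(events == 1L)) {
    warning("no events: Cox partial log-likelihood is 0")
    return(list(value = 0, grad = rep(0, n)))
  }
  er <- exp(risks)
  value <- 0
  grad <- rep(0, n)
  evIdx <- which(events == 1L)
  for (i in evIdx) {
    rs <- times >= times[i]
    s <- sum(er[rs])
    value <- value - (risks[i] - log(s))
    grad[i] <- grad[i] - 1
    grad[rs] <- grad[rs] + er[rs] / s
  }
  list(value = value, grad = grad)
}

#' PET-to-MRI distillation loss
#'
#' `(1/N) sum_n 1_PET,n * || z_n^MRI - sg(z_n^PET) ||^2`: at visits where PET
#' exists, the MRI embedding is pulled toward the (stop-gradient) PET
#' embedding, so molecular information survives MRI-only deployment. The PET
#' branch receives exactly zero gradient; visits without PET contribute 0;
#' N counts the whole batch.
#'
#' @param zMri,zPet aligned embedding matrices (n x d).
#' @param petIndicator 0/1 per row.
#' @return list with `value`, `gradMri`, `gradPet` (zeros).
#' @export
distillationLoss <- function(zMri, zPet, petIndicator) {
  stopifnot(identical(dim(zMri), dim(zPet)))
  n <- nrow(zMri)
  ind <- as.numeric(petIndicator)
  R <- (zMri - zPet) * ind
  value <- sum(R^2) / n
  list(value = value, gradMri = 2 * R / n, gradPet = zPet * 0)
}

#' Fit the softmax temperature on a validation set
#'
#' One-dimensional minimization of the validation NLL of `softmax(l / T)`
#' over `log T` in `[log 0.05, log 20]`, to tolerance 1e-4 in T. Touches
#' only the logits: encoder weights are untouched by construction.
#'
#' @param logits validation logits (n x K).
#' @param labels validation labels in `0..K-1` or a factor.
#' @return the fitted temperature (scalar, > 0).
#' @export
fitTemperature <- function(logits, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("degenerate validation set: a single class cannot calibrate",
         call. = FALSE)
  nll <- function(logT) {
    P <- applyTemperature(logits, exp(logT))
    -mean(log(pmax(P[cbind(seq_along(labels), labels + 1L)], 1e-300)))
  }
  opt <- optimize(nll, lower = log(0.05), upper = log(20), tol = 1e-5)
  exp(opt$minimum)
}

#' Calibrated probabilities from logits and a temperature
#'
#' @param logits n x K matrix.
#' @param temperature positive scalar; `T = 1` is the ordinary softmax.
#' @return n x K probability matrix.
#' @export
applyTemperature <- function(logits, temperature) {
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  softmaxRows(logits / temperature)
}

#' Joint fine-tuning objective
#'
#' `L = alpha * L_diag + beta * L_cox + gamma * L_distill` with nonnegative
#' coefficients (defaults 1, 1, 0.5).
#'
#' @param lDiag,lCox,lDistill component losses.
#' @param coefficients numeric length-3 `(alpha, beta, gamma)`.
#' @return the scalar weighted sum.
#' @export
jointFinetuneLoss <- function(lDiag, lCox, lDistill,
                              coefficients = c(1, 1, 0.5)) {
  if (any(coefficients < 0))
    stop("coefficients must be nonnegative", call. = FALSE)
  sum(coefficients * c(lDiag, lCox, lDistill))
}

#' Inverse-frequency class weights normalized to mean 1
#'
#' @param labels factor or integer labels.
#' @return positive weights, one per class level, mean 1.
#' @export
inverseFrequencyWeights <- function(labels) {
  tab <- table(labels)
  w <- as.numeric(sum(tab) / (length(tab) * tab))
  w / mean(w)
}
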