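# Evaluation battery: classification, survival (IPCW), calibration,
# test-retest reliability, and resampling/comparison inference. Every
# estimator here has a brute-force oracle in the test suite (pair
# enumeration, hand binning, explicit IPCW sums, ANOVA mean squares,
# placement values) that it must match to 1e-10 on small instances.

checkTwoClasses <- function(labels) {
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
}

#' Balanced accuracy (macro-averaged recall)
#'
#' Binary case: `(TPR + TNR) / 2`; multi-class: the mean of per-class
#' recalls.
#'
#' @param labels true labels.
#' @param predicted predicted class labels.
#' @return scalar in `[0, 1]`.
#' @export
balancedAccuracy <- function(labels, predicted) {
  checkTwoClasses(labels)
  labels <- as.character(labels); predicted <- as.character(predicted)
  mean(vapply(unique(labels), function(k)
    mean(predicted[labels == k] == k), 0))
}

#' F1 score
#'
#' Binary: harmonic mean of precision and recall for `positive`; multi-class:
#' macro average over classes.
#'
#' @param labels true labels.
#' @param predicted predicted labels.
#' @param positive positive class (binary case); default: the larger level.
#' @return scalar in `[0, 1]`.
#' @export
f1Score <- function(labels, predicted, positive = NULL) {
  labels <- as.character(labels); predicted <- as.character(predicted)
  f1One <- function(k) {
    tp <- sum(labels == k & predicted == k)
    fp <- sum(labels != k & predicted == k)
    fn <- sum(labels == k & predicted != k)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  lev <- sort(unique(labels))
  if (length(lev) == 2L) f1One(positive %||% lev[2])
  else mean(vapply(lev, f1One, 0))
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' The probability that a random positive scores above a random negative,
#' ties counted 1/2 — computed by the rank formula, equivalent to exhaustive
#' pair enumeration.
#'
#' @param labels binary labels (0/1, logical, or 2-level factor; the larger
#'   level is positive).
#' @param scores numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
aucScore <- function(labels, scores) {
  y <- toBinary(labels)
  checkTwoClasses(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

toBinary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) return(as.integer(labels == levels(labels)[2]))
  u <- sort(unique(labels))
  if (length(u) > 2L) stop("binary labels required", call. = FALSE)
  as.integer(labels == max(u))
}

#' Sensitivity at a fixed specificity
#'
#' The largest attainable true-positive rate among score thresholds whose
#' specificity is at least `specificity`.
#'
#' @param labels binary labels.
#' @param scores numeric scores (higher = more positive).
#' @param specificity target specificity (default 0.80).
#' @return sensitivity in `[0, 1]`.
#' @export
sensitivityAtSpecificity <- function(labels, scores, specificity = 0.80) {
  y <- toBinary(labels)
  checkTwoClasses(y)
  thr <- sort(unique(scores))
  best <- 0
  for (t in thr) {
    pred <- scores >= t
    spec <- mean(!pred[y == 0])
    if (spec >= specificity) best <- max(best, mean(pred[y == 1]))
  }
  best
}

#' Harrell's concordance index
#'
#' Over comparable pairs `P = {(i, j): delta_i = 1, T_i < T_j}`, the fraction
#' with `r_i > r_j`; risk ties count 1/2; tied event times are excluded by
#' the strict inequality (Harrell convention).
#'
#' @param risks predicted risk scores.
#' @param times follow-up times.
#' @param events 0/1 event indicators.
#' @return C-index in `[0, 1]`.
#' @export
cIndex <- function(risks, times, events) {
  n <- length(risks)
  events <- as.integer(events)
  conc <- 0; total <- 0
  for (i in which(events == 1L)) {
    comp <- times > times[i]
    total <- total + sum(comp)
    conc <- conc + sum(risks[i] > risks[comp]) +
      0.5 * sum(risks[i] == risks[comp])
  }
  if (total == 0) stop("no comparable pairs", call. = FALSE)
  conc / total
}

# Kaplan-Meier estimator of the censoring survival G(t), via survival::survfit
# on the flipped indicator; returns left-continuous and right-continuous
# evaluators.
censoringKM <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  tt <- c(0, fit$time)
  ss <- c(1, fit$surv)
  right <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  list(
    at = function(t) pmax(right(t), 1e-12),                  # G(t)
    atMinus = function(t) {                                  # G(t-)
      vapply(t, function(ti) {
        s <- ss[tt < ti]
        if (!length(s)) 1 else max(tail(s, 1), 1e-12)
      }, 0)
    }
  )
}

#' IPCW Brier score curve
#'
#' `Brier(t)` = inverse-probability-of-censoring-weighted mean squared error
#' between the predicted survival probability `S(t|x)` and the observed
#' status: subjects with an event by `t` contribute `(0 - S)^2 / G(T_i-)`,
#' subjects still at risk contribute `(1 - S)^2 / G(t)`, with `G` the
#' Kaplan-Meier estimator of the censoring distribution. With no censoring
#' all weights are 1 and `Brier(t)` is the plain mean squared error.
#'
#' @param survProb n x G matrix of predicted survival probabilities on the
#'   grid (non-increasing per row).
#' @param times,events observed follow-up and event indicators.
#' @param grid strictly increasing evaluation times within follow-up.
#' @return data.frame with `time` and `brier`.
#' @export
brierCurve <- function(survProb, times, events, grid) {
  survProb <- as.matrix(survProb)
  n <- length(times)
  stopifnot(nrow(survProb) == n, ncol(survProb) == length(grid))
  if (any(diff(grid) <= 0))
    stop("grid must be strictly increasing", call. = FALSE)
  if (max(grid) > max(times))
    stop("grid exceeds the observed follow-up", call. = FALSE)
  events <- as.integer(events)
  G <- censoringKM(times, events)
  brier <- vapply(seq_along(grid), function(g) {
    t <- grid[g]
    S <- survProb[, g]
    ev <- times <= t & events == 1L
    atRisk <- times > t
    w <- numeric(n)
    w[ev] <- 1 / G$atMinus(times[ev])
    w[atRisk] <- 1 / G$at(t)
    sum(w * ifelse(ev, (0 - S)^2, ifelse(atRisk, (1 - S)^2, 0))) / n
  }, 0)
  data.frame(time = grid, brier = brier)
}

#' Integrated Brier score
#'
#' `(1 / tau_max) * integral_0^tau_max Brier(t) dt` by the trapezoid rule on
#' the curve's grid (prepending `Brier(0)` = the curve's first value at time
#' 0 if absent).
#'
#' @param curve data.frame from [brierCurve()].
#' @param tauMax integration horizon (default: the last grid time).
#' @return scalar IBS.
#' @export
integratedBrierScore <- function(curve, tauMax = max(curve$time)) {
  cc <- curve[curve$time <= tauMax + 1e-12, ]
  tt <- cc$time; bb <- cc$brier
  if (tt[1] > 0) { tt <- c(0, tt); bb <- c(bb[1], bb) }
  sum(diff(tt) * (head(bb, -1) + tail(bb, -1)) / 2) / tauMax
}

#' Time-dependent (cumulative/dynamic) AUC with IPCW
#'
#' At horizon `t`, cases are subjects with an observed event by `t` and
#' controls are subjects still event-free at `t`; pairs are weighted by the
#' inverse censoring probabilities (case weight `1/G(T_i-)`, control weight
#' `1/G(t)`), ties in risk counted 1/2. Without censoring this reduces to the
#' plain AUC of risks for cases versus controls.
#'
#' @param risks risk scores.
#' @param times,events follow-up and event indicators.
#' @param t evaluation horizon.
#' @return AUC(t) in `[0, 1]`.
#' @export
tdAuc <- function(risks, times, events, t) {
  events <- as.integer(events)
  cases <- which(times <= t & events == 1L)
  controls <- which(times > t)
  if (!length(cases) || !length(controls))
    stop("need at least one case and one control at the horizon",
         call. = FALSE)
  G <- censoringKM(times, events)
  wc <- 1 / G$atMinus(times[cases])
  wk <- rep(1 / G$at(t), length(controls))
  num <- 0; den <- 0
  for (a in seq_along(cases)) {
    ri <- risks[cases[a]]
    cmp <- (ri > risks[controls]) + 0.5 * (ri == risks[controls])
    num <- num + wc[a] * sum(wk * cmp)
    den <- den + wc[a] * sum(wk)
  }
  num / den
}

#' Expected calibration error with equal-mass bins
#'
#' Sorts by confidence into `M` (near-)equal-count bins — when `N` is not
#' divisible by `M` the remainder is distributed one-per-bin to the
#' lowest-confidence bins — and returns
#' `sum_m (|B_m|/N) |acc(B_m) - conf(B_m)|`.
#'
#' @param confidences predicted confidences in `[0, 1]`.
#' @param correctness 0/1 correctness of the prediction.
#' @param bins number of equal-mass bins M (default 10).
#' @return ECE in `[0, 1]`.
#' @export
ece <- function(confidences, correctness, bins = 10L) {
  n <- length(confidences)
  if (bins < 1L || bins > n)
    stop("bins must lie in 1..N", call. = FALSE)
  if (any(confidences < 0 | confidences > 1))
    stop("confidences must lie in [0, 1]", call. = FALSE)
  ord <- order(confidences)
  sizes <- rep(n %/% bins, bins)
  extra <- n %% bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1) + 1L)
  correctness <- as.numeric(correctness)
  sum(vapply(seq_len(bins), function(m) {
    ix <- ord[starts[m]:stops[m]]
    length(ix) / n * abs(mean(correctness[ix]) - mean(confidences[ix]))
  }, 0))
}

#' ICC(3,1): two-way mixed-effects, single-measurement reliability
#'
#' From the two-way ANOVA mean squares, `(BMS - EMS) / (BMS + (k-1) EMS)`
#' with BMS the between-subject and EMS the residual mean square.
#'
#' @param mat n subjects x k repeated measurements, no missing cells.
#' @return ICC(3,1) in `(-1, 1]`.
#' @export
icc31 <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  stopifnot(n >= 2L, k >= 2L)
  if (anyNA(mat)) stop("no missing cells allowed", call. = FALSE)
  grand <- mean(mat)
  rowM <- rowMeans(mat); colM <- colMeans(mat)
  bms <- k * sum((rowM - grand)^2) / (n - 1)
  jms <- n * sum((colM - grand)^2) / (k - 1)
  sse <- sum((mat - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + grand)^2)
  ems <- sse / ((n - 1) * (k - 1))
  if (bms + (k - 1) * ems <= 0)
    stop("zero variance: ICC undefined", call. = FALSE)
  (bms - ems) / (bms + (k - 1) * ems)
}

#' Within-subject coefficient of variation
#'
#' Root mean of per-subject variances, divided by the overall mean.
#'
#' @param mat n x k repeated-measurement matrix with positive overall mean.
#' @return wCV (unitless; 0 for perfect repeatability).
#' @export
withinSubjectCV <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) >= 2L)
  m <- mean(mat)
  if (m <= 0) stop("overall mean must be positive for wCV", call. = FALSE)
  sqrt(mean(apply(mat, 1, var))) / m
}

#' Standardized response mean
#'
#' Mean change divided by the standard deviation of change; errors when the
#' change scores have zero spread.
#'
#' @param change vector of change scores.
#' @return SRM.
#' @export
srm <- function(change) {
  s <- sd(change)
  if (!is.finite(s) || s == 0)
    stop("zero variance of change scores: SRM undefined", call. = FALSE)
  mean(change) / s
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows (subjects) of `data` with replacement `B` times, applies
#' `metric`, and returns the percentile interval. Resamples on which the
#' metric is undefined (error) are redrawn, up to `maxRetries` total retries.
#'
#' @param metric function of a data.frame returning a scalar.
#' @param data data.frame of subject-level rows.
#' @param B bootstrap samples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @param maxRetries cap on total redraws.
#' @return named numeric `c(low, high)` with attribute `"retries"`.
#' @export
bootstrapCi <- function(metric, data, B = 1000L, level = 0.95, seed = 1L,
                        maxRetries = 10L * B) {
  set.seed(seed)
  n <- nrow(data)
  vals <- numeric(B)
  retries <- 0L
  b <- 1L
  while (b <= B) {
    ix <- sample.int(n, n, replace = TRUE)
    v <- tryCatch(metric(data[ix, , drop = FALSE]), error = function(e) NULL)
    if (is.null(v) || !is.finite(v)) {
      retries <- retries + 1L
      if (retries > maxRetries)
        stop("metric undefined on too many bootstrap resamples",
             call. = FALSE)
      next
    }
    vals[b] <- v
    b <- b + 1L
  }
  a <- (1 - level) / 2
  out <- quantile(vals, c(a, 1 - a), names = FALSE, type = 7)
  out <- setNames(out, c("low", "high"))
  attr(out, "retries") <- retries
  out
}

#' DeLong's test for paired AUC comparison
#'
#' Computes the placement-value (structural component) covariance of the two
#' correlated AUCs and a two-sided p-value for `AUC_A - AUC_B` from the
#' normal reference.
#'
#' @param labels binary labels.
#' @param scoresA,scoresB paired score vectors.
#' @return list with `aucA`, `aucB`, `delta`, `varDelta`, `z`, `p`.
#' @export
delongTest <- function(labels, scoresA, scoresB) {
  y <- toBinary(labels)
  checkTwoClasses(y)
  pos <- which(y == 1); neg <- which(y == 0)
  m <- length(pos); n <- length(neg)
  placements <- function(s) {
    V10 <- vapply(pos, function(i)
      mean((s[i] > s[neg]) + 0.5 * (s[i] == s[neg])), 0)
    V01 <- vapply(neg, function(j)
      mean((s[pos] > s[j]) + 0.5 * (s[pos] == s[j])), 0)
    list(V10 = V10, V01 = V01, auc = mean(V10))
  }
  A <- placements(scoresA); B <- placements(scoresB)
  S10 <- cov(cbind(A$V10, B$V10))
  S01 <- cov(cbind(A$V01, B$V01))
  S <- S10 / m + S01 / n
  delta <- A$auc - B$auc
  varDelta <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (varDelta <= 0) {
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(varDelta)
    p <- 2 * pnorm(-abs(z))
  }
  list(aucA = A$auc, aucB = B$auc, delta = delta, varDelta = varDelta,
       z = z, p = p)
}
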