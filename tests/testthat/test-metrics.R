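# Every estimator is pinned to a brute-force oracle on small instances at
# 1e-10, plus an independent library cross-check where one exists.

test_that("balanced accuracy and F1 follow their confusion-table definitions", {
  y <- c(rep(1, 10), rep(0, 10))
  expect_equal(balancedAccuracy(y, y), 1.0)
  # TP=8 FN=2 TN=6 FP=4 -> (0.8 + 0.6) / 2
  pred <- c(rep(1, 8), rep(0, 2), rep(1, 4), rep(0, 6))
  expect_equal(balancedAccuracy(y, pred), 0.7, tolerance = 1e-12)
  expect_equal(f1Score(y, pred, positive = "1"),
               2 * 8 / (2 * 8 + 4 + 2), tolerance = 1e-12)
  # macro BAC on three classes = mean per-class recall
  y3 <- c("a", "a", "b", "b", "c", "c")
  p3 <- c("a", "b", "b", "b", "c", "a")
  expect_equal(balancedAccuracy(y3, p3), mean(c(0.5, 1, 0.5)),
               tolerance = 1e-12)
  expect_error(balancedAccuracy(rep(1, 5), rep(1, 5)), "classes")
})

test_that("AUC equals exhaustive pair counting with ties at one half", {
  y <- c(1, 1, 1, 0, 0, 0)
  s <- c(0.9, 0.5, 0.5, 0.5, 0.2, 0.1)   # one cross-class tie
  expect_equal(aucScore(y, s), oracleAuc(y, s), tolerance = 1e-10)
  expect_equal(aucScore(y, seq_along(y) * (y * 2 - 1)), 1.0)
  # invariant under strictly monotone transforms
  set.seed(1)
  y2 <- rbinom(40, 1, 0.5); s2 <- rnorm(40)
  expect_equal(aucScore(y2, s2), aucScore(y2, exp(s2)), tolerance = 1e-12)
  # pROC agreement
  suppressMessages(requireNamespace("pROC"))
  expect_equal(aucScore(y2, s2),
               as.numeric(pROC::auc(pROC::roc(y2, s2, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("sensitivity at fixed specificity maximizes TPR under the bound", {
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  s <- c(0.9, 0.8, 0.6, 0.3, 0.7, 0.5, 0.4, 0.2, 0.1, 0.05)
  # threshold 0.6: spec = 5/6 >= 0.8, sens = 3/4; no lower threshold keeps
  # specificity at 0.8
  expect_equal(sensitivityAtSpecificity(y, s, 0.8), 0.75, tolerance = 1e-12)
  expect_equal(sensitivityAtSpecificity(y, s, 0), 1.0)
})

test_that("the C-index matches pair enumeration and survival::concordance", {
  # perfectly anti-ordered risks, no censoring
  tt <- c(5, 3, 8, 1); rr <- -tt
  expect_equal(cIndex(rr, tt, rep(1, 4)), 1.0)
  # worked example: P = {(1,2),(1,3),(2,3)}, concordant {(1,2),(1,3)}
  expect_equal(cIndex(c(3, 1, 2), c(1, 2, 3), c(1, 1, 0)), 2 / 3,
               tolerance = 1e-12)
  expect_equal(cIndex(rep(1, 4), tt, rep(1, 4)), 0.5)
  set.seed(2)
  n <- 30
  r <- rnorm(n); t2 <- rexp(n); ev <- rbinom(n, 1, 0.7)
  expect_equal(cIndex(r, t2, ev), oracleCIndex(r, t2, ev),
               tolerance = 1e-10)
  cc <- survival::concordance(survival::Surv(t2, ev) ~ r, reverse = TRUE)
  expect_equal(cIndex(r, t2, ev), as.numeric(cc$concordance),
               tolerance = 1e-10)
  expect_error(cIndex(1, 5, 0), "comparable")
})

test_that("the Brier curve reproduces an explicit IPCW computation", {
  # no censoring + oracle stepwise predictions -> Brier identically 0
  tt <- c(2, 4, 6, 8); ev <- rep(1, 4)
  grid <- c(1, 3, 5, 7)
  S <- outer(tt, grid, function(ti, g) as.numeric(ti > g))
  bc <- brierCurve(S, tt, ev, grid)
  expect_true(all(bc$brier == 0))
  expect_equal(integratedBrierScore(bc, 7), 0)
  # no censoring -> weights 1 and Brier = plain MSE
  set.seed(3)
  Sp <- matrix(runif(16), 4, 4)
  Sp <- t(apply(Sp, 1, function(x) sort(x, decreasing = TRUE)))
  bc2 <- brierCurve(Sp, tt, ev, grid)
  plain <- vapply(seq_along(grid), function(g) {
    obs <- as.numeric(tt > grid[g])
    mean((obs - Sp[, g])^2)
  }, 0)
  expect_equal(bc2$brier, plain, tolerance = 1e-10)
  # censored toy vs a hand-computed IPCW sum with explicit KM weights
  tt3 <- c(1, 2, 3, 4, 5); ev3 <- c(1, 0, 1, 1, 0)
  S3 <- matrix(0.6, 5, 2)
  grid3 <- c(2.5, 3.5)
  G <- oracleCensKM(tt3, ev3)
  hand <- vapply(grid3, function(t) {
    tot <- 0
    for (i in 1:5) {
      if (tt3[i] <= t && ev3[i] == 1) {
        tot <- tot + (0 - 0.6)^2 / G(tt3[i], minus = TRUE)
      } else if (tt3[i] > t) {
        tot <- tot + (1 - 0.6)^2 / G(t)
      }
    }
    tot / 5
  }, 0)
  expect_equal(brierCurve(S3, tt3, ev3, grid3)$brier, hand,
               tolerance = 1e-10)
  expect_error(brierCurve(S3, tt3, ev3, c(1, 10)), "follow-up")
})

test_that("integrated Brier score is the normalized trapezoid integral", {
  curve <- data.frame(time = c(0, 2, 4), brier = c(0.1, 0.2, 0.1))
  expect_equal(integratedBrierScore(curve, 4),
               (0.15 * 2 + 0.15 * 2) / 4, tolerance = 1e-12)
  expect_gte(integratedBrierScore(curve, 4), 0)
  expect_lte(integratedBrierScore(curve, 4), 1)
})

test_that("time-dependent AUC reduces to plain AUC and matches its oracle", {
  tt <- c(1, 2, 5, 6, 8); ev <- rep(1, 5); r <- c(5, 4, 1, 2, 3)
  # cases at t = 3: subjects 1, 2 (highest risks) -> perfect separation
  expect_equal(tdAuc(r, tt, ev, 3), 1.0)
  y <- as.integer(tt <= 3)
  expect_equal(tdAuc(r, tt, ev, 3), aucScore(y, r), tolerance = 1e-12)
  # censored toy vs exhaustive weighted pairs
  tt2 <- c(1, 2, 3, 4, 6, 7); ev2 <- c(1, 0, 1, 1, 0, 1)
  r2 <- c(3.0, 2.5, 2.8, 1.0, 0.5, 1.5)
  t0 <- 3.5
  G <- oracleCensKM(tt2, ev2)
  num <- 0; den <- 0
  for (i in 1:6) {
    if (tt2[i] <= t0 && ev2[i] == 1) {
      wi <- 1 / G(tt2[i], minus = TRUE)
      for (j in 1:6) {
        if (tt2[j] > t0) {
          wj <- 1 / G(t0)
          num <- num + wi * wj *
            ((r2[i] > r2[j]) + 0.5 * (r2[i] == r2[j]))
          den <- den + wi * wj
        }
      }
    }
  }
  expect_equal(tdAuc(r2, tt2, ev2, t0), num / den, tolerance = 1e-10)
  expect_error(tdAuc(r, tt, ev, 0.5), "case")
})

test_that("ECE uses equal-mass bins with remainders to the lowest bins", {
  conf <- c(0.6, 0.6, 0.9, 0.9)
  corr <- c(1, 0, 1, 1)
  expect_equal(ece(conf, corr, 2), 0.5 * abs(0.5 - 0.6) +
                 0.5 * abs(1.0 - 0.9), tolerance = 1e-12)
  # perfect calibration within bins -> 0
  expect_equal(ece(c(0.5, 0.5, 1, 1), c(1, 0, 1, 1), 2), 0)
  # single bin reduces to |accuracy - mean confidence|
  set.seed(4)
  cf <- runif(11); cr <- rbinom(11, 1, 0.5)
  expect_equal(ece(cf, cr, 1), abs(mean(cr) - mean(cf)), tolerance = 1e-12)
  # N = 7, M = 3 -> bin sizes 3, 2, 2 by sorted confidence
  cf2 <- (1:7) / 10; cr2 <- c(0, 1, 0, 1, 1, 0, 1)
  hand <- 3 / 7 * abs(mean(cr2[1:3]) - mean(cf2[1:3])) +
    2 / 7 * abs(mean(cr2[4:5]) - mean(cf2[4:5])) +
    2 / 7 * abs(mean(cr2[6:7]) - mean(cf2[6:7]))
  expect_equal(ece(cf2, cr2, 3), hand, tolerance = 1e-12)
  expect_error(ece(cf2, cr2, 9), "bins")
  expect_gte(ece(cf, cr, 3), 0)
  expect_lte(ece(cf, cr, 3), 1)
})

test_that("reliability statistics match the ANOVA mean-squares oracle", {
  # identical columns: perfect repeatability
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(icc31(m), 1.0)
  expect_equal(withinSubjectCV(m), 0)
  # 4 x 2 hand table: explicit mean squares
  m2 <- rbind(c(9, 10), c(6, 5), c(8, 9), c(2, 3))
  n <- 4; k <- 2
  grand <- mean(m2)
  bms <- k * sum((rowMeans(m2) - grand)^2) / (n - 1)
  jms <- n * sum((colMeans(m2) - grand)^2) / (k - 1)
  sse <- sum((m2 - outer(rowMeans(m2), rep(1, k)) -
                outer(rep(1, n), colMeans(m2)) + grand)^2)
  ems <- sse / ((n - 1) * (k - 1))
  expect_equal(icc31(m2), (bms - ems) / (bms + (k - 1) * ems),
               tolerance = 1e-10)
  expect_gt(icc31(m2), -1); expect_lte(icc31(m2), 1)
  expect_equal(withinSubjectCV(m2),
               sqrt(mean(apply(m2, 1, var))) / mean(m2), tolerance = 1e-12)
  # SRM and its degenerate case
  ch <- c(1, 2, 3, 2)
  expect_equal(srm(ch), mean(ch) / sd(ch), tolerance = 1e-12)
  expect_error(srm(c(2, 2, 2)), "zero variance")
})

test_that("bootstrap intervals and DeLong comparison behave as specified", {
  d <- data.frame(x = rnorm(30))
  ci <- bootstrapCi(function(dd) 7, d, B = 50, seed = 1)
  expect_equal(as.numeric(ci), c(7, 7))
  set.seed(5)
  d2 <- data.frame(y = rbinom(60, 1, 0.5), s = rnorm(60))
  ci2 <- bootstrapCi(function(dd) aucScore(dd$y, dd$s), d2, B = 200,
                     seed = 2)
  expect_lt(ci2["low"], aucScore(d2$y, d2$s))
  expect_gt(ci2["high"], aucScore(d2$y, d2$s))

  # identical scores: zero difference, p = 1
  r0 <- delongTest(d2$y, d2$s, d2$s)
  expect_equal(r0$delta, 0)
  expect_equal(r0$p, 1)
  # placement-value variance oracle on a small toy
  y <- c(1, 1, 1, 0, 0)
  sA <- c(0.9, 0.4, 0.7, 0.3, 0.5)
  sB <- c(0.8, 0.6, 0.2, 0.4, 0.1)
  pos <- which(y == 1); neg <- which(y == 0)
  plc <- function(s) {
    V10 <- vapply(pos, function(i)
      mean((s[i] > s[neg]) + 0.5 * (s[i] == s[neg])), 0)
    V01 <- vapply(neg, function(j)
      mean((s[pos] > s[j]) + 0.5 * (s[pos] == s[j])), 0)
    list(V10 = V10, V01 = V01)
  }
  A <- plc(sA); B <- plc(sB)
  S10 <- cov(cbind(A$V10, B$V10)); S01 <- cov(cbind(A$V01, B$V01))
  varOracle <- (S10[1, 1] + S10[2, 2] - 2 * S10[1, 2]) / 3 +
    (S01[1, 1] + S01[2, 2] - 2 * S01[1, 2]) / 2
  r <- delongTest(y, sA, sB)
  expect_equal(r$varDelta, varOracle, tolerance = 1e-10)
  # pROC cross-check on a larger sample
  suppressMessages(requireNamespace("pROC"))
  set.seed(6)
  sC <- rnorm(60) + d2$y
  ours <- delongTest(d2$y, d2$s, sC)
  theirs <- pROC::roc.test(pROC::roc(d2$y, d2$s, quiet = TRUE),
                           pROC::roc(d2$y, sC, quiet = TRUE),
                           method = "delong", paired = TRUE)
  expect_equal(ours$p, as.numeric(theirs$p.value), tolerance = 1e-8)
})

test_that("metrics are invariant to sample reordering", {
  set.seed(7)
  n <- 25
  y <- rbinom(n, 1, 0.5); s <- rnorm(n)
  tt <- rexp(n) + 0.1; ev <- rbinom(n, 1, 0.8); r <- rnorm(n)
  perm <- sample(n)
  expect_equal(aucScore(y, s), aucScore(y[perm], s[perm]))
  expect_equal(cIndex(r, tt, ev), cIndex(r[perm], tt[perm], ev[perm]))
  expect_equal(ece(plogis(s), y, 5), ece(plogis(s)[perm], y[perm], 5))
})
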