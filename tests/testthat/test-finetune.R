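test_that("gated fusion blends, zero-imputes, and keeps fixed length", {
  d <- 2
  zM <- unitRows(matrix(c(1, 0), 1)); zP <- unitRows(matrix(c(0, 1), 1))
  cc <- matrix(c(0.3, -0.2), 1)
  # w = 0 -> alpha = 0.5
  f <- gatedFusion(zM, zP, cbind(1, 1), cc, gate = list(w = c(0, 0), b = 0))
  expect_equal(f$alpha, 0.5)
  expect_equal(as.numeric(f$e), c(0.5 * zM, 0.5 * zP, 0.3, -0.2))
  expect_equal(ncol(f$e), 2 * d + 2)
  # absent PET: its block is exactly zero regardless of alpha
  f2 <- gatedFusion(zM, zP, cbind(1, 0), cc,
                    gate = list(w = c(2, -1), b = 0.5))
  expect_true(all(f2$e[, (d + 1):(2 * d)] == 0))
  expect_equal(f2$alpha, as.numeric(plogis(2 * 1 + (-1) * 0 + 0.5)))
  # hand assembly with q = 0
  zM3 <- unitRows(matrix(c(0.6, 0.8), 1))
  zP3 <- unitRows(matrix(c(1, 0), 1))
  f3 <- gatedFusion(zM3, zP3, cbind(1, 1), NULL,
                    gate = list(w = c(1, 1), b = 0))
  a <- plogis(2)
  expect_equal(as.numeric(f3$e), c(a * zM3, (1 - a) * zP3),
               tolerance = 1e-12)
  expect_error(gatedFusion(zM, zP, cbind(0, 0), cc), "present")
})

test_that("fusion backward matches finite differences", {
  set.seed(1)
  d <- 3; n <- 4
  zM <- randomUnit(n, d); zP <- randomUnit(n, d)
  ind <- cbind(1, c(1, 0, 1, 1))
  cc <- matrix(rnorm(n * 2), n, 2)
  gate <- list(w = c(0.4, -0.3), b = 0.1)
  tgt <- matrix(rnorm(n * (2 * d + 2)), n, 2 * d + 2)
  f <- gatedFusion(zM, zP, ind, cc, gate)
  bw <- neurossl:::gatedFusionBackward(tgt, f)
  fdM <- numericGradient(function(v)
    sum(gatedFusion(matrix(v, n, d), zP, ind, cc, gate)$e * tgt),
    as.numeric(zM))
  expect_equal(as.numeric(bw$dzMri), fdM, tolerance = 1e-6)
  fdw <- numericGradient(function(v)
    sum(gatedFusion(zM, zP, ind, cc, list(w = v, b = gate$b))$e * tgt),
    gate$w)
  expect_equal(bw$gradGate$w, fdw, tolerance = 1e-6)
})

test_that("class-weighted cross-entropy matches hand computation", {
  K <- 4
  logits <- matrix(0, 3, K)
  expect_equal(diagnosisLoss(logits, c(0, 1, 3))$value, log(K),
               tolerance = 1e-12)
  # a huge logit on the true class drives the loss to 0
  sure <- matrix(c(100, 0, 0, 0), 1)
  expect_lt(diagnosisLoss(sure, 0)$value, 1e-10)
  # hand oracle with weights
  set.seed(2)
  l <- matrix(rnorm(6), 3, 2)
  y <- c(0, 1, 1)
  w <- c(1.5, 0.5)
  manual <- -mean(vapply(1:3, function(i) {
    p <- exp(l[i, ]) / sum(exp(l[i, ]))
    w[y[i] + 1] * log(p[y[i] + 1])
  }, 0))
  r <- diagnosisLoss(l, y, w)
  expect_equal(r$value, manual, tolerance = 1e-12)
  fd <- numericGradient(function(v) diagnosisLoss(matrix(v, 3, 2), y, w)$value,
                        as.numeric(l))
  expect_equal(as.numeric(r$gradLogits), fd, tolerance = 1e-6)
  expect_error(diagnosisLoss(l, c(0, 2, 1)), "labels")
  expect_error(diagnosisLoss(l, y, c(-1, 1)), "positive")
})

test_that("Cox partial likelihood follows the printed formula exactly", {
  # two events, uniform risks: -2 * [0 - log 2] at T=1 plus 0 at T=2 -> log 2
  expect_equal(coxPartialLoglik(c(0, 0), c(1, 2), c(1, 1))$value, log(2),
               tolerance = 1e-12)
  # risks (1, 0): -[(1 - log(1 + e)) + 0]
  expect_equal(coxPartialLoglik(c(1, 0), c(1, 2), c(1, 1))$value,
               -((1 - log(1 + exp(1))) + 0), tolerance = 1e-12)
  # a censored subject with T below every event time joins no risk set
  a <- coxPartialLoglik(c(1, 0), c(1, 2), c(1, 1))$value
  b <- coxPartialLoglik(c(1, 0, 0.4), c(1, 2, 0.5), c(1, 1, 0))$value
  expect_equal(a, b, tolerance = 1e-12)
  # exhaustive evaluation on n = 6 with distinct times, plus survival::coxph
  set.seed(3)
  n <- 6
  r <- rnorm(n); tt <- sample(seq_len(n)); ev <- c(1, 1, 0, 1, 0, 1)
  brute <- 0
  for (i in which(ev == 1)) {
    rs <- which(tt >= tt[i])
    brute <- brute - (r[i] - log(sum(exp(r[rs]))))
  }
  mine <- coxPartialLoglik(r, tt, ev)
  expect_equal(mine$value, brute, tolerance = 1e-10)
  fit <- survival::coxph(survival::Surv(tt, ev) ~ offset(r),
                         ties = "breslow")
  expect_equal(mine$value, -fit$loglik[1], tolerance = 1e-8)
  fd <- numericGradient(function(v) coxPartialLoglik(v, tt, ev)$value, r)
  expect_equal(mine$grad, fd, tolerance = 1e-6)
  expect_warning(out <- coxPartialLoglik(c(1, 2), c(1, 2), c(0, 0)),
                 "no events")
  expect_equal(out$value, 0)
})

test_that("distillation averages over the batch and stops the PET gradient", {
  d <- 3
  z <- randomUnit(3, d, seed = 4)
  expect_equal(distillationLoss(z, z, c(1, 1, 1))$value, 0)
  expect_equal(distillationLoss(z, randomUnit(3, d, seed = 5),
                                c(0, 0, 0))$value, 0)
  zM <- randomUnit(3, d, seed = 6); zP <- zM
  zP[2, ] <- randomUnit(1, d, seed = 7)
  r <- distillationLoss(zM, zP, c(0, 1, 0))
  expect_equal(r$value, sum((zM[2, ] - zP[2, ])^2) / 3, tolerance = 1e-12)
  expect_true(all(r$gradPet == 0))
  fd <- numericGradient(function(v)
    distillationLoss(matrix(v, 3, d), zP, c(0, 1, 0))$value, as.numeric(zM))
  expect_equal(as.numeric(r$gradMri), fd, tolerance = 1e-6)
})

test_that("temperature scaling recovers the miscalibration factor", {
  set.seed(8)
  n <- 800; K <- 3
  logits <- matrix(rnorm(n * K, 0, 1.5), n, K)
  P <- exp(logits) / rowSums(exp(logits))
  labels <- vapply(seq_len(n), function(i)
    sample.int(K, 1, prob = P[i, ]) - 1L, 0L)
  tCal <- fitTemperature(logits, labels)
  expect_lt(abs(tCal - 1), 0.05)
  tOver <- fitTemperature(logits * 3, labels)
  expect_lt(abs(tOver - 3) / 3, 0.1)
  # grid-search oracle agrees with the 1-D minimizer
  grid <- exp(seq(log(0.5), log(8), length.out = 400))
  nll <- vapply(grid, function(T) {
    Pt <- applyTemperature(logits * 3, T)
    -mean(log(Pt[cbind(seq_len(n), labels + 1L)]))
  }, 0)
  expect_lt(abs(tOver - grid[which.min(nll)]) / tOver, 0.02)
  # T = 1 is the ordinary softmax; calibration never changes the argmax
  expect_equal(applyTemperature(logits, 1),
               exp(logits) / rowSums(exp(logits)), tolerance = 1e-12)
  expect_identical(max.col(applyTemperature(logits * 3, tOver), ties.method = "first"),
                   max.col(logits * 3, ties.method = "first"))
  expect_error(fitTemperature(logits, rep(0L, n)), "single class")
  expect_error(applyTemperature(logits, -1), "positive")
})

test_that("the joint objective is the stated weighted sum", {
  expect_equal(jointFinetuneLoss(2.5, 9, 9, c(1, 0, 0)), 2.5)
  expect_equal(jointFinetuneLoss(1, 1, 1, c(0.5, 0.3, 0.2)), 1.0)
  set.seed(9)
  v <- runif(3); cf <- runif(3)
  expect_equal(jointFinetuneLoss(v[1], v[2], v[3], cf), sum(v * cf),
               tolerance = 1e-12)
  expect_error(jointFinetuneLoss(1, 1, 1, c(-1, 0, 0)), "nonnegative")
})

test_that("inverse-frequency class weights have mean one", {
  w <- inverseFrequencyWeights(c("a", "a", "a", "b"))
  expect_equal(mean(w), 1)
  expect_gt(w[2], w[1])
})
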