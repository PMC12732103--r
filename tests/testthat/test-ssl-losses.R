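# Oracles for the loss stack: closed forms where the geometry forces the
# value, scalar softmax computations for generic batches, brute-force pair
# loops for the longitudinal sums, and finite differences for the gradient
# contracts.

test_that("intra-modal InfoNCE matches closed forms and a scalar oracle", {
  d <- 6
  # all candidates at equal similarity -> uniform softmax -> log(C)
  z <- matrix(rep(randomUnit(1, d, seed = 1), 5), 5, d, byrow = TRUE)
  r <- intraModalInfoNCE(z, z, tau = 0.1)
  expect_equal(r$value, log(5), tolerance = 1e-12)
  q <- matrix(rep(z[1, ], 3), 3, d, byrow = TRUE)
  expect_equal(intraModalInfoNCE(z, z, queue = q, tau = 0.1)$value, log(8),
               tolerance = 1e-12)

  # orthogonal positives: positive sim 1, negatives 0, C candidates
  z2 <- diag(1, 4, d)
  r2 <- intraModalInfoNCE(z2, z2, tau = 0.1)
  expect_equal(r2$value, log(1 + 3 * exp(-10)), tolerance = 1e-12)

  # generic batch vs an independent per-anchor softmax computation
  set.seed(2)
  A <- randomUnit(4, 2); P <- randomUnit(4, 2)
  tau <- 0.17
  manual <- mean(vapply(1:4, function(i) {
    sims <- as.numeric(P %*% A[i, ]) / tau
    -log(exp(sims[i]) / sum(exp(sims)))
  }, 0))
  expect_equal(intraModalInfoNCE(A, P, tau = tau)$value, manual,
               tolerance = 1e-12)

  expect_error(intraModalInfoNCE(A, P, tau = 0), "positive")
  expect_error(intraModalInfoNCE(A * 2, P, tau = 0.1), "unit-norm")
})

test_that("cross-modal InfoNCE is symmetric with the expected closed form", {
  d <- 8; N <- 5; tau <- 0.1
  # perfect alignment, mutually orthogonal pairs
  z <- diag(1, N, d)
  r <- crossModalInfoNCE(z, z, tau = tau)
  expect_equal(r$value, 2 * log(1 + (N - 1) * exp(-1 / tau)),
               tolerance = 1e-12)
  # a lone pair has softmax probability 1 in both directions
  s <- randomUnit(1, d, seed = 3)
  t <- randomUnit(1, d, seed = 4)
  expect_equal(crossModalInfoNCE(s, t)$value, 0, tolerance = 1e-12)
  # generic batch equals the sum of two directional values, and swapping
  # modality roles with matched queues leaves the value unchanged
  set.seed(5)
  M <- randomUnit(3, 2); P <- randomUnit(3, 2)
  qm <- randomUnit(2, 2); qp <- randomUnit(2, 2)
  v1 <- crossModalInfoNCE(M, P, qm, qp, tau = 0.2)
  dir1 <- intraModalInfoNCE(M, P, qp, tau = 0.2)$value
  dir2 <- intraModalInfoNCE(P, M, qm, tau = 0.2)$value
  expect_equal(v1$value, dir1 + dir2, tolerance = 1e-12)
  v2 <- crossModalInfoNCE(P, M, qp, qm, tau = 0.2)
  expect_equal(v1$value, v2$value, tolerance = 1e-12)
  expect_error(crossModalInfoNCE(M, P[1:2, ]), "paired")
})

test_that("losses are invariant to batch reordering", {
  set.seed(6)
  A <- randomUnit(6, 4); P <- randomUnit(6, 4)
  perm <- sample(6)
  expect_equal(intraModalInfoNCE(A, P)$value,
               intraModalInfoNCE(A[perm, ], P[perm, ])$value,
               tolerance = 1e-12)
  expect_equal(crossModalInfoNCE(A, P)$value,
               crossModalInfoNCE(A[perm, ], P[perm, ])$value,
               tolerance = 1e-12)
})

test_that("longitudinal losses equal explicit pair enumeration", {
  d <- 4
  # identical embeddings across visits -> 0
  z <- matrix(rep(randomUnit(1, d, seed = 7), 3), 3, d, byrow = TRUE)
  r <- longitudinalConsistency(z, rep("s1", 3), c(0, 6, 12), rep("MRI", 3))
  expect_equal(r$value, 0)
  expect_equal(r$nPairs, 3L)
  # one subject, two visits: the single squared distance
  z2 <- randomUnit(2, d, seed = 8)
  r2 <- longitudinalConsistency(z2, c("a", "a"), c(0, 6), c("MRI", "MRI"))
  expect_equal(r2$value, sum((z2[1, ] - z2[2, ])^2), tolerance = 1e-12)
  # random cohort vs brute-force double loop
  set.seed(9)
  n <- 9
  zz <- randomUnit(n, d)
  sub <- rep(c("a", "b", "c"), each = 3)
  tim <- rep(c(0, 6, 12), 3)
  mod <- rep("MRI", n)
  brute <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i < j && sub[i] == sub[j] && mod[i] == mod[j] && tim[i] != tim[j])
      brute <- brute + sum((zz[i, ] - zz[j, ])^2)
  }
  r3 <- longitudinalConsistency(zz, sub, tim, mod)
  expect_equal(r3$value, brute, tolerance = 1e-12)
  # subjects with a single visit contribute 0
  r4 <- longitudinalConsistency(zz[1:4, ], c("a", "b", "c", "d"),
                                c(0, 0, 0, 0), rep("MRI", 4))
  expect_equal(r4$value, 0)
  expect_equal(r4$nPairs, 0L)
})

test_that("cross-time cross-modal coupling enumerates MRI x PET visit pairs", {
  d <- 4
  z <- matrix(rep(randomUnit(1, d, seed = 10), 4), 4, d, byrow = TRUE)
  r <- crossTimeCrossModal(z, rep("s", 4), c(0, 6, 0, 6),
                           c("MRI", "MRI", "PET", "PET"))
  expect_equal(r$value, 0)
  # one MRI@t1, one PET@t2: single pair
  z2 <- randomUnit(2, d, seed = 11)
  r2 <- crossTimeCrossModal(z2, c("s", "s"), c(0, 6), c("MRI", "PET"))
  expect_equal(r2$value, sum((z2[1, ] - z2[2, ])^2), tolerance = 1e-12)
  # same-time pairs are excluded (they belong to the cross-modal InfoNCE)
  r3 <- crossTimeCrossModal(z2, c("s", "s"), c(6, 6), c("MRI", "PET"))
  expect_equal(r3$value, 0)
  # brute force on a random cohort
  set.seed(12)
  n <- 8
  zz <- randomUnit(n, d)
  sub <- rep(c("a", "b"), each = 4)
  tim <- rep(c(0, 6), 4)
  mod <- rep(c("MRI", "MRI", "PET", "PET"), 2)
  brute <- 0
  for (i in 1:n) for (j in 1:n) {
    if (sub[i] == sub[j] && mod[i] == "MRI" && mod[j] == "PET" &&
        tim[i] != tim[j])
      brute <- brute + sum((zz[i, ] - zz[j, ])^2)
  }
  expect_equal(crossTimeCrossModal(zz, sub, tim, mod)$value, brute,
               tolerance = 1e-12)
})

test_that("BYOL loss honors the stop-gradient contract", {
  d <- 5
  idPred <- list(W = diag(d), b = rep(0, d))
  z <- randomUnit(3, d, seed = 13)
  expect_equal(byolLoss(z, z, idPred)$value, 0)
  z2 <- randomUnit(1, d, seed = 14)
  z3 <- randomUnit(1, d, seed = 15)
  expect_equal(byolLoss(z2, z3, idPred)$value, sum((z2 - z3)^2),
               tolerance = 1e-12)
  # target branch receives exactly zero gradient; online branch matches FD
  set.seed(16)
  pred <- list(W = diag(d) + matrix(rnorm(d * d, 0, 0.1), d), b = rnorm(d))
  zo <- randomUnit(3, d); zt <- randomUnit(3, d)
  r <- byolLoss(zo, zt, pred)
  expect_true(all(r$gradTarget == 0))
  fd <- numericGradient(function(v) {
    byolLoss(matrix(v, 3, d), zt, pred)$value
  }, as.numeric(zo))
  expect_equal(as.numeric(r$gradOnline), fd, tolerance = 1e-5)
  fdW <- numericGradient(function(v) {
    byolLoss(zo, zt, list(W = matrix(v, d, d), b = pred$b))$value
  }, as.numeric(pred$W))
  expect_equal(as.numeric(r$gradPredictor$W), fdW, tolerance = 1e-5)
})

test_that("site-adversarial loss reverses and scales the encoder gradient", {
  d <- 4; S <- 3
  z <- randomUnit(5, d, seed = 17)
  # uniform discriminator -> log(S)
  disc0 <- list(W = matrix(0, d, S), b = rep(0, S))
  expect_equal(siteAdversarialLoss(z, c(1, 2, 3, 1, 2), disc0)$value, log(S),
               tolerance = 1e-12)
  # a discriminator putting probability ~1 on the true site -> loss ~0
  site <- c(1L, 2L, 3L, 1L, 2L)
  one <- siteAdversarialLoss(z[1, , drop = FALSE], 1L,
                             list(W = matrix(0, d, S), b = c(50, 0, 0)))
  expect_lt(one$value, 1e-10)
  # gradient contract vs finite differences
  set.seed(18)
  disc <- list(W = matrix(rnorm(d * S, 0, 0.5), d, S), b = rnorm(S))
  lam <- 0.7
  r <- siteAdversarialLoss(z, site, disc, grlStrength = lam)
  fdz <- numericGradient(function(v)
    siteAdversarialLoss(matrix(v, 5, d), site, disc)$value, as.numeric(z))
  expect_equal(as.numeric(r$gradZ), fdz, tolerance = 1e-5)
  expect_equal(as.numeric(r$gradEncoder), -lam * fdz, tolerance = 1e-5)
  fdW <- numericGradient(function(v)
    siteAdversarialLoss(z, site, list(W = matrix(v, d, S), b = disc$b))$value,
    as.numeric(disc$W))
  expect_equal(as.numeric(r$gradDiscriminator$W), fdW, tolerance = 1e-5)
  expect_error(siteAdversarialLoss(z, c(1, 2, 5, 1, 1), disc), "site")
})

test_that("the total SSL loss is the stated weighted sum", {
  w0 <- sslWeights(intra = 0, cross = 0, byol = 0, long = 0, longx = 0,
                   site = 0)
  expect_equal(totalSslLoss(c(intra = 3, site = 2), w0)$total, 0)
  w1 <- sslWeights(intra = 0.5, cross = 0, byol = 0, long = 0, longx = 0,
                   site = 0)
  expect_equal(totalSslLoss(c(intra = 2), w1)$total, 1.0)
  set.seed(19)
  comp <- setNames(runif(6), c("intra", "cross", "byol", "long", "longx",
                               "site"))
  lam <- runif(6)
  w <- sslWeights(lam[1], lam[2], lam[3], lam[4], lam[5], lam[6])
  expect_equal(totalSslLoss(comp, w)$total, sum(lam * comp),
               tolerance = 1e-12)
  expect_error(sslWeights(intra = -1), "nonnegative")
})

test_that("the MoCo queue is FIFO and the momentum update interpolates", {
  q <- momentumQueue(4, 3)
  k1 <- randomUnit(2, 3, seed = 20)
  k2 <- randomUnit(2, 3, seed = 21)
  k3 <- randomUnit(2, 3, seed = 22)
  q <- queuePush(q, k1)
  q <- queuePush(q, k2)
  expect_equal(queueKeys(q), rbind(k1, k2))
  q <- queuePush(q, k3)  # overwrites the two oldest
  expect_equal(queueKeys(q), rbind(k2, k3))
  expect_error(queuePush(q, 2 * k1), "unit-norm")

  online <- list(a = list(W = matrix(2, 2, 2), b = c(2, 2)))
  key <- list(a = list(W = matrix(0, 2, 2), b = c(0, 0)))
  expect_identical(momentumUpdate(key, online, 1), key)
  expect_identical(momentumUpdate(key, online, 0), online)
  half <- momentumUpdate(key, online, 0.5)
  expect_equal(half$a$W, matrix(1, 2, 2))
  expect_error(momentumUpdate(key, online, 1.5), "momentum")
})
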