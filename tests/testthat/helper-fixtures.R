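# Shared fixtures and small utilities; everything is generated in code.

unitRows <- function(m) m / sqrt(rowSums(m^2))

randomUnit <- function(n, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  unitRows(matrix(rnorm(n * d), n, d))
}

# lazily built shared fixtures (built once per test run)
.fixtures <- new.env(parent = emptyenv())

fixtureCohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generateCohort(
      cohortConfig(nSubjects = 12L, nSites = 2L, gridSize = 8L,
                   visitsRange = c(2L, 3L), petMissingProb = 0.25,
                   seed = 42L))
  }
  .fixtures$cohort
}

tinySpec <- function() encoderSpec(gridSize = 8L, widths = c(4L, 6L, 8L),
                                   dim = 8L, groups = 2L)

# brute-force oracles ---------------------------------------------------------

oracleAuc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

oracleCIndex <- function(risks, times, events) {
  num <- 0; den <- 0
  n <- length(risks)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (events[i] == 1 && times[i] < times[j]) {
      den <- den + 1
      num <- num + (risks[i] > risks[j]) + 0.5 * (risks[i] == risks[j])
    }
  }
  num / den
}

# Kaplan-Meier of the censoring distribution by explicit product
oracleCensKM <- function(times, events) {
  ts <- sort(unique(times[events == 0]))
  function(t, minus = FALSE) {
    s <- 1
    for (u in ts) {
      include <- if (minus) u < t else u <= t
      if (include) {
        atRisk <- sum(times >= u)
        dCens <- sum(times == u & events == 0)
        s <- s * (1 - dCens / atRisk)
      }
    }
    s
  }
}

numericGradient <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
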