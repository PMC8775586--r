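# Independent oracles used across the suite. Each is a deliberately naive
# implementation (scalar arithmetic, brute-force sums, full enumeration) kept
# separate from the package code paths it checks.

# Scalar A1 pigment nomogram (alpha band), transcribed independently from the
# published template parameterization.
oraclePigmentAlpha <- function(lambda, lambdaMax) {
  x <- lambdaMax / lambda
  a <- 0.8795 + 0.0459 * exp(-(lambdaMax - 300)^2 / 11940)
  1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
         exp(-14.9 * (1.104 - x)) + 0.674)
}

# Sort-and-pick 3x3 median with symmetric (edge-replicating) padding.
oracleMedian3x3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ii <- pmin(pmax(i + (-1):1, 1), nr)
      jj <- pmin(pmax(j + (-1):1, 1), nc)
      out[i, j] <- sort(as.vector(img[ii, jj]))[5]
    }
  }
  out
}

# Direct circular autocorrelation: R(dy, dx) of the mean-subtracted image,
# normalized by the zero-lag sum.
oracleCircularAutocorr <- function(img, dy, dx) {
  z <- img - mean(img)
  nr <- nrow(z); nc <- ncol(z)
  shifted <- z[((seq_len(nr) - 1 + dy) %% nr) + 1,
               ((seq_len(nc) - 1 + dx) %% nc) + 1, drop = FALSE]
  sum(z * shifted) / sum(z * z)
}

# Grid-search Weibull likelihood maximizer on a log-spaced 200x200 grid.
oracleWeibullGrid <- function(x, betaRange, gammaRange, n = 200) {
  bs <- exp(seq(log(betaRange[1]), log(betaRange[2]), length.out = n))
  gs <- exp(seq(log(gammaRange[1]), log(gammaRange[2]), length.out = n))
  best <- c(NA, NA, -Inf)
  lx <- log(x)
  for (g in gs) {
    xg <- x^g
    for (b in bs) {
      ll <- length(x) * (log(g) - g * log(b)) + (g - 1) * sum(lx) -
        sum(xg) / b^g
      if (ll > best[3]) best <- c(b, g, ll)
    }
  }
  list(beta = best[1], gamma = best[2], logLik = best[3])
}

# Exact two-sided sign-test p-value by direct binomial summation.
oracleSignP <- function(k, n) {
  probs <- stats::dbinom(0:n, n, 0.5)
  sum(probs[probs <= stats::dbinom(k, n, 0.5) + 1e-12])
}

# Exact two-sided rank-sum p-value by full enumeration of group assignments.
oracleRanksumP <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  wObs <- sum(r[seq_len(na)])
  combos <- utils::combn(na + nb, na)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- na * (na + nb + 1) / 2
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-9)
}

# Brute-force count of integer lattice points inside a disk.
oracleDiskCount <- function(radius) {
  n <- 0L
  for (dx in (-radius):radius)
    for (dy in (-radius):radius)
      if (dx^2 + dy^2 <= radius^2) n <- n + 1L
  n
}

# Small helpers shared by scene-level tests.
makeTestMetadata <- function(stem = "s1", elevation = "up",
                             exposureS = 0.01, ndOd = 0) {
  new("SceneMetadata", stem = stem, elevation = elevation,
      exposureS = exposureS, ndOd = ndOd)
}

makeTestPair <- function(uv, green, stem = "s1", elevation = "up",
                         normalized = FALSE) {
  scenePair(uv, green, makeTestMetadata(stem, elevation),
            normalized = normalized)
}
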