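# central finite-difference gradient, independent of the analytic gradients
fdGradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# random points strictly inside a surface's domain (margin keeps finite
# differences inside too)
randomInteriorPoints <- function(surface, n, margin = 0.05, seed = 1) {
  set.seed(seed)
  lo <- surface@domain[1, ]; hi <- surface@domain[2, ]
  span <- hi - lo
  t(replicate(n, lo + span * (margin + (1 - 2 * margin) * runif(length(lo)))))
}

expect_gradient_consistent <- function(surface, n = 100, seed = 1,
                                       tol = 1e-6) {
  pts <- randomInteriorPoints(surface, n, seed = seed)
  for (i in seq_len(nrow(pts))) {
    x <- pts[i, ]
    g <- surface@gradFunc(x)
    gf <- fdGradient(surface@energyFunc, x)
    expect_lt(max(abs(g - gf)) / max(1, max(abs(g))), tol)
    expect_true(is.finite(surface@energyFunc(x)))
  }
}

# minimal valid TrajectoryStats for analysis-level tests
fakeStats <- function(monitored = list(), meanDev = 0, nSamples = 10L) {
  N <- length(meanDev)
  new("TrajectoryStats", meanDeviation = as.numeric(meanDev),
      gradientProducts = diag(N), nSamples = as.integer(nSamples),
      blockMeans = matrix(rep(as.numeric(meanDev), each = 10), 10, N),
      monitoredSamples = monitored, finalConfiguration = numeric(N),
      storedConfigurations = matrix(numeric(0), 0, N))
}

# random 3-D rigid motion
randomRigidMotion <- function(seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(Q = Q, t = rnorm(3))
}

applyRigid <- function(x, rm) {
  xyz <- matrix(x, ncol = 3, byrow = TRUE)
  as.vector(t(xyz %*% t(rm$Q) + matrix(rm$t, nrow(xyz), 3, byrow = TRUE)))
}
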