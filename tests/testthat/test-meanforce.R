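test_that("zero mean deviation gives a zero gradient estimate", {
  st <- fakeStats(meanDev = c(0, 0))
  est <- estimateGradient(st, restraintSpec(c(1, 2), k = 100))
  expect_identical(est@gradient, c(0, 0))
})

test_that("the stiff-spring estimator matches the 1-D quadratic closed form", {
  a <- 1; z <- 0.8
  q <- quadraticWell(a, 1)
  spec <- restraintSpec(z, k = 100)
  st <- runRestrained(q, identityCVSet(1), spec,
                      samplerConfig(temperature = 0.5, timestep = 0.002,
                                    nStepsTotal = 4e4, nStepsBurnin = 4000,
                                    seed = 21), x0 = z)
  est <- estimateGradient(st, spec)
  # k a z / (a + k) = 0.990 * a z, approaching a z as k -> Inf
  expect_equal(unname(est@gradient), 100 * a * z / (a + 100),
               tolerance = 3 * est@standardError / abs(est@gradient))
})

test_that("stiff-spring bias shrinks monotonically with k (deterministic limit)", {
  a <- 2; z <- 1
  q <- quadraticWell(a, 1)
  bias <- vapply(c(10, 100, 1000), function(k) {
    # timestep scaled to the combined stiffness; average only the
    # fully relaxed tail
    st <- runRestrained(q, identityCVSet(1), restraintSpec(z, k),
                        samplerConfig(temperature = 0,
                                      timestep = 0.5 / (a + k),
                                      nStepsTotal = 200, nStepsBurnin = 190),
                        x0 = z)
    abs(unname(estimateGradient(st, restraintSpec(z, k))@gradient) - a * z)
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
  expect_equal(bias[1], a^2 * z / (a + 10), tolerance = 1e-4)
})

test_that("the double-well spine gradient is recovered at x = 0.5", {
  dw <- doubleWell(h = 5, c = 1)
  spec <- restraintSpec(c(0.5, 0), k = 400)
  st <- runRestrained(dw, identityCVSet(2), spec,
                      samplerConfig(temperature = 0.5925, timestep = 5e-4,
                                    nStepsTotal = 3e4, nStepsBurnin = 5000,
                                    seed = 31), x0 = c(0.5, 0))
  est <- estimateGradient(st, spec)
  # dV/dx = 4 h (x^3 - x) = -7.5 at x = 0.5
  expect_equal(est@gradient[1], -7.5,
               tolerance = 3 * est@standardError[1] / 7.5)
})

test_that("metric tensor has exact values for rigid linear CV maps", {
  # identity CVs: M = I exactly
  dw <- doubleWell()
  st <- runRestrained(dw, identityCVSet(2), restraintSpec(c(0, 0)),
                      samplerConfig(temperature = 0.3, nStepsTotal = 200,
                                    nStepsBurnin = 20, seed = 3), c(0, 0))
  expect_identical(estimateMetric(st), diag(2))
})

test_that("metric of distance CVs encodes bond-vector geometry", {
  # lone distance between two free atoms: M = 2 exactly
  q6 <- quadraticWell(1, 6)
  dcv <- cvSet(cvDistance(1, 2, "d"))
  x0 <- c(0, 0, 0, 1, 0, 0)
  st <- runRestrained(q6, dcv, restraintSpec(1, k = 50),
                      samplerConfig(temperature = 0, timestep = 0.002,
                                    nStepsTotal = 200, nStepsBurnin = 10),
                      x0)
  expect_equal(unname(estimateMetric(st)[1, 1]), 2, tolerance = 1e-12)

  # two distances sharing a vertex at angle phi: M12 = cos(phi)
  q9 <- quadraticWell(1e-9, 9)
  two <- cvSet(cvDistance(1, 2, "d12"), cvDistance(2, 3, "d23"))
  for (phi in c(90, 60, 120)) {
    rad <- phi * pi / 180
    x <- c(1, 0, 0, 0, 0, 0, cos(rad), sin(rad), 0)
    J <- cvGradients(two, x)
    M <- tcrossprod(J)
    expect_equal(M[1, 2], cos(rad), tolerance = 1e-12)
  }
  # right angle: orthogonal bond vectors, zero off-diagonal
  xr <- c(1, 0, 0, 0, 0, 0, 0, 1, 0)
  expect_equal(tcrossprod(cvGradients(two, xr))[1, 2], 0)
})

test_that("block standard errors scale like independent-sample errors", {
  q <- quadraticWell(1, 1)
  spec <- restraintSpec(0, k = 9)
  st <- runRestrained(q, identityCVSet(1), spec,
                      samplerConfig(temperature = 1, timestep = 0.005,
                                    nStepsTotal = 5e4, nStepsBurnin = 5000,
                                    seed = 77), 0)
  est <- estimateGradient(st, spec)
  # theoretical SD of the mean of n_eff decorrelated samples
  sdTheta <- sqrt(1 / 10)
  tau <- 1 / (10 * 0.005)          # relaxation steps
  nEff <- st@nSamples / (2 * tau)
  expect_equal(unname(est@standardError), 9 * sdTheta / sqrt(nEff),
               tolerance = 0.5)
})
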