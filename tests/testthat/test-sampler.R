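test_that("harmonic restraint energy and force have closed forms", {
  spec <- restraintSpec(0, k = 100)
  atRef <- harmonicRestraint(0, spec)
  expect_identical(atRef$energy, 0)
  expect_identical(atRef$force, 0)
  off <- harmonicRestraint(0.1, spec)
  expect_equal(off$energy, 0.5)
  expect_equal(off$force, -10)
  doubled <- harmonicRestraint(0.1, restraintSpec(0, k = 200))
  expect_equal(doubled$energy, 2 * off$energy)
  expect_equal(doubled$force, 2 * off$force)
})

test_that("equal seeds reproduce trajectories bit for bit", {
  dw <- doubleWell(5, 1)
  cvs <- identityCVSet(2)
  cfg <- samplerConfig(temperature = 0.5, nStepsTotal = 500,
                       nStepsBurnin = 100, seed = 99, storeEvery = 50)
  s1 <- runRestrained(dw, cvs, restraintSpec(c(0.3, 0)), cfg, c(0.3, 0))
  s2 <- runRestrained(dw, cvs, restraintSpec(c(0.3, 0)), cfg, c(0.3, 0))
  expect_identical(s1@meanDeviation, s2@meanDeviation)
  expect_identical(s1@finalConfiguration, s2@finalConfiguration)
  expect_identical(s1@storedConfigurations, s2@storedConfigurations)
  cfg@seed <- 100L
  s3 <- runRestrained(dw, cvs, restraintSpec(c(0.3, 0)), cfg, c(0.3, 0))
  expect_false(identical(s1@meanDeviation, s3@meanDeviation))
})

test_that("zero temperature relaxes to the restrained minimizer", {
  # V = a x^2 / 2 restrained at z: minimum at k z / (a + k)
  a <- 2; k <- 50; z <- 1.2
  q <- quadraticWell(a, 1)
  cfg <- samplerConfig(temperature = 0, timestep = 0.005,
                       nStepsTotal = 2000, nStepsBurnin = 1500)
  st <- runRestrained(q, identityCVSet(1), restraintSpec(z, k), cfg, x0 = 0)
  expect_equal(st@finalConfiguration, k * z / (a + k), tolerance = 1e-6)
  expect_equal(unname(st@meanDeviation), z - k * z / (a + k),
               tolerance = 1e-6)
})

test_that("identity CVs give the identity Gram matrix at every step", {
  dw <- doubleWell(5, 1)
  st <- runRestrained(dw, identityCVSet(2), restraintSpec(c(0.5, 0)),
                      samplerConfig(temperature = 0.5, nStepsTotal = 300,
                                    nStepsBurnin = 50, seed = 2),
                      c(0.5, 0))
  expect_identical(st@gradientProducts, diag(2))
})

test_that("restrained means and variances match the Gaussian closed form", {
  # combined quadratic a + k: mean k z/(a+k), variance kBT/(a+k)
  a <- 1; k <- 9; z <- 2; kBT <- 1
  q <- quadraticWell(a, 1)
  cfg <- samplerConfig(temperature = kBT, timestep = 0.005,
                       nStepsTotal = 1e5, nStepsBurnin = 5000, seed = 42)
  st <- runRestrained(q, identityCVSet(1), restraintSpec(z, k), cfg, x0 = 0,
                      monitors = identityCVSet(1, labels = "xmon"))
  est <- estimateGradient(st, restraintSpec(z, k))
  expect_equal(unname(est@gradient), k * a * z / (a + k),
               tolerance = 3 * est@standardError / abs(est@gradient))
  v <- var(st@monitoredSamples$xmon)
  expect_lt(abs(v - kBT / (a + k)) / (kBT / (a + k)), 0.05)
})

test_that("burn-in doubling on an equilibrated start is within noise", {
  a <- 1; k <- 9; z <- 2
  q <- quadraticWell(a, 1)
  x0 <- k * z / (a + k)  # start at the restrained mean
  st1 <- runRestrained(q, identityCVSet(1), restraintSpec(z, k),
                       samplerConfig(temperature = 1, timestep = 0.005,
                                     nStepsTotal = 2e4, nStepsBurnin = 2000,
                                     seed = 8), x0)
  st2 <- runRestrained(q, identityCVSet(1), restraintSpec(z, k),
                       samplerConfig(temperature = 1, timestep = 0.005,
                                     nStepsTotal = 2e4, nStepsBurnin = 4000,
                                     seed = 8), x0)
  se <- estimateGradient(st1, restraintSpec(z, k))@standardError / k
  expect_lt(abs(st1@meanDeviation - st2@meanDeviation), 2 * se)
})

test_that("sampler reports domain escapes and rejects bad inputs", {
  dw <- doubleWell(5, 1)
  cvs <- identityCVSet(2)
  cfg <- samplerConfig(temperature = 0.5, nStepsTotal = 100, nStepsBurnin = 10)
  expect_error(runRestrained(dw, cvs, restraintSpec(c(0, 0)), cfg,
                             c(10, 0)), "outside the surface domain")
  # a hugely displaced anchor drags the trajectory out of the domain
  expect_error(runRestrained(dw, cvs, restraintSpec(c(50, 0), k = 1e4),
                             cfg, c(1, 0)), "left the surface domain")
  expect_error(samplerConfig(nStepsTotal = 100, nStepsBurnin = 100))
})
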