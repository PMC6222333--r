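mkEst <- function(g, N = length(g))
  new("MeanForceEstimate", gradient = as.numeric(g), metric = diag(N),
      standardError = numeric(N), imageIndex = 1L)

test_that("zero gradients integrate to a flat profile", {
  p <- initString(c(0, 0), c(1, 1), R = 11)
  prof <- integrateProfile(p, replicate(11, mkEst(c(0, 0)), simplify = FALSE))
  expect_identical(profileG(prof), numeric(75))
  expect_identical(profileG(prof)[1], 0)
})

test_that("a straight line with constant gradient integrates to g * L", {
  L <- 2.4; g <- 1.7
  p <- initString(0, L, R = 9)
  prof <- integrateProfile(p, replicate(9, mkEst(g), simplify = FALSE),
                           nGrid = 75)
  expect_equal(profileG(prof)[75], g * L, tolerance = 1e-6)
  # additivity: the cumulative integral ends where segment sums end
  mid <- profileG(prof)[38]
  expect_equal(mid + (profileG(prof)[75] - mid), g * L, tolerance = 1e-12)
})

test_that("grid refinement changes converged barriers by less than 0.1%", {
  # integrable analytic case: z(alpha) = alpha, dG/dz = sin(2 pi z) * 3
  p <- initString(0, 1, R = 25)
  ests <- lapply(seq_len(25), function(r)
    mkEst(3 * sin(2 * pi * images(p)[r, 1])))
  b1 <- max(profileG(integrateProfile(p, ests, nGrid = 75)))
  b2 <- max(profileG(integrateProfile(p, ests, nGrid = 150)))
  expect_lt(abs(b2 - b1) / b1, 0.001)
  expect_error(integrateProfile(initString(0, 1, R = 3),
                                replicate(3, mkEst(0), simplify = FALSE)),
               "at least 4")
})

test_that("stationary-state classification labels minima and maxima in order", {
  a <- seq(0, 1, length.out = 101)
  single <- new("FreeEnergyProfile", alphaGrid = a,
                G = 4 * sin(pi * a)^2 * c(rep(1, 101)), stderr = numeric(101),
                sourceCycles = 1L)
  ss <- locateStationaryStates(single)
  expect_identical(ss$label, c("RC", "TS1", "PC"))
  expect_equal(ss$alpha[2], 0.5, tolerance = 0.02)

  mono <- new("FreeEnergyProfile", alphaGrid = a, G = a * 3 - a * a,
              stderr = numeric(101), sourceCycles = 1L)
  mono@G <- mono@G - mono@G[1]
  expect_identical(locateStationaryStates(mono)$label, c("RC", "PC"))
})

test_that("the GAC-like analytic spine yields 4 TS and 3 IM in order", {
  pr <- protonRelaySurface(6)
  sp <- relaySpine(pr, s = seq(0, 8, length.out = 401))
  prof <- new("FreeEnergyProfile", alphaGrid = sp$s / 8, G = sp$G,
              stderr = numeric(401), sourceCycles = 1L)
  ss <- locateStationaryStates(prof)
  expect_identical(ss$label,
                   c("RC", "TS1", "IM1", "TS2", "IM2", "TS3", "IM3",
                     "TS4", "PC"))
  expect_equal(ss$G, unname(gacProfileValues()), tolerance = 1e-6)
})

test_that("low-prominence wiggles are suppressed by the local-stderr rule", {
  a <- seq(0, 1, length.out = 201)
  G <- 5 * sin(pi * a)^2
  G[90:112] <- G[90:112] + 0.05 * sin(seq(0, 4 * pi, length.out = 23))
  se <- rep(0.2, 201)
  noisy <- new("FreeEnergyProfile", alphaGrid = a, G = G - G[1],
               stderr = se, sourceCycles = 1L)
  expect_identical(locateStationaryStates(noisy)$label, c("RC", "TS1", "PC"))
  # with stderr zero the same wiggles are kept as genuine extrema
  clean <- new("FreeEnergyProfile", alphaGrid = a, G = G - G[1],
               stderr = numeric(201), sourceCycles = 1L)
  expect_gt(nrow(locateStationaryStates(clean)), 3)
})

test_that("profile uncertainty pools trailing cycles pointwise", {
  a <- seq(0, 1, length.out = 41)
  base <- new("FreeEnergyProfile", alphaGrid = a, G = a * 2 - a^2 * 2,
              stderr = numeric(41), sourceCycles = 1L)
  base@G <- base@G - base@G[1]
  same <- profileUncertainty(list(base, base, base))
  expect_identical(profileStderr(same), numeric(41))

  # two profiles differing by c at one point: sample SD = c / sqrt(2)
  shifted <- base
  shifted@G[20] <- shifted@G[20] + 0.4
  two <- profileUncertainty(list(base, shifted))
  expect_equal(profileStderr(two)[20], 0.4 / sqrt(2))
  expect_identical(profileStderr(two)[10], 0)

  bad <- new("FreeEnergyProfile", alphaGrid = seq(0, 1, length.out = 40),
             G = numeric(40), stderr = numeric(40), sourceCycles = 1L)
  expect_error(profileUncertainty(list(base, bad)), "mismatched")
})

test_that("injected i.i.d. noise is recovered by the pooled SD", {
  a <- seq(0, 1, length.out = 75)
  sigma <- 0.3
  set.seed(5)
  profs <- lapply(1:10, function(i) {
    g <- 5 * sin(pi * a)^2 + rnorm(75, sd = sigma)
    g <- g - g[1]; g[1] <- 0
    new("FreeEnergyProfile", alphaGrid = a, G = g, stderr = numeric(75),
        sourceCycles = as.integer(i))
  })
  pooled <- profileUncertainty(profs)
  sds <- profileStderr(pooled)[-1]   # alpha = 0 pinned to zero by centering
  # centering against the alpha = 0 noise inflates the SD by ~sqrt(2);
  # the mean recovered SD must sit between sigma and sqrt(2) sigma
  expect_lt(abs(mean(sds) - sigma * sqrt(1.5)) / sigma, 0.4)
  expect_gt(mean(sds), 0.6 * sigma)
})

test_that("Eyring conversions reproduce transition-state-theory identities", {
  kB <- 1.380649e-23; h <- 6.62607015e-34
  Tk <- 305
  expect_equal(eyringBarrier(kB * Tk / h, Tk), 0, tolerance = 1e-12)
  # round trip
  expect_equal(eyringRate(eyringBarrier(0.2, 300), 300), 0.2,
               tolerance = 1e-10)
  expect_error(eyringBarrier(-1), "rate")
  expect_error(eyringBarrier(1, -5), "temperature")
})

test_that("half-life conversion is exact and scales inversely with rate", {
  hl <- firstOrderHalfLife(2)
  expect_equal(hl$seconds, log(2) / 2)
  expect_equal(firstOrderHalfLife(4)$seconds, hl$seconds / 2)
  expect_equal(hl$days, hl$seconds / 86400)
  expect_error(firstOrderHalfLife(0), "rate")
})
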