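test_that("analytic gradients match finite differences on random interior points", {
  surfaces <- list(mullerBrown(), doubleWell(5, 1), doubleWell(2, 7),
                   protonRelaySurface(6), protonRelaySurface(4, sacProfileValues()),
                   quadraticWell(c(1, 3)))
  for (s in surfaces) expect_gradient_consistent(s, n = 100)
})

test_that("double well has exact closed-form features", {
  dw <- doubleWell(h = 5, c = 1)
  expect_identical(energy(dw, c(0, 0)) - energy(dw, c(1, 0)), 5)
  expect_identical(energy(dw, c(-1, 0)), energy(dw, c(1, 0)))
  expect_identical(energy(dw, c(1, 0)), 0)
  expect_equal(energyGradient(dw, c(0, 0)), c(0, 0))
  expect_error(doubleWell(h = -1), "h must be")
  expect_error(doubleWell(h = 5, c = 0), "c must be")
})

test_that("Mueller-Brown stationary points match the grid-search + Newton oracle", {
  mb <- mullerBrown()
  # coarse grid scan locates the basins, Newton refines them
  gx <- seq(-1.6, 1.2, by = 0.05)
  gy <- seq(-0.4, 2.2, by = 0.05)
  E <- outer(gx, gy, Vectorize(function(x, y) energy(mb, c(x, y))))
  imin <- arrayInd(which.min(E), dim(E))
  deep <- refineStationary(mb, c(gx[imin[1]], gy[imin[2]]))
  expect_lt(deep$gradientNorm, 1e-6)
  expect_equal(deep$energy, -146.6995, tolerance = 1e-6)
  expect_equal(deep$x, c(-0.558224, 1.441726), tolerance = 1e-4)
  expect_true(all(deep$hessianEigenvalues > 0))

  second <- refineStationary(mb, c(0.6, 0.0))
  expect_equal(second$energy, -108.16672, tolerance = 1e-6)

  sad <- refineStationary(mb, c(0.2, 0.3))
  expect_lt(sad$gradientNorm, 1e-6)
  expect_equal(sad$x, c(0.212487, 0.292988), tolerance = 1e-4)
  expect_identical(sum(sad$hessianEigenvalues < 0), 1L)
})

test_that("proton relay spine reproduces the prescribed stationary values exactly", {
  spec <- gacProfileValues()
  pr <- protonRelaySurface(6, spec)
  sp <- relaySpine(pr, s = seq_along(spec) - 1)
  expect_equal(sp$G, unname(spec), tolerance = 1e-12)
  # stationary: gradient vanishes at every knot
  for (m in seq_along(spec))
    expect_lt(abs(energyGradient(pr, c(m - 1, rep(0, 5)))[1]), 1e-10)
  # dense evaluation: no extrema beyond the prescribed ones
  dense <- relaySpine(pr)
  nmax <- sum(diff(sign(diff(dense$G))) == -2)
  nmin <- sum(diff(sign(diff(dense$G))) == 2)
  expect_identical(nmax, 4L)
  expect_identical(nmin, 3L)
})

test_that("proton relay validates its barrier specification", {
  expect_error(protonRelaySurface(6, c(0, 5, 6, 3, 2)), "alternate")
  expect_error(protonRelaySurface(6, c(0, 5, 3, 8)), "minima")
  expect_error(protonRelaySurface(1), "nCV")
  # flat spec is the degenerate no-barrier case
  flat <- protonRelaySurface(2, c(0, 0, 0))
  expect_identical(energy(flat, c(0.7, 0)), 0)
})

test_that("brute-force oracle recovers the analytic double-well MEP", {
  dw <- doubleWell(h = 5, c = 1)
  ref <- bruteForceMEP(dw, c(-1, 0), c(1, 0), resolution = 0.02)
  expect_lt(max(abs(ref@points[, 2])), 0.02)
  expect_equal(max(ref@energies), 5, tolerance = 1e-3)
  expect_identical(length(ref@saddleIndices), 1L)
  expect_lt(abs(ref@points[ref@saddleIndices, 1]), 0.02)
  # uniform spacing after construction
  seg <- sqrt(rowSums(diff(ref@points)^2))
  expect_lt((max(seg) - min(seg)) / mean(seg), 1e-8)
})

test_that("brute-force oracle is symmetric under endpoint reversal", {
  dw <- doubleWell(h = 3, c = 2)
  f <- bruteForceMEP(dw, c(-1, 0), c(1, 0), resolution = 0.02, nPoints = 51)
  r <- bruteForceMEP(dw, c(1, 0), c(-1, 0), resolution = 0.02, nPoints = 51)
  expect_lt(max(distanceToPath(f, r@points)), 0.02)
})

test_that("coincident endpoints give a single-point, zero-length path", {
  dw <- doubleWell()
  ref <- bruteForceMEP(dw, c(0.5, 0.1), c(0.5, 0.1))
  expect_identical(nrow(ref@points), 1L)
  expect_identical(ref@saddleIndices, integer(0))
})

test_that("surface registry round-trips serializable descriptions", {
  for (s in list(mullerBrown(), doubleWell(3, 2),
                 protonRelaySurface(4, sacProfileValues()),
                 quadraticWell(c(2, 5)))) {
    spec <- surfaceSpec(s)
    s2 <- buildSurface(spec$name, spec$parameters)
    x <- (s@domain[1, ] + s@domain[2, ]) / 2
    expect_identical(energy(s2, x), energy(s, x))
  }
  expect_error(buildSurface("nope"), "unknown surface")
})
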