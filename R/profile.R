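#' @include AllClasses.R string.R
NULL

#' Integrate the free-energy profile along a string
#'
#' G(alpha) = G(0) + integral of sum_i (dz_i/dalpha)(dG/dz_i) dalpha.
#' Both dz_i/dalpha and dG/dz_i are interpolated over alpha by natural
#' cubic splines through the image values, and the tangential integrand is
#' integrated with the trapezoidal rule on a dense grid (default 75 points
#' inclusive of both endpoints).  G is reported relative to alpha = 0.
#'
#' @param path a converged \code{\linkS4class{StringPath}}.
#' @param estimates per-image list of \code{\linkS4class{MeanForceEstimate}}.
#' @param nGrid number of grid points covering [0, 1] inclusive.
#' @return a \code{\linkS4class{FreeEnergyProfile}}.
#' @export
integrateProfile <- function(path, estimates, nGrid = 75L) {
  stopifnot(is(path, "StringPath"))
  R <- nrow(path@images); N <- ncol(path@images)
  if (length(estimates) != R)
    stop("need one mean-force estimate per image")
  if (R < 4L) stop("cubic splines need at least 4 images")
  a <- path@alphas
  grid <- seq(0, 1, length.out = nGrid)
  integrand <- numeric(nGrid)
  gmat <- vapply(estimates, function(e) e@gradient, numeric(N))
  gmat <- matrix(gmat, nrow = N)  # N x R
  for (i in seq_len(N)) {
    zi <- splinefun(a, path@images[, i], method = "natural")
    gi <- splinefun(a, gmat[i, ], method = "natural")
    integrand <- integrand + zi(grid, deriv = 1) * gi(grid)
  }
  G <- as.numeric(cumtrapz(grid, integrand))
  G <- G - G[1]
  G[1] <- 0
  new("FreeEnergyProfile", alphaGrid = grid, G = G,
      stderr = numeric(nGrid), sourceCycles = path@cycle)
}

#' Pointwise uncertainty across trailing-cycle profiles
#'
#' Combines free-energy profiles from trailing optimization cycles into
#' their mean with the per-point standard deviation attached -- the
#' standard error recipe of averaging the profiles of the last cycles
#' after convergence.
#'
#' @param profiles list of \code{\linkS4class{FreeEnergyProfile}} objects
#'   on a common alpha grid (at least 2).
#' @return a \code{\linkS4class{FreeEnergyProfile}} holding the mean G and
#'   pointwise SD in \code{stderr}.
#' @export
profileUncertainty <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  grid <- profiles[[1]]@alphaGrid
  for (p in profiles)
    if (!isTRUE(all.equal(p@alphaGrid, grid, tolerance = 1e-12)))
      stop("profiles are on mismatched grids")
  Gs <- vapply(profiles, profileG, numeric(length(grid)))
  G <- rowMeans(Gs)
  G <- G - G[1]; G[1] <- 0
  new("FreeEnergyProfile", alphaGrid = grid, G = G,
      stderr = apply(Gs, 1, sd),
      sourceCycles = as.integer(unlist(lapply(profiles,
                                              function(p) p@sourceCycles))))
}

#' Profile of the mean over the trailing cycles of an optimization
#'
#' Integrates one profile per trailing cycle (path + that cycle's
#' mean-force estimates) and pools them with
#' \code{\link{profileUncertainty}}.
#'
#' @param opt a \code{\linkS4class{StringOptimization}}.
#' @param lastCycles how many trailing cycles to pool (default 10).
#' @param nGrid integration grid size.
#' @return a \code{\linkS4class{FreeEnergyProfile}} with pointwise SDs.
#' @export
trailingProfile <- function(opt, lastCycles = 10L, nGrid = 75L) {
  stopifnot(is(opt, "StringOptimization"))
  nc <- length(opt@cyclePaths)
  idx <- seq.int(max(1L, nc - lastCycles + 1L), nc)
  if (length(idx) < 2L) stop("need at least 2 trailing cycles")
  profiles <- lapply(idx, function(cyc)
    integrateProfile(opt@cyclePaths[[cyc]], opt@estimates[[cyc]], nGrid))
  profileUncertainty(profiles)
}

#' Locate and classify stationary states along a profile
#'
#' Interior local maxima become transition states (TS1, TS2, ...), interior
#' local minima intermediates (IM1, ...); the endpoints are the reactant
#' (RC, alpha = 0) and product (PC, alpha = 1) complexes.  Adjacent
#' extremum pairs whose free-energy separation falls below a prominence
#' threshold (default 2 x the local pointwise SD) are treated as noise
#' wiggles and suppressed.
#'
#' @param profile a \code{\linkS4class{FreeEnergyProfile}}.
#' @param path optional \code{\linkS4class{StringPath}}; when given, CV
#'   values at each state are interpolated by cubic splines and appended
#'   as columns.
#' @param cvNames column names for the interpolated CV values.
#' @param prominence threshold multiplier on the local stderr.
#' @return data.frame with columns label, alpha, G, stderr (and CV columns
#'   when \code{path} is supplied).
#' @export
locateStationaryStates <- function(profile, path = NULL, cvNames = NULL,
                                   prominence = 2) {
  stopifnot(is(profile, "FreeEnergyProfile"))
  a <- profile@alphaGrid; G <- profile@G; se <- profile@stderr
  n <- length(G)
  if (!n) stop("empty profile")
  d <- diff(G)
  idx <- integer(0); kind <- character(0)
  for (i in 2:(n - 1)) {
    if (d[i - 1] > 0 && d[i] < 0) { idx <- c(idx, i); kind <- c(kind, "max") }
    if (d[i - 1] < 0 && d[i] > 0) { idx <- c(idx, i); kind <- c(kind, "min") }
  }
  # prominence pruning: an extremum whose free-energy separation from both
  # flanking stationary values (neighbouring extrema or the endpoints)
  # falls below `prominence` x its local stderr is a noise wiggle; remove
  # it together with its closer opposite-kind neighbour so the sequence
  # stays alternating
  repeat {
    if (!length(idx)) break
    flank <- c(G[1], G[idx], G[n])
    m <- length(idx)
    prom <- pmin(abs(G[idx] - flank[seq_len(m)]),
                 abs(G[idx] - flank[seq_len(m) + 2L]))
    thr <- prominence * se[idx]
    bad <- which(prom < thr)
    if (!length(bad)) break
    j <- bad[which.min((prom / pmax(thr, 1e-300))[bad])]
    # cancel the wiggle against whichever flanking stationary value is
    # closest in G; when that is an endpoint, the wiggle goes alone
    dl <- if (j > 1L) abs(G[idx[j]] - G[idx[j - 1L]]) else
      abs(G[idx[j]] - G[1])
    dr <- if (j < m) abs(G[idx[j]] - G[idx[j + 1L]]) else
      abs(G[idx[j]] - G[n])
    drop <- if (dl <= dr) {
      if (j > 1L) c(j - 1L, j) else j
    } else {
      if (j < m) c(j, j + 1L) else j
    }
    idx <- idx[-drop]; kind <- kind[-drop]
    # merge any same-kind neighbours left behind, keeping the more extreme
    while (length(idx) > 1L &&
           any(same <- kind[-1] == kind[-length(kind)])) {
      i2 <- which(same)[1] + 1L
      drop2 <- if (kind[i2] == "max") {
        if (G[idx[i2]] >= G[idx[i2 - 1L]]) i2 - 1L else i2
      } else {
        if (G[idx[i2]] <= G[idx[i2 - 1L]]) i2 - 1L else i2
      }
      idx <- idx[-drop2]; kind <- kind[-drop2]
    }
  }
  labs <- character(length(idx))
  labs[kind == "max"] <- paste0("TS", seq_len(sum(kind == "max")))
  labs[kind == "min"] <- paste0("IM", seq_len(sum(kind == "min")))
  states <- data.frame(
    label = c("RC", labs, "PC"),
    alpha = c(a[1], a[idx], a[n]),
    G = c(G[1], G[idx], G[n]),
    stderr = c(se[1], se[idx], se[n]),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    N <- ncol(path@images)
    if (is.null(cvNames)) cvNames <- colnames(path@images)
    if (is.null(cvNames)) cvNames <- sprintf("cv_%d", seq_len(N))
    for (i in seq_len(N)) {
      zi <- splinefun(path@alphas, path@images[, i], method = "natural")
      states[[cvNames[i]]] <- zi(states$alpha)
    }
  }
  states
}

#' Free-energy barrier from a first-order rate constant (Eyring)
#'
#' Transition-state theory inversion of k = (kB T / h) exp(-dG / RT):
#' dG = R T ln(kB T / (h k)), with CODATA constants, in kcal/mol.
#'
#' @param rate first-order rate constant, 1/s.
#' @param temperature absolute temperature, K (default 298.15).
#' @return activation free energy, kcal/mol.
#' @examples
#' eyringBarrier(0.2)    # ~18.4, an enzyme turning over in seconds
#' eyringBarrier(8e-8)   # ~27.1, the uncatalyzed solution reaction
#' @export
eyringBarrier <- function(rate, temperature = 298.15) {
  if (any(rate <= 0)) stop("rate must be > 0")
  if (any(temperature <= 0)) stop("temperature must be > 0")
  .R_kcal * temperature * log(.kB_J * temperature / (.h_J * rate))
}

#' First-order rate constant from a free-energy barrier (Eyring)
#'
#' @param barrier activation free energy, kcal/mol.
#' @param temperature absolute temperature, K.
#' @return rate constant, 1/s.
#' @export
eyringRate <- function(barrier, temperature = 298.15) {
  if (any(temperature <= 0)) stop("temperature must be > 0")
  .kB_J * temperature / .h_J * exp(-barrier / (.R_kcal * temperature))
}

#' Half-life of a first-order decay
#'
#' t1/2 = ln(2) / k, reported in seconds and days.
#'
#' @param rate first-order rate constant, 1/s.
#' @return list with \code{seconds} and \code{days}.
#' @examples
#' firstOrderHalfLife(0.2)$seconds   # ~3.5 s
#' firstOrderHalfLife(8e-8)$days     # ~100 days
#' @export
firstOrderHalfLife <- function(rate) {
  if (any(rate <= 0)) stop("rate must be > 0")
  s <- log(2) / rate
  list(seconds = s, days = s / 86400)
}
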