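#' @include AllClasses.R meanforce.R
NULL

#' Construct a string path
#'
#' @param images R x N matrix of CV values.
#' @param alphas parameter values in [0, 1]; default uniform.
#' @param cycle cycle index tag.
#' @return a \code{\linkS4class{StringPath}}.
#' @export
stringPath <- function(images, alphas = NULL, cycle = 0L) {
  images <- as.matrix(images)
  if (is.null(alphas)) alphas <- seq(0, 1, length.out = nrow(images))
  new("StringPath", images = images, alphas = as.numeric(alphas),
      cycle = as.integer(cycle))
}

#' Initialize a string by linear interpolation between two endpoints
#'
#' With R images the uniform image spacing is Delta alpha = 1/(R - 1).
#'
#' @param from,to CV vectors at alpha = 0 and alpha = 1.
#' @param R number of images (default 25).
#' @return a \code{\linkS4class{StringPath}}.
#' @examples
#' initString(c(-1, 0), c(1, 0), R = 25)
#' @export
initString <- function(from, to, R = 25L) {
  stopifnot(length(from) == length(to), R >= 2L)
  a <- seq(0, 1, length.out = R)
  stringPath(outer(1 - a, from) + outer(a, to), a)
}

#' Construct an optimization schedule
#'
#' Defaults mirror the standard protocol: 100 cycles of steepest descent
#' with scalar step 0.001, smoothing 0.01, and an RMSD convergence
#' tolerance of 0.01 CV units.
#'
#' @param nCycles number of cycles.
#' @param descentStep scalar steepest-descent step Delta t.
#' @param smoothing smoothing parameter s in [0, 0.5).
#' @param rmsdTolerance convergence tolerance (CV units).
#' @param sampler per-cycle \code{\linkS4class{SamplerConfig}}.
#' @param endpointMode "free" (default: endpoints relax downhill without
#'   projection, appropriate when the terminal states are free-energy
#'   minima) or "fixed".
#' @param maxStep per-image displacement cap per cycle; \code{NA} (default)
#'   selects 0.1 x the mean inter-image arc spacing each cycle.  Explicit
#'   steepest descent is only linearly stable where
#'   \code{descentStep * curvature < 2}; the cap bounds the excursion of
#'   images sitting in stiffer regions without altering the converged path.
#' @param meanForce "sampling" or "exact" (see
#'   \code{\linkS4class{OptimizationSchedule}}).
#' @param earlyStop stop early once converged.
#' @return an \code{\linkS4class{OptimizationSchedule}}.
#' @export
optimizationSchedule <- function(nCycles = 100L, descentStep = 0.001,
                                 smoothing = 0.01, rmsdTolerance = 0.01,
                                 sampler = samplerConfig(),
                                 endpointMode = "free", maxStep = NA_real_,
                                 meanForce = "sampling", earlyStop = FALSE)
  new("OptimizationSchedule", nCycles = as.integer(nCycles),
      descentStep = descentStep, smoothing = smoothing,
      rmsdTolerance = rmsdTolerance, sampler = sampler,
      endpointMode = endpointMode, maxStep = maxStep,
      meanForce = meanForce, earlyStop = earlyStop)

.weightedNorm <- function(v, w) sqrt(sum((w * v)^2))

#' Unit tangent of the string at an image
#'
#' Central finite difference over alpha for interior images, one-sided at
#' the endpoints, normalized in the weighted CV metric.
#'
#' @param path a \code{\linkS4class{StringPath}} with at least 3 images.
#' @param imageIndex image at which to evaluate.
#' @param weights per-CV arc-length weights.
#' @return unit tangent vector in CV space.
#' @export
pathTangent <- function(path, imageIndex, weights = 1) {
  stopifnot(is(path, "StringPath"))
  z <- path@images; a <- path@alphas; R <- nrow(z)
  if (R < 3L) stop("tangents require at least 3 images")
  i <- as.integer(imageIndex)
  t <- if (i == 1L) (z[2, ] - z[1, ]) / (a[2] - a[1])
       else if (i == R) (z[R, ] - z[R - 1, ]) / (a[R] - a[R - 1])
       else (z[i + 1, ] - z[i - 1, ]) / (a[i + 1] - a[i - 1])
  w <- rep_len(weights, ncol(z))
  n <- .weightedNorm(t, w)
  if (n < 1e-14) stop("degenerate tangent: adjacent images coincide")
  t / n
}

#' Evolve one image by metric-scaled projected steepest descent
#'
#' The update is z' = z + descentStep * P[M (-gradient)], where the
#' projector P = I - t t^T removes the component along the unit tangent so
#' only the orthogonal mean force drives the image; passing
#' \code{project = FALSE} (used for free endpoints) applies the full
#' downhill update.
#'
#' @param z CV vector of the image.
#' @param estimate a \code{\linkS4class{MeanForceEstimate}} at the image.
#' @param tangent unit tangent (weighted metric) at the image.
#' @param descentStep scalar step Delta t.
#' @param project remove the tangential component (default TRUE).
#' @param weights per-CV arc-length weights.
#' @return updated CV vector.
#' @export
evolveImage <- function(z, estimate, tangent, descentStep, project = TRUE,
                        weights = 1) {
  stopifnot(is(estimate, "MeanForceEstimate"))
  if (!all(is.finite(estimate@gradient))) stop("non-finite gradient")
  disp <- descentStep * as.vector(estimate@metric %*% (-estimate@gradient))
  if (project) {
    w2 <- rep_len(weights, length(z))^2
    disp <- disp - tangent * sum(w2 * disp * tangent)
  }
  z + disp
}

#' Smooth a string among adjacent images
#'
#' Interior images are replaced by
#' (1 - s) z_r + (s/2)(z_{r-1} + z_{r+1}); endpoints are unchanged.
#'
#' @param path a \code{\linkS4class{StringPath}}.
#' @param s smoothing parameter in [0, 0.5).
#' @return smoothed \code{\linkS4class{StringPath}}.
#' @export
smoothPath <- function(path, s = 0.01) {
  stopifnot(is(path, "StringPath"), s >= 0, s < 0.5)
  z <- path@images; R <- nrow(z)
  if (R > 2L && s > 0) {
    interior <- 2:(R - 1)
    z[interior, ] <- (1 - s) * z[interior, ] +
      s / 2 * (z[interior - 1, ] + z[interior + 1, ])
  }
  stringPath(z, path@alphas, path@cycle)
}

.arcLengths <- function(z, w) {
  dz <- diff(z)
  sqrt(rowSums(sweep(dz, 2, w, `*`)^2))
}

#' Reparametrize a string to equal arc length
#'
#' Images are redistributed by piecewise-linear interpolation along the
#' polyline so that consecutive weighted-Euclidean arc lengths are equal
#' (iterated to a relative spread below \code{tol}); endpoints are
#' preserved exactly and alpha values become uniform with
#' Delta alpha = 1/(R - 1).
#'
#' @param path a \code{\linkS4class{StringPath}}.
#' @param weights per-CV arc-length weights.
#' @param tol relative arc-length uniformity tolerance.
#' @param maxIter safety cap on interpolation passes.
#' @return reparametrized \code{\linkS4class{StringPath}}.
#' @export
reparametrize <- function(path, weights = 1, tol = 1e-10, maxIter = 100L) {
  stopifnot(is(path, "StringPath"))
  z <- path@images; R <- nrow(z)
  w <- rep_len(weights, ncol(z))
  if (R < 3L) return(stringPath(z, seq(0, 1, length.out = R), path@cycle))
  for (it in seq_len(maxIter)) {
    seg <- .arcLengths(z, w)
    L <- sum(seg)
    if (L <= 0) stop("zero-length path cannot be reparametrized")
    spread <- (max(seg) - min(seg)) / (L / (R - 1))
    if (spread <= tol) break
    cum <- c(0, cumsum(seg))
    targets <- seq(0, L, length.out = R)
    zNew <- z
    j <- 1L
    for (i in 2:(R - 1)) {
      tgt <- targets[i]
      while (j < R - 1L && cum[j + 1L] < tgt) j <- j + 1L
      frac <- (tgt - cum[j]) / (cum[j + 1L] - cum[j])
      zNew[i, ] <- z[j, ] + frac * (z[j + 1L, ] - z[j, ])
    }
    z <- zNew
  }
  stringPath(z, seq(0, 1, length.out = R), path@cycle)
}

#' RMSD between two string paths
#'
#' Square root of the mean squared per-CV, per-image difference.
#'
#' @param a,b \code{\linkS4class{StringPath}} objects of equal shape.
#' @return scalar RMSD in CV units.
#' @export
pathRMSD <- function(a, b) {
  stopifnot(is(a, "StringPath"), is(b, "StringPath"))
  if (!identical(dim(a@images), dim(b@images)))
    stop("paths have different shapes")
  sqrt(mean((a@images - b@images)^2))
}

# deterministic per-(cycle, image) seed table derived from the master seed
.seedTable <- function(masterSeed, nCycles, R) {
  set.seed(masterSeed)
  matrix(sample.int(.Machine$integer.max - 1L, nCycles * R), nCycles, R)
}

#' Optimize a string to the minimum free energy path
#'
#' Runs the full per-cycle protocol: restrained sampling at every image
#' (warm-started from the previous cycle), mean-force and metric
#' estimation, metric-scaled projected steepest descent, smoothing, and
#' equal-arc-length reparametrization; convergence is recorded both
#' prospectively (consecutive-cycle RMSD) and retrospectively (RMSD
#' against the final path).  All per-(cycle, image) sampler seeds derive
#' deterministically from \code{masterSeed}, so runs are exactly
#' reproducible and any single image trajectory can be re-run in
#' isolation.
#'
#' In \code{meanForce = "exact"} mode (identity CVs spanning all surface
#' coordinates) the sampler is bypassed and the exact surface gradient
#' serves as the mean force with an identity metric -- the zero-temperature,
#' infinitely-stiff-restraint limit of the estimator.
#'
#' @param initial starting \code{\linkS4class{StringPath}}.
#' @param surface the \code{\linkS4class{PotentialSurface}}.
#' @param cvset the string's \code{\linkS4class{CVSet}}.
#' @param k harmonic restraint force constant(s).
#' @param schedule an \code{\linkS4class{OptimizationSchedule}}.
#' @param masterSeed master RNG seed.
#' @param x0 optional R x d matrix of initial configurations (one per
#'   image); defaults to the image CV values when the CV set is the
#'   identity map over all coordinates.
#' @param monitors optional monitored-coordinate \code{\linkS4class{CVSet}}
#'   recorded during the final cycle's sampling.
#' @param verbose print per-cycle progress (key=value lines).
#' @return a \code{\linkS4class{StringOptimization}}.
#' @export
optimizeString <- function(initial, surface, cvset, k = 100,
                           schedule = optimizationSchedule(),
                           masterSeed = 1L, x0 = NULL, monitors = NULL,
                           verbose = FALSE) {
  stopifnot(is(initial, "StringPath"), is(surface, "PotentialSurface"),
            is(cvset, "CVSet"), is(schedule, "OptimizationSchedule"))
  R <- nrow(initial@images); N <- ncol(initial@images)
  if (N != nCVs(cvset)) stop("path width does not match CV count")
  w <- cvWeights(cvset)
  exact <- schedule@meanForce == "exact"
  if (exact) {
    kinds <- vapply(cvset@cvs, function(cv) cv@kind, character(1))
    if (!all(kinds == "identity") || N != surface@dimension)
      stop("exact mean forces require identity CVs over all coordinates")
  }
  lo <- surface@domain[1, ]; hi <- surface@domain[2, ]
  if (any(initial@images[c(1, R), ] < matrix(lo, 2, N, byrow = TRUE)) ||
      any(initial@images[c(1, R), ] > matrix(hi, 2, N, byrow = TRUE)))
    stop("initial path endpoints outside the surface domain")

  seeds <- .seedTable(masterSeed, schedule@nCycles, R)
  path <- reparametrize(initial, w)
  if (!exact) {
    if (is.null(x0)) {
      eng <- .cvEngine(cvset, surface@dimension)
      if (is.null(eng$identityIdx) || N != surface@dimension)
        stop("x0 must be supplied unless the CV set is the identity map")
      x0 <- path@images[, order(eng$identityIdx), drop = FALSE]
    }
    x0 <- as.matrix(x0)
    if (!identical(dim(x0), c(R, surface@dimension)))
      stop("x0 must be an R x dimension matrix")
  }
  configs <- x0

  cyclePaths <- vector("list", schedule@nCycles)
  estimatesAll <- vector("list", schedule@nCycles)
  rmsdStep <- numeric(0)
  lastStats <- list()
  nDone <- 0L

  for (cyc in seq_len(schedule@nCycles)) {
    ests <- vector("list", R)
    stats <- if (!exact) vector("list", R)
    wantMon <- !is.null(monitors) && cyc == schedule@nCycles
    for (r in seq_len(R)) {
      z <- path@images[r, ]
      if (exact) {
        ests[[r]] <- new("MeanForceEstimate",
                         gradient = as.numeric(surface@gradFunc(z)),
                         metric = diag(N), standardError = numeric(N),
                         imageIndex = as.integer(r))
      } else {
        spec <- restraintSpec(z, k)
        cfg <- schedule@sampler
        cfg@seed <- seeds[cyc, r]
        st <- runRestrained(surface, cvset, spec, cfg, configs[r, ],
                            monitors = if (wantMon) monitors)
        configs[r, ] <- st@finalConfiguration
        stats[[r]] <- st
        ests[[r]] <- estimateGradient(st, spec, r)
      }
    }
    # evolve -> smooth -> reparametrize
    zNew <- path@images
    seg <- .arcLengths(path@images, w)
    cap <- if (is.na(schedule@maxStep)) 0.1 * mean(seg) else schedule@maxStep
    for (r in seq_len(R)) {
      endp <- r == 1L || r == R
      if (endp && schedule@endpointMode == "fixed") next
      tv <- if (!endp) pathTangent(path, r, w)
      zp <- evolveImage(path@images[r, ], ests[[r]],
                        if (endp) NULL else tv,
                        schedule@descentStep, project = !endp, weights = w)
      disp <- zp - path@images[r, ]
      dn <- .weightedNorm(disp, w)
      if (is.finite(cap) && dn > cap) disp <- disp * (cap / dn)
      zNew[r, ] <- path@images[r, ] + disp
    }
    newPath <- stringPath(zNew, path@alphas, cyc)
    newPath <- smoothPath(newPath, schedule@smoothing)
    newPath <- reparametrize(newPath, w)
    newPath@cycle <- as.integer(cyc)
    rmsdStep[cyc] <- pathRMSD(newPath, path)
    path <- newPath
    cyclePaths[[cyc]] <- path
    estimatesAll[[cyc]] <- ests
    if (!exact) lastStats <- stats
    nDone <- cyc
    if (verbose) {
      mg <- mean(vapply(ests, function(e) sqrt(mean(e@gradient^2)), numeric(1)))
      message(sprintf("cycle=%d rmsd_step=%.3g mean_rms_gradient=%.3g",
                      cyc, rmsdStep[cyc], mg))
    }
    if (schedule@earlyStop && cyc >= 5L &&
        all(rmsdStep[(cyc - 4L):cyc] < schedule@rmsdTolerance)) break
  }

  cyclePaths <- cyclePaths[seq_len(nDone)]
  estimatesAll <- estimatesAll[seq_len(nDone)]
  final <- cyclePaths[[nDone]]
  devs <- array(0, dim = c(nDone, R, N))
  rmsdFinal <- numeric(nDone)
  for (cyc in seq_len(nDone)) {
    devs[cyc, , ] <- cyclePaths[[cyc]]@images - final@images
    rmsdFinal[cyc] <- sqrt(mean(devs[cyc, , ]^2))
  }
  if (nDone >= 30L) {
    rs <- rmsdStep[seq_len(nDone)]
    early <- mean(head(rs, nDone %/% 4))
    lateM <- mean(tail(rs, nDone %/% 4))
    if (lateM >= early && lateM > schedule@rmsdTolerance)
      warning("per-cycle string RMSD is not decreasing: possible stagnation")
  }

  new("StringOptimization", finalPath = final, cyclePaths = cyclePaths,
      estimates = estimatesAll,
      convergence = new("ConvergenceRecord", rmsdVsFinal = rmsdFinal,
                        rmsdStep = rmsdStep[seq_len(nDone)],
                        deviations = devs),
      lastStats = if (exact) list() else lastStats,
      masterSeed = as.integer(masterSeed))
}

#' Total sampling budget of a string protocol
#'
#' Protocol arithmetic: \code{psPerImage} picoseconds of sampling per image
#' per cycle, times images, times cycles.  The standard protocol
#' (20 ps x 25 images x 100 cycles) totals 50 ns; with R images the
#' uniform spacing is Delta alpha = 1/(R - 1).
#'
#' @param psPerImage sampling per image per cycle, picoseconds.
#' @param images number of images R.
#' @param cycles number of optimization cycles.
#' @return list with \code{totalPs}, \code{totalNs} and \code{deltaAlpha}.
#' @examples
#' samplingBudget()  # 50 ns, delta alpha = 1/24
#' @export
samplingBudget <- function(psPerImage = 20, images = 25L, cycles = 100L)
  list(totalPs = psPerImage * images * cycles,
       totalNs = psPerImage * images * cycles / 1000,
       deltaAlpha = 1 / (images - 1))
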