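#' @include AllClasses.R cv.R
NULL

#' Construct a sampler configuration
#'
#' Dynamics are overdamped Langevin (Euler-Maruyama):
#' \deqn{x' = x - \Delta t \, \nabla(V + U_{restraint})/\gamma +
#'   \sqrt{2 k_B T \Delta t/\gamma}\,\xi,}
#' whose stationary distribution approaches the Boltzmann weight
#' exp(-(V + U)/kBT) as the timestep shrinks.  The default burn-in discards
#' the first quarter of each trajectory, mirroring the convention of using
#' only the final three quarters of a per-cycle restrained run.
#'
#' @param temperature thermal energy kBT in the surface's energy units;
#'   0 gives noise-free steepest-descent relaxation.
#' @param friction damping gamma (inverse time units).
#' @param timestep integration step; must resolve the stiffest mode
#'   (timestep * (curvature + restraint k) / friction well below 2).
#' @param nStepsTotal total steps per trajectory.
#' @param nStepsBurnin discarded initial steps (default 25\% of total).
#' @param stride accumulate every stride-th post-burn-in step.
#' @param storeEvery if positive, keep every storeEvery-th post-burn-in
#'   configuration snapshot.
#' @param seed RNG seed making the trajectory bit-for-bit reproducible.
#' @return a \code{\linkS4class{SamplerConfig}}.
#' @export
samplerConfig <- function(temperature = 0.5925, friction = 1, timestep = 5e-4,
                          nStepsTotal = 2000L,
                          nStepsBurnin = as.integer(nStepsTotal %/% 4L),
                          stride = 1L, storeEvery = 0L, seed = 1L)
  new("SamplerConfig", temperature = temperature, friction = friction,
      timestep = timestep, nStepsTotal = as.integer(nStepsTotal),
      nStepsBurnin = as.integer(nStepsBurnin), stride = as.integer(stride),
      storeEvery = as.integer(storeEvery), seed = as.integer(seed))

#' Construct a harmonic restraint specification
#'
#' @param zRef per-CV reference values.
#' @param k per-CV force constants (recycled), energy / CV-unit^2.  The
#'   default 100 is stiff enough that restrained CV means track their
#'   references to within about 0.1 CV units on unit-curvature surfaces.
#' @return a \code{\linkS4class{RestraintSpec}}.
#' @export
restraintSpec <- function(zRef, k = 100)
  new("RestraintSpec", zRef = as.numeric(zRef),
      k = rep_len(as.numeric(k), length(zRef)))

#' Harmonic restraint energy and force on the collective variables
#'
#' Energy sum_i k_i (theta_i - z_i)^2 / 2; force on theta_i is
#' -k_i (theta_i - z_i).
#'
#' @param theta current CV values.
#' @param spec a \code{\linkS4class{RestraintSpec}}.
#' @return list(energy, force) with force per CV.
#' @examples
#' harmonicRestraint(0.1, restraintSpec(0, k = 100))  # energy 0.5, force -10
#' @export
harmonicRestraint <- function(theta, spec) {
  stopifnot(is(spec, "RestraintSpec"), length(theta) == length(spec@zRef))
  dtheta <- theta - spec@zRef
  list(energy = sum(spec@k * dtheta^2) / 2, force = -spec@k * dtheta)
}

#' Run a restrained overdamped-Langevin trajectory
#'
#' Evolves a configuration on V(x) + harmonic restraint(theta[x]) and
#' accumulates the time averages the mean-force and metric-tensor
#' estimators require: the per-CV deviation (zRef - theta) and the Gram
#' matrix of CV Cartesian gradients.  Accumulation uses only post-burn-in
#' samples.  Identical seeds and inputs reproduce identical output.
#'
#' @param surface a \code{\linkS4class{PotentialSurface}}.
#' @param cvset the restrained \code{\linkS4class{CVSet}}.
#' @param spec a \code{\linkS4class{RestraintSpec}} (one entry per CV).
#' @param config a \code{\linkS4class{SamplerConfig}}.
#' @param x0 initial configuration inside the surface domain.
#' @param monitors optional \code{\linkS4class{CVSet}} of monitored
#'   coordinates, recorded at every accumulated sample without affecting
#'   the dynamics.
#' @param nBlocks number of equal blocks for error estimation.
#' @return a \code{\linkS4class{TrajectoryStats}}.
#' @export
runRestrained <- function(surface, cvset, spec, config, x0, monitors = NULL,
                          nBlocks = 10L) {
  stopifnot(is(surface, "PotentialSurface"), is(cvset, "CVSet"),
            is(spec, "RestraintSpec"), is(config, "SamplerConfig"))
  d <- surface@dimension
  if (length(x0) != d) stop("x0 has wrong dimension")
  lo <- surface@domain[1, ]; hi <- surface@domain[2, ]
  if (any(x0 < lo | x0 > hi)) stop("x0 outside the surface domain")
  N <- nCVs(cvset)
  if (length(spec@zRef) != N) stop("restraint spec does not match CV count")

  eng <- .cvEngine(cvset, d)
  mon <- if (!is.null(monitors)) .cvEngine(monitors, d)
  gradF <- surface@gradFunc
  kvec <- spec@k; zRef <- spec@zRef
  dt <- config@timestep; gamma <- config@friction
  cdt <- dt / gamma
  nTot <- config@nStepsTotal; nBurn <- config@nStepsBurnin
  stride <- config@stride; storeEvery <- config@storeEvery

  set.seed(config@seed)
  noiseScale <- sqrt(2 * config@temperature * dt / gamma)
  # pre-generated noise keeps the loop lean and the run reproducible
  noise <- if (noiseScale > 0)
    matrix(rnorm(nTot * d) * noiseScale, nTot, d) else NULL

  nSamp <- length(seq.int(nBurn + 1L, nTot, by = stride))
  sumDev <- numeric(N)
  constJJ <- if (!is.null(eng$constJac)) tcrossprod(eng$constJac)
  sumJJ <- matrix(0, N, N)
  blockSize <- max(1L, nSamp %/% nBlocks)
  blockSums <- matrix(0, nBlocks, N)
  blockCounts <- integer(nBlocks)
  monMat <- if (!is.null(mon))
    matrix(NA_real_, nSamp, nCVs(monitors),
           dimnames = list(NULL, cvLabels(monitors)))
  nStore <- if (storeEvery > 0L) nSamp %/% storeEvery else 0L
  stored <- matrix(NA_real_, nStore, d)

  x <- as.numeric(x0)
  isamp <- 0L; istore <- 0L
  for (step in seq_len(nTot)) {
    th <- eng$eval(x)
    dev <- th - zRef
    f <- -gradF(x)
    if (!is.null(eng$identityIdx)) {
      f[eng$identityIdx] <- f[eng$identityIdx] - kvec * dev
    } else {
      J <- eng$jac(x)
      f <- f - as.vector(crossprod(J, kvec * dev))
    }
    x <- x + cdt * f
    if (!is.null(noise)) x <- x + noise[step, ]
    if (!all(is.finite(x)))
      stop("non-finite configuration at step ", step)
    if (any(x < lo) || any(x > hi))
      stop("trajectory left the surface domain at step ", step)
    if (step > nBurn && (step - nBurn - 1L) %% stride == 0L) {
      isamp <- isamp + 1L
      th <- eng$eval(x)
      dev <- zRef - th
      sumDev <- sumDev + dev
      if (is.null(constJJ)) {
        J <- eng$jac(x)
        sumJJ <- sumJJ + tcrossprod(J)
      }
      b <- min(nBlocks, 1L + (isamp - 1L) %/% blockSize)
      blockSums[b, ] <- blockSums[b, ] + dev
      blockCounts[b] <- blockCounts[b] + 1L
      if (!is.null(mon)) monMat[isamp, ] <- mon$eval(x)
      if (storeEvery > 0L && isamp %% storeEvery == 0L && istore < nStore) {
        istore <- istore + 1L
        stored[istore, ] <- x
      }
    }
  }

  gp <- if (!is.null(constJJ)) constJJ else sumJJ / isamp
  gp <- (gp + t(gp)) / 2
  ok <- blockCounts > 0L
  blockMeans <- blockSums[ok, , drop = FALSE] / blockCounts[ok]
  monList <- if (!is.null(mon))
    setNames(lapply(seq_len(ncol(monMat)), function(j) monMat[, j]),
             colnames(monMat)) else list()
  new("TrajectoryStats",
      meanDeviation = sumDev / isamp, gradientProducts = gp,
      nSamples = isamp, blockMeans = blockMeans,
      monitoredSamples = monList, finalConfiguration = x,
      storedConfigurations = stored[seq_len(istore), , drop = FALSE])
}
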