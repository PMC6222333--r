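#' @include AllClasses.R sampler.R
NULL

#' Define reactant and product basins as CV boxes
#'
#' Axis-aligned per-CV interval boxes.  The convenience form
#' \code{basinBoxes} centers boxes of half-width
#' \code{3 sqrt(kBT / k)} (the restrained equilibrium width) on the
#' reactant and product CV values.
#'
#' @param reactantLower,reactantUpper,productLower,productUpper per-CV
#'   bounds; the two boxes must be disjoint.
#' @param maxSteps trajectory step cap for committor shots.
#' @return a \code{\linkS4class{BasinDefinition}}.
#' @export
basinDefinition <- function(reactantLower, reactantUpper,
                            productLower, productUpper, maxSteps = 10000L)
  new("BasinDefinition",
      reactantLower = as.numeric(reactantLower),
      reactantUpper = as.numeric(reactantUpper),
      productLower = as.numeric(productLower),
      productUpper = as.numeric(productUpper),
      maxSteps = as.integer(maxSteps))

#' @rdname basinDefinition
#' @param rcCV,pcCV CV values of the reactant and product states.
#' @param halfWidth per-CV box half-width (default 3 sqrt(kBT/k)).
#' @param temperature,k thermal energy and restraint stiffness used for
#'   the default half-width.
#' @export
basinBoxes <- function(rcCV, pcCV, halfWidth = 3 * sqrt(temperature / k),
                       temperature = 0.5925, k = 100, maxSteps = 10000L) {
  hw <- rep_len(halfWidth, length(rcCV))
  basinDefinition(rcCV - hw, rcCV + hw, pcCV - hw, pcCV + hw, maxSteps)
}

#' Sample a restrained transition-state ensemble
#'
#' Runs a restrained trajectory anchored at the transition-state CV values
#' and returns thinned configuration snapshots for committor shooting.
#' The thinning interval defaults to ten times the restrained relaxation
#' time (in steps), so successive snapshots are effectively decorrelated.
#'
#' @param surface a \code{\linkS4class{PotentialSurface}}.
#' @param cvset the string's \code{\linkS4class{CVSet}}.
#' @param tsCV CV values at the transition state (e.g. a row of the
#'   stationary-state table).
#' @param k restraint force constant(s).
#' @param config a \code{\linkS4class{SamplerConfig}}; its step budget is
#'   expanded automatically if too short for the requested snapshot count.
#' @param nConfigs number of configurations to return.
#' @param x0 starting configuration (defaults to the TS CV values for
#'   identity CV sets).
#' @param thin snapshot thinning interval in steps.
#' @return nConfigs x dimension matrix of configurations.
#' @export
sampleTSEnsemble <- function(surface, cvset, tsCV, k = 100,
                             config = samplerConfig(), nConfigs = 10L,
                             x0 = NULL, thin = NULL) {
  tsCV <- as.numeric(tsCV)
  if (is.null(thin))
    thin <- max(1L, as.integer(ceiling(
      10 * config@friction / (mean(k) * config@timestep))))
  if (is.null(x0)) {
    eng <- .cvEngine(cvset, surface@dimension)
    if (is.null(eng$identityIdx))
      stop("x0 must be supplied for non-identity CV sets")
    x0 <- tsCV[order(eng$identityIdx)]
  }
  need <- config@nStepsBurnin + thin * nConfigs
  if (config@nStepsTotal < need) {
    config@nStepsTotal <- as.integer(need)
  }
  config@storeEvery <- as.integer(thin)
  stats <- runRestrained(surface, cvset, restraintSpec(tsCV, k), config, x0)
  cfgs <- stats@storedConfigurations
  if (nrow(cfgs) < nConfigs)
    stop("sampler returned fewer snapshots than requested")
  cfgs[seq_len(nConfigs), , drop = FALSE]
}

#' Estimate committor probabilities by unbiased shooting
#'
#' For each configuration, launches \code{nShots} unbiased (restraint-free)
#' overdamped-Langevin trajectories with fresh noise and records the
#' fraction that enter the product basin before the reactant basin.
#' Trajectories exceeding \code{maxSteps} are counted as unresolved and
#' excluded from pB.
#'
#' @param surface a \code{\linkS4class{PotentialSurface}}.
#' @param cvset CV set defining the basin coordinates.
#' @param configs matrix of starting configurations (one per row).
#' @param basins a \code{\linkS4class{BasinDefinition}}.
#' @param nShots trajectories per configuration.
#' @param config a \code{\linkS4class{SamplerConfig}} supplying
#'   temperature, friction, timestep and the base seed.
#' @param nBins histogram bin count for the pB distribution.
#' @return a \code{\linkS4class{CommittorResult}}.
#' @export
estimateCommittor <- function(surface, cvset, configs, basins, nShots = 200L,
                              config = samplerConfig(), nBins = 10L) {
  stopifnot(is(basins, "BasinDefinition"))
  configs <- as.matrix(configs)
  d <- surface@dimension
  if (ncol(configs) != d) stop("configurations have wrong dimension")
  if (nShots < 1L) stop("nShots must be >= 1")
  eng <- .cvEngine(cvset, d)
  gradF <- surface@gradFunc
  dt <- config@timestep; gamma <- config@friction
  cdt <- dt / gamma
  noiseScale <- sqrt(2 * config@temperature * dt / gamma)
  lo <- surface@domain[1, ]; hi <- surface@domain[2, ]
  rl <- basins@reactantLower; ru <- basins@reactantUpper
  pl <- basins@productLower; pu <- basins@productUpper
  maxSteps <- basins@maxSteps

  set.seed(config@seed)
  nCfg <- nrow(configs)
  pB <- numeric(nCfg)
  unresolved <- 0L
  for (ic in seq_len(nCfg)) {
    hitB <- 0L; resolved <- 0L
    for (shot in seq_len(nShots)) {
      x <- configs[ic, ]
      committed <- NA
      # noise drawn in chunks: most shots commit long before maxSteps
      chunk <- 512L
      noise <- matrix(rnorm(chunk * d) * noiseScale, chunk, d)
      irow <- 0L
      for (step in seq_len(maxSteps)) {
        irow <- irow + 1L
        if (irow > chunk) {
          noise <- matrix(rnorm(chunk * d) * noiseScale, chunk, d)
          irow <- 1L
        }
        x <- x - cdt * gradF(x) + noise[irow, ]
        if (any(x < lo) || any(x > hi))
          stop("committor trajectory left the surface domain")
        th <- eng$eval(x)
        if (all(th >= rl & th <= ru)) { committed <- FALSE; break }
        if (all(th >= pl & th <= pu)) { committed <- TRUE; break }
      }
      if (is.na(committed)) unresolved <- unresolved + 1L
      else {
        resolved <- resolved + 1L
        if (committed) hitB <- hitB + 1L
      }
    }
    if (resolved == 0L)
      stop("all trajectories unresolved for configuration ", ic,
           "; increase maxSteps")
    pB[ic] <- hitB / resolved
  }
  breaks <- seq(0, 1, length.out = nBins + 1L)
  counts <- as.integer(table(cut(pB, breaks, include.lowest = TRUE)))
  new("CommittorResult", pB = pB, nShots = as.integer(nShots),
      histBreaks = breaks, histCounts = counts,
      unresolvedFraction = unresolved / (nCfg * nShots))
}
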