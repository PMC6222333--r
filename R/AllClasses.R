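#' @include MFEPath-package.R
NULL

#' PotentialSurface: an analytic energy landscape with exact gradients
#'
#' Container for an analytic potential energy surface.  Energies are in
#' abstract kcal/mol-like units; coordinates are Cartesian-like.  The
#' gradient function must be exact (tests enforce consistency with central
#' finite differences).
#'
#' @slot name short identifier (e.g. \code{"muller_brown"}).
#' @slot dimension number of Cartesian-like coordinates.
#' @slot parameters named constants defining the functional form.
#' @slot domain 2 x dimension matrix of per-coordinate (lower, upper) bounds
#'   inside which the energy is finite.
#' @slot energyFunc function(x) -> scalar energy.
#' @slot gradFunc function(x) -> gradient vector of length \code{dimension}.
#' @exportClass PotentialSurface
setClass("PotentialSurface",
  representation(name = "character", dimension = "integer",
                 parameters = "list", domain = "matrix",
                 energyFunc = "function", gradFunc = "function"),
  validity = function(object) {
    msg <- character()
    if (object@dimension < 1L) msg <- c(msg, "dimension must be >= 1")
    if (!identical(dim(object@domain), c(2L, object@dimension)))
      msg <- c(msg, "domain must be a 2 x dimension matrix")
    else if (any(object@domain[1, ] >= object@domain[2, ]))
      msg <- c(msg, "domain lower bounds must be below upper bounds")
    if (length(msg)) msg else TRUE
  })

#' ReferencePath: an oracle path with energies and saddle indices
#'
#' Holds a ground-truth path computed independently of the string optimizer
#' (see \code{\link{bruteForceMEP}}).  Points are uniformly spaced along the
#' polyline after construction.
#'
#' @slot points matrix, one row per path point.
#' @slot energies energy at each point.
#' @slot saddleIndices indices of local energy maxima along the path.
#' @exportClass ReferencePath
setClass("ReferencePath",
  representation(points = "matrix", energies = "numeric",
                 saddleIndices = "integer"),
  validity = function(object) {
    if (nrow(object@points) != length(object@energies))
      return("points and energies must have matching lengths")
    TRUE
  })

#' CVDefinition: one collective variable
#'
#' A scalar function theta[x] of the configuration.  \code{kind} is one of
#' \code{"distance"} (between two atoms; indices are 1-based atom numbers,
#' coordinates are consecutive xyz triplets), \code{"dihedral"} (four atoms,
#' degrees on (-180, 180], IUPAC sign convention), or \code{"identity"}
#' (one raw coordinate; the index is the coordinate number).
#'
#' @slot kind "distance", "dihedral" or "identity".
#' @slot indices atom indices (distance/dihedral) or coordinate index
#'   (identity); must be distinct.
#' @slot weight positive scale factor used in the arc-length metric.
#' @slot label human-readable name.
#' @exportClass CVDefinition
setClass("CVDefinition",
  representation(kind = "character", indices = "integer",
                 weight = "numeric", label = "character"),
  validity = function(object) {
    msg <- character()
    need <- c(distance = 2L, dihedral = 4L, identity = 1L)
    if (!object@kind %in% names(need))
      msg <- c(msg, "kind must be distance, dihedral or identity")
    else if (length(object@indices) != need[[object@kind]])
      msg <- c(msg, sprintf("%s CV needs %d indices", object@kind, need[[object@kind]]))
    if (anyDuplicated(object@indices)) msg <- c(msg, "indices must be distinct")
    if (any(object@indices < 1L)) msg <- c(msg, "indices must be positive")
    if (length(object@weight) != 1L || object@weight <= 0)
      msg <- c(msg, "weight must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' CVSet: an ordered set of collective variables
#'
#' @slot cvs list of \code{\linkS4class{CVDefinition}} with unique labels.
#' @exportClass CVSet
setClass("CVSet", representation(cvs = "list"),
  validity = function(object) {
    if (!length(object@cvs)) return("CVSet must contain at least one CV")
    if (!all(vapply(object@cvs, is, logical(1), "CVDefinition")))
      return("all elements must be CVDefinition objects")
    labs <- vapply(object@cvs, function(cv) cv@label, character(1))
    if (anyDuplicated(labs)) return("CV labels must be unique")
    TRUE
  })

#' SamplerConfig: settings for the restrained Langevin sampler
#'
#' @slot temperature thermal energy kBT in the surface's energy units
#'   (0 gives deterministic steepest-descent relaxation).
#' @slot friction damping coefficient gamma (inverse time).
#' @slot timestep integration step.
#' @slot nStepsTotal total number of steps.
#' @slot nStepsBurnin steps discarded before accumulation
#'   (default one quarter of the trajectory).
#' @slot stride sampling stride for the accumulators (1 = every step).
#' @slot storeEvery if > 0, keep every storeEvery-th post-burn-in
#'   configuration (for committor seeding).
#' @slot seed RNG seed.
#' @exportClass SamplerConfig
setClass("SamplerConfig",
  representation(temperature = "numeric", friction = "numeric",
                 timestep = "numeric", nStepsTotal = "integer",
                 nStepsBurnin = "integer", stride = "integer",
                 storeEvery = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@temperature < 0) msg <- c(msg, "temperature must be >= 0")
    if (object@friction <= 0) msg <- c(msg, "friction must be > 0")
    if (object@timestep <= 0) msg <- c(msg, "timestep must be > 0")
    if (object@nStepsBurnin < 0L || object@nStepsBurnin >= object@nStepsTotal)
      msg <- c(msg, "need 0 <= nStepsBurnin < nStepsTotal")
    if (object@stride < 1L) msg <- c(msg, "stride must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' RestraintSpec: harmonic anchors for the collective variables
#'
#' @slot zRef per-CV reference values at which each CV is restrained.
#' @slot k per-CV harmonic force constants (energy / CV-unit^2), all > 0.
#' @exportClass RestraintSpec
setClass("RestraintSpec",
  representation(zRef = "numeric", k = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@zRef) != length(object@k))
      msg <- c(msg, "zRef and k must have the same length")
    if (any(object@k <= 0)) msg <- c(msg, "force constants must be > 0")
    if (length(msg)) msg else TRUE
  })

#' TrajectoryStats: accumulators from one restrained trajectory
#'
#' Time averages over the post-burn-in samples of one restrained run:
#' the per-CV deviation (zRef - theta), the Gram matrix of CV Cartesian
#' gradients, block means of the deviation for error estimation, monitored
#' coordinate series, and configuration snapshots.
#'
#' @slot meanDeviation per-CV time average of (zRef - theta[x(t)]).
#' @slot gradientProducts N x N time average of
#'   sum_k (dtheta_i/dx_k)(dtheta_j/dx_k); symmetric.
#' @slot nSamples number of accumulated samples.
#' @slot blockMeans nBlocks x N matrix of per-block deviation means.
#' @slot monitoredSamples named list of per-sample monitored coordinate values.
#' @slot finalConfiguration last configuration (warm start for the next cycle).
#' @slot storedConfigurations thinned configuration snapshots (possibly 0 rows).
#' @exportClass TrajectoryStats
setClass("TrajectoryStats",
  representation(meanDeviation = "numeric", gradientProducts = "matrix",
                 nSamples = "integer", blockMeans = "matrix",
                 monitoredSamples = "list", finalConfiguration = "numeric",
                 storedConfigurations = "matrix"),
  validity = function(object) {
    gp <- object@gradientProducts
    if (nrow(gp) != ncol(gp)) return("gradientProducts must be square")
    if (max(abs(gp - t(gp))) > 1e-8 * max(1, max(abs(gp))))
      return("gradientProducts must be symmetric")
    TRUE
  })

#' MeanForceEstimate: free-energy gradient and metric tensor at one image
#'
#' @slot gradient per-CV estimate of dG/dz_i.
#' @slot metric N x N metric tensor M (symmetric, PSD to tolerance).
#' @slot standardError per-CV standard error of the gradient (block averaging).
#' @slot imageIndex which image the estimate belongs to.
#' @exportClass MeanForceEstimate
setClass("MeanForceEstimate",
  representation(gradient = "numeric", metric = "matrix",
                 standardError = "numeric", imageIndex = "integer"),
  validity = function(object) {
    M <- object@metric
    if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M))))
      return("metric must be symmetric")
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(1, max(abs(ev))))
      return("metric must be positive semidefinite to tolerance")
    TRUE
  })

#' StringPath: a discretized string of images in CV space
#'
#' @slot images R x N matrix of CV values z[alpha].
#' @slot alphas R strictly increasing values from 0 to 1.
#' @slot cycle optimization cycle the path belongs to.
#' @exportClass StringPath
setClass("StringPath",
  representation(images = "matrix", alphas = "numeric", cycle = "integer"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@images) != length(object@alphas))
      msg <- c(msg, "one alpha per image required")
    a <- object@alphas
    if (length(a) >= 2 &&
        (abs(a[1]) > 1e-12 || abs(a[length(a)] - 1) > 1e-12 || any(diff(a) <= 0)))
      msg <- c(msg, "alphas must increase strictly from 0 to 1")
    if (length(msg)) msg else TRUE
  })

#' OptimizationSchedule: the per-cycle string protocol
#'
#' Defaults follow the standard protocol: 100 cycles, steepest-descent step
#' 0.001, smoothing 0.01, convergence RMSD tolerance 0.01 CV units.
#'
#' @slot nCycles number of optimization cycles.
#' @slot descentStep scalar steepest-descent time step (Delta t).
#' @slot smoothing smoothing parameter s in [0, 0.5).
#' @slot rmsdTolerance convergence tolerance in CV units.
#' @slot sampler per-cycle \code{\linkS4class{SamplerConfig}}.
#' @slot endpointMode "free" (unprojected downhill updates) or "fixed".
#' @slot maxStep per-image per-cycle displacement cap; \code{NA} selects
#'   0.1 x mean inter-image arc spacing (trust-region style stabilization).
#' @slot meanForce "sampling" (restrained trajectories) or "exact"
#'   (analytic surface gradients; identity CVs only, the k -> Inf, T -> 0
#'   limit of the estimator).
#' @slot earlyStop stop once the trailing-window consecutive-cycle RMSD
#'   falls below rmsdTolerance.
#' @exportClass OptimizationSchedule
setClass("OptimizationSchedule",
  representation(nCycles = "integer", descentStep = "numeric",
                 smoothing = "numeric", rmsdTolerance = "numeric",
                 sampler = "SamplerConfig", endpointMode = "character",
                 maxStep = "numeric", meanForce = "character",
                 earlyStop = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@smoothing < 0 || object@smoothing >= 0.5)
      msg <- c(msg, "smoothing must be in [0, 0.5)")
    if (object@descentStep <= 0) msg <- c(msg, "descentStep must be > 0")
    if (!object@endpointMode %in% c("free", "fixed"))
      msg <- c(msg, "endpointMode must be 'free' or 'fixed'")
    if (!object@meanForce %in% c("sampling", "exact"))
      msg <- c(msg, "meanForce must be 'sampling' or 'exact'")
    if (length(msg)) msg else TRUE
  })

#' ConvergenceRecord: retrospective convergence diagnostics
#'
#' @slot rmsdVsFinal per-cycle RMSD against the final path (last entry 0).
#' @slot rmsdStep RMSD between consecutive cycles.
#' @slot deviations nCycles x R x N array of per-cycle, per-image, per-CV
#'   deviations from the final path.
#' @exportClass ConvergenceRecord
setClass("ConvergenceRecord",
  representation(rmsdVsFinal = "numeric", rmsdStep = "numeric",
                 deviations = "array"))

#' StringOptimization: full result of a string optimization
#'
#' @slot finalPath converged \code{\linkS4class{StringPath}}.
#' @slot cyclePaths per-cycle paths (list of StringPath).
#' @slot estimates per-cycle lists of \code{\linkS4class{MeanForceEstimate}}.
#' @slot convergence \code{\linkS4class{ConvergenceRecord}}.
#' @slot lastStats per-image \code{\linkS4class{TrajectoryStats}} of the
#'   final cycle (empty list in exact-gradient mode).
#' @slot masterSeed seed from which all per-(cycle, image) seeds derive.
#' @exportClass StringOptimization
setClass("StringOptimization",
  representation(finalPath = "StringPath", cyclePaths = "list",
                 estimates = "list", convergence = "ConvergenceRecord",
                 lastStats = "list", masterSeed = "integer"))

#' FreeEnergyProfile: G(alpha) along the string on a dense grid
#'
#' @slot alphaGrid dense grid covering [0, 1] inclusive.
#' @slot G free energy relative to alpha = 0 (G[1] is exactly 0).
#' @slot stderr per-point standard deviation across trailing cycles
#'   (zeros when computed from a single cycle).
#' @slot sourceCycles cycle indices the profile was computed from.
#' @exportClass FreeEnergyProfile
setClass("FreeEnergyProfile",
  representation(alphaGrid = "numeric", G = "numeric", stderr = "numeric",
                 sourceCycles = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@G) != length(object@alphaGrid) ||
        length(object@stderr) != length(object@alphaGrid))
      msg <- c(msg, "alphaGrid, G and stderr must have equal lengths")
    if (length(object@G) && object@G[1] != 0)
      msg <- c(msg, "G must be 0 at alpha = 0")
    a <- object@alphaGrid
    if (length(a) && (abs(a[1]) > 1e-12 || abs(a[length(a)] - 1) > 1e-12))
      msg <- c(msg, "alphaGrid must cover [0, 1] inclusive")
    if (length(msg)) msg else TRUE
  })

#' BasinDefinition: reactant and product regions in CV space
#'
#' Regions are axis-aligned boxes over CV values; they must be disjoint.
#'
#' @slot reactantLower,reactantUpper per-CV bounds of the reactant box.
#' @slot productLower,productUpper per-CV bounds of the product box.
#' @slot maxSteps per-trajectory step cap for committor shots.
#' @exportClass BasinDefinition
setClass("BasinDefinition",
  representation(reactantLower = "numeric", reactantUpper = "numeric",
                 productLower = "numeric", productUpper = "numeric",
                 maxSteps = "integer"),
  validity = function(object) {
    n <- length(object@reactantLower)
    if (any(c(length(object@reactantUpper), length(object@productLower),
              length(object@productUpper)) != n))
      return("all bounds must have the same length")
    if (any(object@reactantLower > object@reactantUpper) ||
        any(object@productLower > object@productUpper))
      return("lower bounds must not exceed upper bounds")
    overlap <- all(object@reactantLower <= object@productUpper &
                   object@productLower <= object@reactantUpper)
    if (overlap) return("reactant and product regions must be disjoint")
    if (object@maxSteps < 1L) return("maxSteps must be >= 1")
    TRUE
  })

#' CommittorResult: committor probabilities from shooting trajectories
#'
#' @slot pB per-configuration committed-to-product fractions in [0, 1].
#' @slot nShots trajectories launched per configuration.
#' @slot histBreaks,histCounts binned distribution of pB.
#' @slot unresolvedFraction fraction of trajectories hitting the step cap.
#' @exportClass CommittorResult
setClass("CommittorResult",
  representation(pB = "numeric", nShots = "integer", histBreaks = "numeric",
                 histCounts = "integer", unresolvedFraction = "numeric"),
  validity = function(object) {
    if (length(object@pB) && (min(object@pB) < 0 || max(object@pB) > 1))
      return("pB values must lie in [0, 1]")
    if (object@unresolvedFraction < 0 || object@unresolvedFraction > 1)
      return("unresolvedFraction must lie in [0, 1]")
    TRUE
  })

#' ConformerPopulations: angular cluster fractions along the path
#'
#' @slot perImage images x clusters matrix of membership fractions
#'   (rows sum to 1).
#' @slot centers circular cluster means in degrees on (-180, 180].
#' @slot label name of the clustered dihedral.
#' @exportClass ConformerPopulations
setClass("ConformerPopulations",
  representation(perImage = "matrix", centers = "numeric", label = "character"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@perImage) != length(object@centers))
      msg <- c(msg, "one center per cluster column required")
    if (nrow(object@perImage) &&
        max(abs(rowSums(object@perImage) - 1)) > 1e-9)
      msg <- c(msg, "per-image fractions must sum to 1")
    if (length(object@centers) &&
        (min(object@centers) <= -180 || max(object@centers) > 180))
      msg <- c(msg, "centers must lie in (-180, 180]")
    if (length(msg)) msg else TRUE
  })

#' RunConfig: a complete, serializable run specification
#'
#' Round-trips losslessly through the YAML configuration format (see
#' \code{\link{readRunConfig}}).
#'
#' @slot surface list(name, parameters) resolvable by \code{\link{buildSurface}}.
#' @slot cvs list of CV declarations (kind, indices, label, weight).
#' @slot monitors like \code{cvs}, for monitored (non-string) coordinates.
#' @slot endpoints list(a, b) of CV vectors the initial string interpolates.
#' @slot images number of images R.
#' @slot cycles number of optimization cycles.
#' @slot descentStep,smoothing string evolution parameters.
#' @slot forceConstant harmonic restraint force constant.
#' @slot endpointMode "free" or "fixed".
#' @slot sampler list of sampler settings.
#' @slot masterSeed master seed recorded in every output artifact.
#' @slot outputDir destination directory for archives.
#' @exportClass RunConfig
setClass("RunConfig",
  representation(surface = "list", cvs = "list", monitors = "list",
                 endpoints = "list", images = "integer", cycles = "integer",
                 descentStep = "numeric", smoothing = "numeric",
                 forceConstant = "numeric", endpointMode = "character",
                 sampler = "list", masterSeed = "integer",
                 outputDir = "character"))
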