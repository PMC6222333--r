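#' @include AllClasses.R
NULL

#' Evaluate the energy of a surface at a configuration
#' @param surface a \code{\linkS4class{PotentialSurface}}.
#' @param x configuration vector.
#' @return scalar energy.
#' @export
setGeneric("energy", function(surface, x) standardGeneric("energy"))

#' Evaluate the exact energy gradient at a configuration
#' @param surface a \code{\linkS4class{PotentialSurface}}.
#' @param x configuration vector.
#' @return gradient vector.
#' @export
setGeneric("energyGradient", function(surface, x) standardGeneric("energyGradient"))

#' Number of collective variables in a set
#' @param x a \code{\linkS4class{CVSet}}.
#' @return integer count.
#' @export
setGeneric("nCVs", function(x) standardGeneric("nCVs"))

#' Labels of the collective variables
#' @param x a \code{\linkS4class{CVSet}}.
#' @return character vector.
#' @export
setGeneric("cvLabels", function(x) standardGeneric("cvLabels"))

#' Arc-length weights of the collective variables
#' @param x a \code{\linkS4class{CVSet}}.
#' @return numeric vector.
#' @export
setGeneric("cvWeights", function(x) standardGeneric("cvWeights"))

#' Image matrix of a string path
#' @param x a \code{\linkS4class{StringPath}}.
#' @return R x N matrix of CV values.
#' @export
setGeneric("images", function(x) standardGeneric("images"))

#' Arc-length parameter values of a string path
#' @param x a \code{\linkS4class{StringPath}} or
#'   \code{\linkS4class{FreeEnergyProfile}}.
#' @return numeric vector.
#' @export
setGeneric("alphas", function(x) standardGeneric("alphas"))

#' Number of images of a string path
#' @param x a \code{\linkS4class{StringPath}}.
#' @return integer count.
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))

#' Free-energy values of a profile
#' @param x a \code{\linkS4class{FreeEnergyProfile}}.
#' @return numeric vector on the profile's alpha grid.
#' @export
setGeneric("profileG", function(x) standardGeneric("profileG"))

#' Per-point uncertainty of a profile
#' @param x a \code{\linkS4class{FreeEnergyProfile}}.
#' @return numeric vector of standard deviations.
#' @export
setGeneric("profileStderr", function(x) standardGeneric("profileStderr"))

setMethod("energy", "PotentialSurface", function(surface, x) {
  stopifnot(length(x) == surface@dimension)
  surface@energyFunc(x)
})

setMethod("energyGradient", "PotentialSurface", function(surface, x) {
  stopifnot(length(x) == surface@dimension)
  surface@gradFunc(x)
})

setMethod("nCVs", "CVSet", function(x) length(x@cvs))
setMethod("cvLabels", "CVSet", function(x)
  vapply(x@cvs, function(cv) cv@label, character(1)))
setMethod("cvWeights", "CVSet", function(x)
  vapply(x@cvs, function(cv) cv@weight, numeric(1)))

setMethod("images", "StringPath", function(x) x@images)
setMethod("alphas", "StringPath", function(x) x@alphas)
setMethod("nImages", "StringPath", function(x) nrow(x@images))
setMethod("alphas", "FreeEnergyProfile", function(x) x@alphaGrid)
setMethod("profileG", "FreeEnergyProfile", function(x) x@G)
setMethod("profileStderr", "FreeEnergyProfile", function(x) x@stderr)

setMethod("show", "PotentialSurface", function(object) {
  cat(sprintf("PotentialSurface '%s': %d coordinate(s)\n",
              object@name, object@dimension))
  cat("  domain:", paste(sprintf("[%.3g, %.3g]", object@domain[1, ],
                                 object@domain[2, ]), collapse = " x "), "\n")
  if (length(object@parameters))
    cat("  parameters:", paste(names(object@parameters), collapse = ", "), "\n")
})

setMethod("show", "CVSet", function(object) {
  cat(sprintf("CVSet with %d collective variable(s)\n", nCVs(object)))
  for (cv in object@cvs)
    cat(sprintf("  %-12s %-9s indices: %s\n", cv@label, cv@kind,
                paste(cv@indices, collapse = ",")))
})

setMethod("show", "StringPath", function(object) {
  cat(sprintf("StringPath: %d images x %d CVs (cycle %d)\n",
              nrow(object@images), ncol(object@images), object@cycle))
})

setMethod("show", "FreeEnergyProfile", function(object) {
  n <- length(object@G)
  cat(sprintf("FreeEnergyProfile on %d grid points\n", n))
  if (n) {
    cat(sprintf("  G range: [%.3f, %.3f]; G(1) = %.3f\n",
                min(object@G), max(object@G), object@G[n]))
    if (any(object@stderr > 0))
      cat(sprintf("  max pointwise SD: %.3g (cycles %s)\n",
                  max(object@stderr),
                  paste(range(object@sourceCycles), collapse = "-")))
  }
})

setMethod("show", "StringOptimization", function(object) {
  nc <- length(object@cyclePaths)
  cat(sprintf("StringOptimization: %d cycle(s), %d images x %d CVs\n",
              nc, nrow(object@finalPath@images), ncol(object@finalPath@images)))
  r <- object@convergence@rmsdStep
  if (length(r))
    cat(sprintf("  final consecutive-cycle RMSD: %.3g\n", r[length(r)]))
})

setMethod("show", "CommittorResult", function(object) {
  cat(sprintf("CommittorResult: %d configuration(s), %d shots each\n",
              length(object@pB), object@nShots))
  if (length(object@pB))
    cat(sprintf("  mean pB = %.3f; unresolved fraction = %.3f\n",
                mean(object@pB), object@unresolvedFraction))
})

setMethod("show", "ConformerPopulations", function(object) {
  cat(sprintf("ConformerPopulations for '%s': %d cluster(s) over %d image(s)\n",
              object@label, length(object@centers), nrow(object@perImage)))
  cat("  centers (deg):", paste(sprintf("%.1f", object@centers), collapse = ", "), "\n")
})
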