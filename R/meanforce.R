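#' @include AllClasses.R sampler.R
NULL

#' Estimate the free-energy gradient at an image
#'
#' The mean-force estimator for a harmonically restrained trajectory:
#' \deqn{dG/dz_i = k_i \, \overline{(z_i - \theta_i[x(t)])},}
#' the force constant times the time average of the deviation of each CV
#' from its anchor.  (A literal temperature prefactor reading,
#' \code{k * T_sim * mean}, where T_sim is the sampled trajectory length,
#' is exposed for comparison via \code{literalPrefactor} but is
#' dimensionally inconsistent and not recommended.)  Standard errors come
#' from non-overlapping block averages.
#'
#' @param stats a \code{\linkS4class{TrajectoryStats}}.
#' @param spec the \code{\linkS4class{RestraintSpec}} used for the run.
#' @param imageIndex image the estimate belongs to.
#' @param literalPrefactor use the literal k*T prefactor reading (where T
#'   is the number of accumulated samples times one, i.e. trajectory length
#'   in sampling strides); default FALSE.
#' @return a \code{\linkS4class{MeanForceEstimate}} (metric filled by
#'   \code{\link{estimateMetric}}).
#' @export
estimateGradient <- function(stats, spec, imageIndex = 1L,
                             literalPrefactor = FALSE) {
  stopifnot(is(stats, "TrajectoryStats"), is(spec, "RestraintSpec"))
  if (stats@nSamples < 1L) stop("no accumulated samples")
  pref <- if (literalPrefactor) spec@k * stats@nSamples else spec@k
  grad <- pref * stats@meanDeviation
  nb <- nrow(stats@blockMeans)
  se <- if (nb >= 2L)
    pref * apply(stats@blockMeans, 2, sd) / sqrt(nb)
  else rep(NA_real_, length(grad))
  new("MeanForceEstimate", gradient = as.numeric(grad),
      metric = estimateMetric(stats), standardError = as.numeric(se),
      imageIndex = as.integer(imageIndex))
}

#' Estimate the metric tensor at an image
#'
#' The time average of the Gram matrix of CV Cartesian gradients,
#' \deqn{M_{ij} = \overline{\sum_k (\partial\theta_i/\partial x_k)
#'   (\partial\theta_j/\partial x_k)},}
#' which accounts for the curvilinear relation between CVs and Cartesian
#' coordinates.  Identity CVs give the identity matrix exactly; a lone
#' distance CV between two free points gives exactly 2.
#'
#' @param stats a \code{\linkS4class{TrajectoryStats}}.
#' @return symmetric N x N matrix.
#' @export
estimateMetric <- function(stats) {
  stopifnot(is(stats, "TrajectoryStats"))
  M <- stats@gradientProducts
  (M + t(M)) / 2
}

#' Sample an image and estimate mean force and metric in one call
#'
#' Convenience wrapper: runs \code{\link{runRestrained}} and converts the
#' accumulators with \code{\link{estimateGradient}}.
#'
#' @inheritParams runRestrained
#' @param imageIndex image index recorded in the estimate.
#' @return list(estimate, stats).
#' @export
sampleMeanForce <- function(surface, cvset, spec, config, x0,
                            monitors = NULL, imageIndex = 1L) {
  stats <- runRestrained(surface, cvset, spec, config, x0, monitors)
  list(estimate = estimateGradient(stats, spec, imageIndex), stats = stats)
}
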