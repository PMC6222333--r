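#' @include AllClasses.R
NULL

.deg2unit <- function(deg) cbind(cos(deg * pi / 180), sin(deg * pi / 180))
.unit2deg <- function(xy) {
  deg <- atan2(xy[, 2], xy[, 1]) * 180 / pi
  deg[deg <= -180] <- deg[deg <= -180] + 360
  # map -180 exactly to +180 so the range is (-180, 180]
  deg[abs(deg + 180) < 1e-12] <- 180
  deg
}

#' Cluster per-image dihedral samples into conformer populations
#'
#' Circular k-means: angles are embedded as unit vectors on the circle and
#' clustered with seeded multi-restart k-means; cluster centers are the
#' circular means, so wraparound at +/-180 degrees is handled naturally.
#' With \code{nClusters = "auto"}, k in 2..5 is scored by the mean
#' silhouette width on the embedded points and a single cluster is chosen
#' when no split scores convincingly (best silhouette < 0.5).
#'
#' @param samples list with one numeric vector of angle samples (degrees)
#'   per image; every image needs at least one sample.
#' @param nClusters integer number of clusters, or \code{"auto"}.
#' @param label name of the clustered dihedral.
#' @param nRestarts k-means restarts.
#' @param seed RNG seed for the restarts.
#' @return a \code{\linkS4class{ConformerPopulations}}: per-image
#'   membership fractions (rows sum to 1) and circular cluster centers in
#'   degrees on (-180, 180].
#' @examples
#' pops <- clusterDihedralPopulations(list(c(-50, -55), c(80, 85)),
#'                                    nClusters = 2)
#' @export
clusterDihedralPopulations <- function(samples, nClusters = "auto",
                                       label = "dihedral", nRestarts = 10L,
                                       seed = 1L) {
  if (!length(samples) || any(!vapply(samples, length, integer(1))))
    stop("every image needs at least one angle sample")
  pooled <- unlist(samples, use.names = FALSE)
  emb <- .deg2unit(pooled)
  nUnique <- nrow(unique(round(emb, 10)))

  fitK <- function(k) {
    set.seed(seed)
    kmeans(emb, centers = k, nstart = nRestarts)
  }
  if (identical(nClusters, "auto")) {
    best <- NULL; bestSil <- -Inf
    if (nUnique >= 2L) {
      dd <- dist(emb)
      for (k in 2:min(5L, nUnique)) {
        # k close to the number of distinct angles can defeat the random
        # center draw; such k are simply not candidates
        fit <- tryCatch(fitK(k), error = function(e) NULL)
        if (is.null(fit)) next
        sil <- mean(silhouette(fit$cluster, dd)[, 3])
        if (sil > bestSil) { bestSil <- sil; best <- fit }
      }
    }
    fit <- if (bestSil >= 0.5) best else fitK(1L)
  } else {
    k <- as.integer(nClusters)
    if (k > nUnique) stop("more clusters requested than distinct angles")
    fit <- fitK(k)
  }

  # circular means per cluster (normalized embedded centroids)
  k <- nrow(fit$centers)
  centers <- unname(.unit2deg(fit$centers /
                                sqrt(rowSums(fit$centers^2))))
  ord <- order(centers)
  centers <- centers[ord]
  relabel <- match(seq_len(k), ord)

  perImage <- matrix(0, length(samples), k)
  off <- 0L
  for (im in seq_along(samples)) {
    n <- length(samples[[im]])
    cl <- relabel[fit$cluster[(off + 1L):(off + n)]]
    perImage[im, ] <- tabulate(cl, k) / n
    off <- off + n
  }
  colnames(perImage) <- sprintf("C%d", seq_len(k))
  new("ConformerPopulations", perImage = perImage, centers = centers,
      label = label)
}

#' Per-image statistics of a monitored coordinate
#'
#' Tabulates the mean and standard deviation of a monitored (non-string)
#' coordinate recorded during restrained sampling, one row per image.
#'
#' @param statsList list of \code{\linkS4class{TrajectoryStats}}, one per
#'   image, each carrying the monitored label.
#' @param label name of the monitored coordinate.
#' @param alphas optional per-image alpha values to attach.
#' @return data.frame with columns image, alpha (if given), mean, sd.
#' @export
monitoredSeries <- function(statsList, label, alphas = NULL) {
  vals <- lapply(statsList, function(st) {
    if (!label %in% names(st@monitoredSamples))
      stop("monitored label '", label, "' missing from a trajectory")
    st@monitoredSamples[[label]]
  })
  out <- data.frame(
    image = seq_along(statsList),
    mean = vapply(vals, mean, numeric(1)),
    sd = vapply(vals, function(v) if (length(v) > 1L) sd(v) else 0,
                numeric(1)))
  if (!is.null(alphas)) out <- cbind(out[1], alpha = alphas, out[-1])
  out
}
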