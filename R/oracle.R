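#' @include AllClasses.R surfaces.R string.R
NULL

#' Finite-difference Hessian of a surface
#'
#' Central-difference Hessian of the energy, symmetrized.  Used by the
#' oracle machinery to classify stationary points (a first-order saddle
#' has exactly one negative eigenvalue).
#'
#' @param surface a \code{\linkS4class{PotentialSurface}}.
#' @param x configuration.
#' @param h finite-difference step.
#' @return symmetric dimension x dimension matrix.
#' @export
numericHessian <- function(surface, x, h = 1e-5) {
  d <- surface@dimension
  H <- matrix(0, d, d)
  f <- surface@energyFunc
  for (i in seq_len(d)) for (j in i:d) {
    pp <- function(di, dj) {
      q <- x; q[i] <- q[i] + di; q[j] <- q[j] + dj; f(q)
    }
    H[i, j] <- H[j, i] <-
      (pp(h, h) - pp(h, -h) - pp(-h, h) + pp(-h, -h)) / (4 * h * h)
  }
  H
}

#' Newton refinement of a stationary point
#'
#' Drives the gradient to zero by damped Newton iterations from a nearby
#' starting point; works for minima and saddles alike.
#'
#' @param surface a \code{\linkS4class{PotentialSurface}}.
#' @param x0 starting configuration.
#' @param tol gradient-norm convergence tolerance.
#' @param maxIter iteration cap.
#' @return list(x, energy, gradientNorm, hessianEigenvalues).
#' @export
refineStationary <- function(surface, x0, tol = 1e-10, maxIter = 100L) {
  x <- as.numeric(x0)
  for (it in seq_len(maxIter)) {
    g <- surface@gradFunc(x)
    if (sqrt(sum(g^2)) < tol) break
    H <- numericHessian(surface, x)
    step <- tryCatch(solve(H, g), error = function(e) g * 0.01)
    sn <- sqrt(sum(step^2))
    if (sn > 0.25) step <- step * (0.25 / sn)  # Newton is only locally safe
    x <- x - step
  }
  list(x = x, energy = surface@energyFunc(x),
       gradientNorm = sqrt(sum(surface@gradFunc(x)^2)),
       hessianEigenvalues = eigen(numericHessian(surface, x),
                                  symmetric = TRUE)$values)
}

# one equal-arc-length linear resampling pass over a polyline
.resampleOnce <- function(pts, nOut) {
  seg <- sqrt(rowSums(diff(pts)^2))
  keep <- c(TRUE, seg > 1e-14)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 2L) return(pts[rep(1L, nOut), , drop = FALSE])
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  targets <- seq(0, L, length.out = nOut)
  out <- matrix(0, nOut, ncol(pts))
  out[1, ] <- pts[1, ]; out[nOut, ] <- pts[nrow(pts), ]
  j <- 1L
  for (i in 2:(nOut - 1L)) {
    tgt <- targets[i]
    while (j < length(seg) && cum[j + 1L] < tgt) j <- j + 1L
    frac <- (tgt - cum[j]) / seg[j]
    out[i, ] <- pts[j, ] + frac * (pts[j + 1L, ] - pts[j, ])
  }
  out
}

# iterate resampling until consecutive spacings are uniform to ~1e-9
.resamplePolyline <- function(pts, nOut, tol = 1e-9, maxIter = 100L) {
  for (it in seq_len(maxIter)) {
    pts <- .resampleOnce(pts, nOut)
    seg <- sqrt(rowSums(diff(pts)^2))
    if (!length(seg) || mean(seg) == 0) break
    if ((max(seg) - min(seg)) / mean(seg) <= tol) break
  }
  pts
}

# steepest-descent branch from a saddle: kick along +/- the unstable
# eigenvector, then follow -grad with normalized steps of length h until
# the gradient flattens out; the landing basin is Newton-refined
.descentBranch <- function(surface, saddle, direction, h, maxSteps = 20000L) {
  x <- saddle + h * direction
  pts <- rbind(saddle, x)
  for (i in seq_len(maxSteps)) {
    g <- surface@gradFunc(x)
    gn <- sqrt(sum(g^2))
    if (gn < 1e-8) break
    x <- x - g * (h / gn)
    pts <- rbind(pts, x)
    if (i > 3L) {
      # flat region: normalized descent stalls near the minimum
      if (surface@energyFunc(pts[nrow(pts) - 1L, ]) -
          surface@energyFunc(x) < 1e-12 * max(1, abs(surface@energyFunc(x))))
        break
    }
  }
  endMin <- refineStationary(surface, x, maxIter = 60L)
  rbind(pts, endMin$x)
}

#' Brute-force minimum-energy path oracle
#'
#' Computes a ground-truth minimum-energy path between two basins by a
#' method independent of the string optimizer.  A minimax (bottleneck)
#' search on a dense 8-connected energy grid -- the route minimizing the
#' maximum energy en route, extracted via the minimum-spanning-tree
#' bottleneck property -- locates the saddle regions; each candidate is
#' refined to a true first-order saddle by Newton iteration, and the MEP
#' is then assembled from steepest-descent paths dropped from every
#' saddle into its two adjacent basins (the defining property of the
#' MEP), finally resampled to uniform arc length.  Restricted to 2-D
#' surfaces (the multi-barrier relay surfaces carry their own analytic
#' spine oracle, \code{\link{relaySpine}}).
#'
#' @param surface a 2-D \code{\linkS4class{PotentialSurface}}.
#' @param a,b endpoint coordinate vectors inside the domain.
#' @param resolution grid spacing (also sets the descent step, h =
#'   resolution / 4).
#' @param nPoints number of points in the returned path.
#' @param relaxIter transverse relaxation sweeps used only in the
#'   saddle-free fallback (both endpoints in one basin).
#' @return a \code{\linkS4class{ReferencePath}} with uniformly spaced
#'   points, energies, and the indices of prominent local energy maxima
#'   (the saddles crossed).
#' @export
bruteForceMEP <- function(surface, a, b, resolution = 0.01, nPoints = 201L,
                          relaxIter = 400L) {
  if (surface@dimension != 2L)
    stop("the grid oracle supports 2-D surfaces only")
  lo <- surface@domain[1, ]; hi <- surface@domain[2, ]
  if (any(a < lo | a > hi) || any(b < lo | b > hi))
    stop("endpoints outside the surface domain")
  if (sqrt(sum((a - b)^2)) < resolution / 2) {
    pts <- matrix(a, 1, 2)
    return(new("ReferencePath", points = pts,
               energies = surface@energyFunc(a), saddleIndices = integer(0)))
  }
  gx <- seq(lo[1], hi[1], by = resolution)
  gy <- seq(lo[2], hi[2], by = resolution)
  nx <- length(gx); ny <- length(gy)
  E <- outer(seq_len(nx), seq_len(ny),
             function(i, j) mapply(function(ii, jj)
               surface@energyFunc(c(gx[ii], gy[jj])), i, j))
  nid <- function(i, j) (j - 1L) * nx + i
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (s in shifts) {
    irng <- seq.int(1L + max(-s[1], 0L), nx - max(s[1], 0L))
    jrng <- seq.int(1L + max(-s[2], 0L), ny - max(s[2], 0L))
    ii <- rep(irng, times = length(jrng))
    jj <- rep(jrng, each = length(irng))
    from <- c(from, nid(ii, jj))
    to <- c(to, nid(ii + s[1], jj + s[2]))
    wt <- c(wt, pmax(E[cbind(ii, jj)], E[cbind(ii + s[1], jj + s[2])]))
  }
  g <- graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- set_edge_attr(g, "weight", value = wt)
  tree <- mst(g)  # minimax path = unique tree path (bottleneck property)
  ia <- c(which.min(abs(gx - a[1])), which.min(abs(gy - a[2])))
  ib <- c(which.min(abs(gx - b[1])), which.min(abs(gy - b[2])))
  vp <- shortest_paths(tree, nid(ia[1], ia[2]), nid(ib[1], ib[2]),
                       weights = NA)$vpath[[1]]
  ids <- as.integer(vp)
  if (length(ids) < 2L) stop("grid too coarse to connect the endpoints")
  raw <- cbind(gx[(ids - 1L) %% nx + 1L], gy[(ids - 1L) %/% nx + 1L])
  raw[1, ] <- a; raw[nrow(raw), ] <- b

  # saddle candidates: prominent energy maxima along the raw node path
  enRaw <- apply(raw, 1, surface@energyFunc)
  cand <- .prominentMaxima(enRaw,
                           promTol = 1e-3 * max(1e-12, diff(range(enRaw))))
  saddles <- list()
  for (i in cand) {
    ref <- refineStationary(surface, raw[i, ])
    ok <- ref$gradientNorm < 1e-6 &&
      sum(ref$hessianEigenvalues < 0) == 1L &&
      all(ref$x >= lo) && all(ref$x <= hi)
    if (!ok) next
    dup <- any(vapply(saddles, function(s)
      sqrt(sum((s$x - ref$x)^2)) < resolution, logical(1)))
    if (!dup) saddles[[length(saddles) + 1L]] <- c(ref, list(rawIndex = i))
  }

  h <- resolution / 4
  if (!length(saddles)) {
    # both endpoints share one basin: relax the raw path transversally
    pts <- .resamplePolyline(raw, nPoints)
    lambdaMax <- max(vapply(unique(c(seq(1, nrow(pts), by = 10), nrow(pts))),
                            function(i)
      max(abs(eigen(numericHessian(surface, pts[i, ]),
                    symmetric = TRUE, only.values = TRUE)$values)),
      numeric(1)))
    rate <- 0.9 / max(lambdaMax, 1e-6)
    n <- nrow(pts)
    for (it in seq_len(relaxIter)) {
      tang <- rbind(pts[2, ] - pts[1, ],
                    pts[3:n, ] - pts[1:(n - 2), ],
                    pts[n, ] - pts[n - 1, ])
      tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-300)
      for (i in 2:(n - 1)) {
        gvec <- surface@gradFunc(pts[i, ])
        gperp <- gvec - sum(gvec * tang[i, ]) * tang[i, ]
        gn <- sqrt(sum(gperp^2))
        if (gn > 0)
          pts[i, ] <- pts[i, ] - gperp * min(rate, resolution / 2 / gn)
      }
      if (it %% 25L == 0L) pts <- .resamplePolyline(pts, n)
    }
  } else {
    # order saddles as the minimax route crosses them, then chain
    # steepest-descent branches: a ... saddle_1 ... m_1 ... saddle_2 ... b
    ord <- order(vapply(saddles, function(s) s$rawIndex, numeric(1)))
    saddles <- saddles[ord]
    pts <- matrix(a, 1, 2)
    current <- a
    for (s in saddles) {
      H <- numericHessian(surface, s$x)
      ev <- eigen(H, symmetric = TRUE)
      v <- ev$vectors[, which.min(ev$values)]
      b1 <- .descentBranch(surface, s$x, v, h)
      b2 <- .descentBranch(surface, s$x, -v, h)
      e1 <- b1[nrow(b1), ]; e2 <- b2[nrow(b2), ]
      if (sum((e1 - current)^2) > sum((e2 - current)^2)) {
        tmp <- b1; b1 <- b2; b2 <- tmp
        e1 <- b1[nrow(b1), ]
      }
      if (sqrt(sum((e1 - current)^2)) > 10 * resolution)
        warning("descent branch does not land on the previous basin; ",
                "the grid may be too coarse")
      pts <- rbind(pts, b1[rev(seq_len(nrow(b1))), ], b2)
      current <- b2[nrow(b2), ]
    }
    if (sqrt(sum((current - b)^2)) > 10 * resolution)
      warning("assembled MEP does not terminate at the requested endpoint")
    pts <- rbind(pts, b)
  }

  pts <- .resamplePolyline(pts, nPoints)
  en <- apply(pts, 1, surface@energyFunc)
  sad <- .prominentMaxima(en, promTol = 1e-3 * max(1e-12, diff(range(en))))
  new("ReferencePath", points = pts, energies = en,
      saddleIndices = as.integer(sad))
}

# interior local maxima with prominence above promTol relative to the
# lowest intervening minima on both sides
.prominentMaxima <- function(en, promTol) {
  n <- length(en)
  if (n < 3L) return(integer(0))
  cand <- which(diff(sign(diff(en))) == -2) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    leftMin <- min(en[1:i]); rightMin <- min(en[i:n])
    keep[k] <- (en[i] - max(leftMin, rightMin)) > promTol
  }
  cand[keep]
}

#' Distance from points to a reference path
#'
#' Minimum Euclidean distance from each query point to the polyline of a
#' \code{\linkS4class{ReferencePath}}.
#'
#' @param ref a \code{\linkS4class{ReferencePath}}.
#' @param pts query points (matrix, one per row).
#' @return numeric vector of distances.
#' @export
distanceToPath <- function(ref, pts) {
  P <- ref@points
  pts <- as.matrix(pts)
  if (nrow(P) == 1L)
    return(sqrt(rowSums((pts - matrix(P[1, ], nrow(pts), ncol(P),
                                      byrow = TRUE))^2)))
  vapply(seq_len(nrow(pts)), function(i) {
    q <- pts[i, ]
    dmin <- Inf
    for (s in seq_len(nrow(P) - 1L)) {
      a <- P[s, ]; b <- P[s + 1L, ]
      ab <- b - a
      t <- sum((q - a) * ab) / max(sum(ab^2), 1e-300)
      t <- min(1, max(0, t))
      dmin <- min(dmin, sqrt(sum((q - a - t * ab)^2)))
    }
    dmin
  }, numeric(1))
}
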