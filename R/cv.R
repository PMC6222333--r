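#' @include AllClasses.R
NULL

#' Construct collective variable definitions
#'
#' \code{cvDistance} is the interatomic distance between atoms \code{i} and
#' \code{j} (the configuration is read as consecutive xyz triplets);
#' \code{cvDihedral} is the torsion angle of atoms \code{i-j-k-l} in degrees
#' on (-180, 180] with the IUPAC sign convention (cis = 0);
#' \code{cvIdentity} reads raw coordinate \code{index}.
#'
#' @param i,j,k,l 1-based atom indices.
#' @param index 1-based coordinate index.
#' @param label human-readable name (defaults to a generated one).
#' @param weight positive arc-length weight (default 1; the usual distance
#'   CV sets are commensurate in length units, so unit weights apply).
#' @return a \code{\linkS4class{CVDefinition}}.
#' @examples
#' cvDistance(1, 2, label = "Pg-O3b")
#' @export
cvDistance <- function(i, j, label = sprintf("d_%d_%d", i, j), weight = 1)
  new("CVDefinition", kind = "distance", indices = as.integer(c(i, j)),
      weight = weight, label = label)

#' @rdname cvDistance
#' @export
cvDihedral <- function(i, j, k, l,
                       label = sprintf("phi_%d_%d_%d_%d", i, j, k, l),
                       weight = 1)
  new("CVDefinition", kind = "dihedral", indices = as.integer(c(i, j, k, l)),
      weight = weight, label = label)

#' @rdname cvDistance
#' @export
cvIdentity <- function(index, label = sprintf("x_%d", index), weight = 1)
  new("CVDefinition", kind = "identity", indices = as.integer(index),
      weight = weight, label = label)

#' Bundle collective variables into an ordered set
#'
#' @param ... \code{\linkS4class{CVDefinition}} objects, or a single list
#'   of them.
#' @return a \code{\linkS4class{CVSet}}.
#' @examples
#' cvSet(cvIdentity(1, "x"), cvIdentity(2, "y"))
#' @export
cvSet <- function(...) {
  cvs <- list(...)
  if (length(cvs) == 1L && is.list(cvs[[1]]) && !is(cvs[[1]], "CVDefinition"))
    cvs <- cvs[[1]]
  new("CVSet", cvs = cvs)
}

#' An all-identity CV set over the first d coordinates
#' @param d number of coordinates.
#' @param labels optional CV labels.
#' @return a \code{\linkS4class{CVSet}}.
#' @export
identityCVSet <- function(d, labels = sprintf("x_%d", seq_len(d)))
  cvSet(lapply(seq_len(d), function(j) cvIdentity(j, labels[j])))

.atomCoords <- function(x, atom) x[(3L * (atom - 1L) + 1L):(3L * atom)]

.cross <- function(u, v)
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])

# value + sparse gradient (coordinate indices and values) of one CV
.cvValueGrad <- function(cv, x, wantGrad = TRUE) {
  if (cv@kind == "identity") {
    j <- cv@indices
    if (j > length(x)) stop("identity CV index exceeds configuration length")
    return(list(value = x[j], idx = j, grad = if (wantGrad) 1))
  }
  if (3L * max(cv@indices) > length(x))
    stop(cv@kind, " CV atom index exceeds configuration length")
  if (cv@kind == "distance") {
    ai <- cv@indices[1]; aj <- cv@indices[2]
    ri <- .atomCoords(x, ai); rj <- .atomCoords(x, aj)
    dv <- ri - rj
    d <- sqrt(sum(dv^2))
    if (d < 1e-12)
      stop("degenerate distance CV '", cv@label, "': coincident points")
    idx <- c((3L * (ai - 1L) + 1L):(3L * ai), (3L * (aj - 1L) + 1L):(3L * aj))
    return(list(value = d, idx = idx,
                grad = if (wantGrad) c(dv / d, -dv / d)))
  }
  # dihedral, degrees; analytic gradient in degrees per length unit
  at <- cv@indices
  p1 <- .atomCoords(x, at[1]); p2 <- .atomCoords(x, at[2])
  p3 <- .atomCoords(x, at[3]); p4 <- .atomCoords(x, at[4])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  n1sq <- sum(n1^2); n2sq <- sum(n2^2); b2n <- sqrt(sum(b2^2))
  if (n1sq < 1e-18 || n2sq < 1e-18 || b2n < 1e-12)
    stop("degenerate dihedral CV '", cv@label, "': collinear geometry")
  phi <- atan2(sum(.cross(n1, n2) * b2) / b2n, sum(n1 * n2)) * 180 / pi
  if (phi <= -180) phi <- phi + 360
  out <- list(value = phi,
              idx = as.vector(vapply(at, function(a)
                (3L * (a - 1L) + 1L):(3L * a), integer(3))))
  if (wantGrad) {
    g1 <- -(b2n / n1sq) * n1
    g4 <- (b2n / n2sq) * n2
    c12 <- sum(b1 * b2) / b2n^2
    c32 <- sum(b3 * b2) / b2n^2
    g2 <- -(1 + c12) * g1 + c32 * g4
    g3 <- c12 * g1 - (1 + c32) * g4
    out$grad <- c(g1, g2, g3, g4) * 180 / pi
  }
  out
}

#' Evaluate a CV set on a configuration
#'
#' @param cvset a \code{\linkS4class{CVSet}}.
#' @param x configuration vector (coordinates, or xyz triplets for
#'   molecular CVs).
#' @return named numeric vector of CV values; distances in configuration
#'   length units, dihedrals in degrees on (-180, 180].
#' @examples
#' cvs <- cvSet(cvDistance(1, 2, "d12"))
#' evaluateCVs(cvs, c(0, 0, 0, 3, 4, 0))  # 5
#' @export
evaluateCVs <- function(cvset, x) {
  stopifnot(is(cvset, "CVSet"))
  vals <- vapply(cvset@cvs, function(cv)
    .cvValueGrad(cv, x, wantGrad = FALSE)$value, numeric(1))
  names(vals) <- cvLabels(cvset)
  vals
}

#' Exact Cartesian partial derivatives of a CV set
#'
#' Rows correspond to CVs, columns to configuration coordinates; entries
#' for coordinates a CV does not read are zero.  Partials are analytic and
#' match central finite differences to high accuracy.
#'
#' @inheritParams evaluateCVs
#' @return N x length(x) matrix of dtheta_i / dx_k.
#' @export
cvGradients <- function(cvset, x) {
  stopifnot(is(cvset, "CVSet"))
  N <- nCVs(cvset)
  J <- matrix(0, N, length(x),
              dimnames = list(cvLabels(cvset), NULL))
  for (i in seq_len(N)) {
    vg <- .cvValueGrad(cvset@cvs[[i]], x)
    J[i, vg$idx] <- vg$grad
  }
  J
}

# Fast evaluation engine used by the sampler: returns closures and, for
# purely linear CV maps (identity CVs), a constant Jacobian.
.cvEngine <- function(cvset, d) {
  kinds <- vapply(cvset@cvs, function(cv) cv@kind, character(1))
  N <- length(kinds)
  if (all(kinds == "identity")) {
    idx <- vapply(cvset@cvs, function(cv) cv@indices, integer(1))
    J <- matrix(0, N, d)
    J[cbind(seq_len(N), idx)] <- 1
    list(eval = function(x) x[idx], jac = function(x) J,
         constJac = J, identityIdx = idx)
  } else {
    list(eval = function(x) vapply(cvset@cvs, function(cv)
           .cvValueGrad(cv, x, wantGrad = FALSE)$value, numeric(1)),
         jac = function(x) cvGradients(cvset, x),
         constJac = NULL, identityIdx = NULL)
  }
}

#' Unwrap a circular angle series
#'
#' Removes 360-degree jumps so consecutive values differ by less than 180
#' degrees; used when monitoring slowly rotating dihedrals.
#'
#' @param angles numeric vector of angles in degrees.
#' @return unwrapped series (first value unchanged).
#' @export
unwrapAngles <- function(angles) {
  if (length(angles) < 2L) return(angles)
  d <- diff(angles)
  d <- d - 360 * round(d / 360)
  angles[1] + c(0, cumsum(d))
}
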