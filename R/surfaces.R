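#' @include AllClasses.R
NULL

.newSurface <- function(name, dimension, parameters, domain, energyFunc, gradFunc)
  new("PotentialSurface", name = name, dimension = as.integer(dimension),
      parameters = parameters, domain = domain,
      energyFunc = energyFunc, gradFunc = gradFunc)

#' The Mueller-Brown benchmark surface
#'
#' The canonical four-Gaussian two-dimensional test landscape for minimum
#' (free) energy path methods, with its standard literature parameter set
#' recorded in \code{parameters}.  It has three minima and two saddle points;
#' the deepest minimum lies near (-0.558, 1.442) with energy about -146.70.
#'
#' @return a \code{\linkS4class{PotentialSurface}} of dimension 2.
#' @examples
#' mb <- mullerBrown()
#' energy(mb, c(-0.558, 1.442))
#' @export
mullerBrown <- function() {
  p <- list(A = c(-200, -100, -170, 15),
            a = c(-1, -1, -6.5, 0.7),
            b = c(0, 0, 11, 0.6),
            c = c(-10, -10, -6.5, 0.7),
            x0 = c(1, 0, -0.5, -1),
            y0 = c(0, 0.5, 1.5, 1))
  eF <- function(x) {
    dx <- x[1] - p$x0; dy <- x[2] - p$y0
    sum(p$A * exp(p$a * dx^2 + p$b * dx * dy + p$c * dy^2))
  }
  gF <- function(x) {
    dx <- x[1] - p$x0; dy <- x[2] - p$y0
    e <- p$A * exp(p$a * dx^2 + p$b * dx * dy + p$c * dy^2)
    c(sum(e * (2 * p$a * dx + p$b * dy)), sum(e * (p$b * dx + 2 * p$c * dy)))
  }
  dom <- rbind(c(-1.7, -0.6), c(1.3, 2.3))
  .newSurface("muller_brown", 2L, p, dom, eF, gF)
}

#' A quartic double well with harmonic transverse confinement
#'
#' V(x, y) = h (x^2 - 1)^2 + c y^2 / 2, with minima at (+/-1, 0), a saddle
#' at the origin, and an exact barrier of h.
#'
#' @param h barrier height (energy units), > 0.
#' @param c transverse stiffness, > 0.
#' @return a \code{\linkS4class{PotentialSurface}} of dimension 2.
#' @examples
#' dw <- doubleWell(h = 5)
#' energy(dw, c(0, 0)) - energy(dw, c(1, 0))  # exactly 5
#' @export
doubleWell <- function(h = 5, c = 1) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0) stop("h must be > 0")
  if (!is.numeric(c) || length(c) != 1L || c <= 0) stop("c must be > 0")
  eF <- function(x) h * (x[1]^2 - 1)^2 + c * x[2]^2 / 2
  gF <- function(x) c(4 * h * x[1] * (x[1]^2 - 1), c * x[2])
  dom <- rbind(c(-4, -6), c(4, 6))
  .newSurface("double_well", 2L, list(h = h, c = c), dom, eF, gF)
}

#' An isotropic or per-coordinate quadratic well
#'
#' V(x) = sum_i a_i x_i^2 / 2.  Mainly used for sampler calibration, where
#' the stationary distribution and restrained means have closed forms.
#'
#' @param a per-coordinate curvatures (recycled to \code{dimension}).
#' @param dimension number of coordinates.
#' @return a \code{\linkS4class{PotentialSurface}}.
#' @export
quadraticWell <- function(a = 1, dimension = length(a)) {
  a <- rep_len(a, dimension)
  if (any(a <= 0)) stop("curvatures must be > 0")
  eF <- function(x) sum(a * x^2) / 2
  gF <- function(x) a * x
  dom <- rbind(rep(-1e3, dimension), rep(1e3, dimension))
  .newSurface("quadratic", as.integer(dimension), list(a = a), dom, eF, gF)
}

# C2 monotone ramp ("smootherstep"): w(0)=0, w(1)=1, w'(0)=w'(1)=w''(0)=w''(1)=0
.smoother <- function(t) t^3 * (10 - 15 * t + 6 * t^2)
.smootherD <- function(t) 30 * t^2 * (1 - t)^2

# 1-D spine profile through prescribed alternating stationary values.
# Stationary points sit at s = 0, 1, ..., M-1 (unit spacing keeps the local
# curvature |f''| <= ~5.8 x the largest stationary-value drop, so stiff
# harmonic restraints can hold images anywhere on the profile), with
# quadratic walls beyond the ends.
.spineProfile <- function(values, wall = 50) {
  M <- length(values)
  send <- M - 1
  f <- function(s) {
    if (s <= 0) return(values[1] + wall * s^2)
    if (s >= send) return(values[M] + wall * (s - send)^2)
    i <- min(M - 1L, 1L + floor(s))
    t <- s - (i - 1L)
    values[i] + (values[i + 1] - values[i]) * .smoother(t)
  }
  df <- function(s) {
    if (s <= 0) return(2 * wall * s)
    if (s >= send) return(2 * wall * (s - send))
    i <- min(M - 1L, 1L + floor(s))
    t <- s - (i - 1L)
    (values[i + 1] - values[i]) * .smootherD(t)
  }
  list(f = f, df = df, knots = seq(0, send))
}

#' Default stationary-value sequences for proton-relay benchmark profiles
#'
#' Free energies (energy units, relative to the reactant state) at the
#' alternating stationary states RC, TS1, IM1, ..., PC of the two benchmark
#' topologies: a four-barrier, three-intermediate proton-relay chain
#' (\code{gacProfileValues}) and a variant whose second barrier dominates
#' strongly (\code{sacProfileValues}).  Values at states with published
#' magnitudes follow those magnitudes; the remaining interior states are
#' fixed, plausible choices that preserve the topology.
#'
#' @return numeric vector of alternating minimum/maximum free energies.
#' @export
gacProfileValues <- function()
  c(RC = 0, TS1 = 9.1, IM1 = 5.0, TS2 = 14.0, IM2 = 8.5,
    TS3 = 12.0, IM3 = -6.0, TS4 = 2.0, PC = -1.7)

#' @rdname gacProfileValues
#' @export
sacProfileValues <- function()
  c(RC = 0, TS1 = 9.1, IM1 = 4.0, TS2 = 25.0, IM2 = -8.0,
    TS3 = -7.2, IM3 = -7.9, TS4 = -6.5, PC = -12.2)

#' A multi-barrier proton-relay benchmark surface
#'
#' A one-dimensional chain of sequential barriers and intermediates embedded
#' in \code{nCV} coordinates: the first coordinate carries the prescribed
#' spine profile (a C2 interpolation through \code{barrierSpec} with
#' stationary points exactly at the prescribed values, spaced one CV unit
#' apart so the profile's curvature stays within reach of stiff harmonic
#' restraints), and the remaining coordinates are harmonically confined
#' around zero.  The exact minimum free energy path therefore runs along
#' the first coordinate axis from 0 to (number of states - 1), with an
#' analytically known profile; \code{\link{relaySpine}} exposes it for
#' oracle comparison.  When restraining images on this surface choose the
#' force constant above the largest profile curvature (about 5.8 x the
#' largest inter-state free-energy drop; k = 400 is ample for the default
#' profiles).
#'
#' @param nCV number of coordinates, 2 to 6 (6 emulates the six-distance CV
#'   set of a general-acid relay, 4 the four-distance substrate-assisted set).
#' @param barrierSpec alternating stationary free energies starting and
#'   ending at minima (see \code{\link{gacProfileValues}}).
#' @param kappa transverse confinement stiffness.
#' @return a \code{\linkS4class{PotentialSurface}}.
#' @export
protonRelaySurface <- function(nCV = 6, barrierSpec = gacProfileValues(),
                               kappa = 20) {
  nCV <- as.integer(nCV)
  if (nCV < 2L || nCV > 6L) stop("nCV must be between 2 and 6")
  v <- as.numeric(barrierSpec)
  if (length(v) < 3L) stop("barrierSpec needs at least 3 stationary values")
  if (all(v == v[1])) {
    # degenerate flat spine: no barriers, straight-line MEP
    send <- length(v) - 1
    sp <- list(f = function(s) v[1] +
                 if (s < 0) 50 * s^2
                 else if (s > send) 50 * (s - send)^2 else 0,
               df = function(s)
                 if (s < 0) 100 * s
                 else if (s > send) 100 * (s - send) else 0)
  } else {
    d <- diff(v)
    if (any(d == 0) || any(d[-1] * d[-length(d)] >= 0))
      stop("barrierSpec must strictly alternate between minima and maxima")
    if (d[1] <= 0 || length(d) %% 2 != 0)
      stop("barrierSpec must start and end at minima (odd length, rising first)")
    sp <- .spineProfile(v)
  }
  eF <- function(x) sp$f(x[1]) + kappa * sum(x[-1]^2) / 2
  gF <- function(x) c(sp$df(x[1]), kappa * x[-1])
  send <- length(v) - 1
  dom <- rbind(c(-1, rep(-3, nCV - 1L)), c(send + 1, rep(3, nCV - 1L)))
  .newSurface("proton_relay", nCV,
              list(barrierSpec = v, kappa = kappa), dom, eF, gF)
}

#' Exact spine profile of a proton-relay surface
#'
#' Evaluates the analytic 1-D profile of \code{\link{protonRelaySurface}}
#' along its first coordinate (the exact MFEP), for oracle comparison.
#'
#' @param surface a surface built by \code{\link{protonRelaySurface}}.
#' @param s positions along the first coordinate (default: a dense grid
#'   spanning the stationary states at 0, 1, ..., M-1).
#' @return data.frame with columns \code{s} and \code{G}.
#' @export
relaySpine <- function(surface, s = NULL) {
  if (surface@name != "proton_relay") stop("not a proton_relay surface")
  v <- surface@parameters$barrierSpec
  if (is.null(s)) s <- seq(0, length(v) - 1, length.out = 801)
  sp <- .spineProfile(v)
  data.frame(s = s, G = vapply(s, sp$f, numeric(1)))
}

#' Build a surface from a serializable name + parameter description
#'
#' Registry used by the configuration reader: resolves
#' \code{"muller_brown"}, \code{"double_well"}, \code{"proton_relay"} and
#' \code{"quadratic"} with their parameter lists.
#'
#' @param name surface name.
#' @param parameters named list of parameters (may be empty for defaults).
#' @return a \code{\linkS4class{PotentialSurface}}.
#' @export
buildSurface <- function(name, parameters = list()) {
  switch(name,
    muller_brown = mullerBrown(),
    double_well = do.call(doubleWell, parameters),
    proton_relay = do.call(protonRelaySurface, parameters),
    quadratic = do.call(quadraticWell, parameters),
    stop("unknown surface name: ", name))
}

#' Serializable description of a surface
#'
#' Inverse of \code{\link{buildSurface}} for the built-in registry surfaces.
#'
#' @param surface a \code{\linkS4class{PotentialSurface}}.
#' @return list(name, parameters).
#' @export
surfaceSpec <- function(surface) {
  pars <- switch(surface@name,
    muller_brown = list(),
    double_well = surface@parameters,
    proton_relay = list(nCV = surface@dimension,
                        barrierSpec = surface@parameters$barrierSpec,
                        kappa = surface@parameters$kappa),
    quadratic = list(a = surface@parameters$a),
    stop("surface '", surface@name, "' is not serializable"))
  list(name = surface@name, parameters = pars)
}
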