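---
title: "Mapping minimum free energy paths with the string method in collective variables"
author: "MFEPath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping minimum free energy paths with the string method in collective variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MFEPath)
```

## The model

Multi-step chemical transformations — proton relays, phosphoryl
transfers, conformational switches — are described here by a small set of
collective variables (CVs) $\theta[x] = (\theta_1, \dots, \theta_N)$,
scalar functions of the configuration $x$ (interatomic distances,
dihedrals, or raw coordinates).  On the free-energy surface $G(z)$ over
CV values $z$, the minimum free energy path (MFEP) is the curve along
which the mean force $f = -\nabla_z G$ has no component perpendicular to
the path.  Because CVs are curvilinear functions of the Cartesian
coordinates, the stationarity condition carries the metric tensor $M$:

$$[\,M(z)\,f(z)\,]^{\perp} = 0, \qquad
  M_{ij} = \Big\langle \sum_k
  \frac{\partial\theta_i}{\partial x_k}
  \frac{\partial\theta_j}{\partial x_k} \Big\rangle .$$

The string method discretizes the path into $R$ images $z[\alpha]$,
$\alpha \in [0,1]$, and alternates four operations per cycle:

1. **Restrained sampling.** Each image is sampled with every CV
   harmonically anchored at its image value
   ($U = \sum_i k_i(\theta_i - z_i)^2/2$).  The time average of the
   deviation gives the mean-force estimate
   $dG/dz_i = k_i\,\overline{(z_i - \theta_i[x(t)])}$ — the stiff-spring
   estimator, exact in the limit $k \to \infty$ of infinitely stiff
   anchors — and the same trajectory averages the Gram matrix above into
   $M$.  (A literal temperature-prefactor variant of the estimator is
   exposed as `literalPrefactor` in `estimateGradient` for comparison,
   but it is dimensionally inconsistent and off by default.)
2. **Evolution.** Each interior image moves by
   $z' = z + \Delta t\, P\,[M(-\nabla G)]$ with the projector
   $P = I - \hat t\hat t^{\mathsf T}$ removing the tangential component;
   tangents are central finite differences over $\alpha$, normalized in
   the weighted CV metric.
3. **Smoothing.** Interior images are mixed with their neighbours,
   $z'_r = (1-s) z_r + (s/2)(z_{r-1} + z_{r+1})$.
4. **Reparametrization.** Images are redistributed along the polyline to
   equal weighted-Euclidean arc length, $\Delta\alpha = 1/(R-1)$,
   iterated until the segment spread is below $10^{-10}$ relative (one
   linear-interpolation pass is not exactly uniform; iteration makes the
   operation idempotent to tight tolerance).

The free-energy profile follows by integrating the tangential mean force,
$$G(z[\alpha]) = G(z[0]) + \int_0^{\alpha}
  \sum_i \frac{dz_i}{d\alpha'} \frac{dG}{dz_i}\, d\alpha' ,$$
with $dz_i/d\alpha$ and $dG/dz_i$ interpolated by natural cubic splines
through the image values and the trapezoidal rule applied on a dense grid
(75 points including both endpoints; the "count endpoints or intervals"
ambiguity is resolved as *inclusive* and is configurable via `nGrid`).
Natural (zero second derivative) boundary conditions avoid endpoint
overshoot on short strings.

## Defaults and what they mean

| parameter | default | units | rationale |
|---|---|---|---|
| images $R$ | 25 | — | standard protocol; $\Delta\alpha = 1/24$ |
| cycles | 100 | — | standard protocol |
| descent step $\Delta t$ | 0.001 | (CV units)$^2$/energy | see stability notes below |
| smoothing $s$ | 0.01 | — | weak zigzag dissipation |
| RMSD tolerance | 0.01 | CV units | convergence criterion vs the final path |
| restraint $k$ | 100 | energy/(CV unit)$^2$ | holds $\langle\theta\rangle$ within $\sim$0.1 CV units at unit curvature; must exceed $\max|G''|$ along the path |
| temperature (kBT) | 0.5925 | energy | room temperature for kcal/mol-like units |
| burn-in | 25% | — | discard the first quarter of each per-cycle trajectory, keep the rest |
| friction $\gamma$ | 1 | 1/time | overdamped scale |
| sampler timestep | 5e-4 | time | resolves the stiffest mode, $\Delta t_{\mathrm{samp}}(k + V'')/\gamma \ll 2$ |
| trailing window | 10 cycles | — | profile mean and pointwise SD |

Energies are abstract kcal/mol-like units; `samplerConfig(temperature=)`
takes the thermal energy $k_BT$ directly, so any consistent unit system
works.  CV weights default to 1 because the canonical CV sets are bond
distances in a common length unit; mixed-unit CV sets must set weights
explicitly.

The per-image initial configuration of cycle $c+1$ is the final
configuration of cycle $c$ (warm start); cycle 1 starts from
configurations on the initial path.  All per-(cycle, image) sampler seeds
are drawn up front from the master seed, so a full optimization is
bit-for-bit reproducible and any single image trajectory can be re-run in
isolation.

## The sampler

Dynamics are overdamped Langevin integrated by Euler–Maruyama:
$x' = x - \Delta t\,\nabla(V + U)/\gamma + \sqrt{2 k_B T \Delta t/\gamma}\,\xi$.
The MFEP formalism is derived for diffusive CV dynamics, and the
overdamped engine has a provable stationary distribution
($\propto e^{-(V+U)/k_BT}$ as $\Delta t \to 0$), which the test suite
verifies against Gaussian closed forms on quadratic potentials (restrained
mean $kz/(a+k)$, variance $k_BT/(a+k)$).  At `temperature = 0` the same
loop performs deterministic steepest-descent relaxation.  Restraint
forces act on every coordinate a CV reads, via the chain rule — the only
self-consistent choice.  The Euler discretization inflates stationary
variances by a factor $\approx 1/(1-\lambda\Delta t/2)$ with $\lambda$
the combined stiffness, which is why default timesteps keep
$\lambda\Delta t \lesssim 0.1$.

Committor shots reuse the same engine without restraints; because the
dynamics are diffusive there are no momenta to resample, so "fresh
Maxwell velocities" of an inertial shooting protocol have no analogue
here — shots differ only through the noise stream.

## Numerical stability choices

Three numerical facts shaped the optimizer; all were derived from linear
stability analysis and are enforced by defaults rather than left to the
user to discover.

**Per-image step cap.** Explicit steepest descent is linearly stable only
where $\Delta t\,\lambda < 2$ ($\lambda$ = local free-energy curvature).
The Mueller–Brown benchmark has basin curvatures up to $\approx 4\,000$,
so the protocol step $\Delta t = 0.001$ is unstable near its minima.
`optimizeString` therefore caps each image's per-cycle displacement at
0.1 × the mean inter-image spacing (`maxStep = NA` selects this
trust-region-style default).  In unstable regions the capped update
oscillates with bounded amplitude ($\lesssim$ 0.75 × cap $\approx$ 0.008
CV units on Mueller–Brown) instead of diverging, which keeps the trailing
RMSD-to-final well below the 0.01 convergence criterion while leaving
well-conditioned problems untouched.

**Advective zigzag damping.** With finite-difference tangents, the
projected update advects transverse displacements along the string at
speed $\propto |\nabla G|$; forward-Euler advection with central
differences is unconditionally unstable, growing zigzag modes by
$\approx \tfrac12 C^2$ per cycle with Courant number
$C = \Delta t\,|\nabla G| / \text{spacing}$.  The $s = 0.01$ smoothing
damps the fastest mode by $\approx 2s$ per cycle, so the scheme is stable
when $C \lesssim \sqrt{2s} \approx 0.14$ — satisfied by the protocol step
on all shipped benchmarks, and the reason `descentStep` should not be
raised casually.

**Stiff-spring validity.** The estimator holds an image on the path only
if $k$ exceeds the largest (negative) curvature of $G$ along the path;
otherwise images slide off barrier flanks and the profile washes out.
The proton-relay generator therefore spaces its stationary states one CV
unit apart, bounding $|G''| \le 5.8\,\Delta G_{\max}$ ($\approx 105$ for
the default profile), and relay runs use $k = 400$.

## The synthetic benchmark surfaces

`mullerBrown()` is the canonical four-Gaussian 2-D landscape (standard
literature parameters recorded in `parameters`); `doubleWell(h, c)` is
$h(x^2-1)^2 + cy^2/2$ with an exact barrier $h$; `protonRelaySurface()`
embeds a 1-D spine with prescribed alternating stationary free energies
(C$^2$ "smootherstep" interpolation, stationary values hit exactly) in
2–6 coordinates with harmonic transverse confinement.  The default
GAC-like profile has 4 barriers and 3 intermediates at the free-energy
scale typical of enzyme-catalyzed hydrolysis (rate-limiting TS2 = 14.0,
TS3 = 12.0, deep intermediate IM3 = −6.0, mildly exergonic PC = −1.7);
`sacProfileValues()` gives the strongly rate-limited 4-CV variant of a
direct, uncatalyzed-like route (TS2 = 25.0, strongly exergonic
PC = −12.2).

`bruteForceMEP()` is the independent oracle: a minimax (bottleneck) route
on a dense 8-connected energy grid — extracted through the
minimum-spanning-tree bottleneck property — locates the saddle regions;
Newton iteration refines each candidate to a true first-order saddle
(exactly one negative Hessian eigenvalue), and the MEP is assembled from
normalized steepest-descent paths dropped from each saddle into its two
basins, then resampled to uniform arc length.  Nothing in this pipeline
touches the string machinery.

What these surfaces emulate is the *topology and stiffness scale* of a
reaction free-energy landscape: multiple sequential barriers,
kcal/mol-like magnitudes, Boltzmann fluctuations at room temperature.
What they do not emulate: high-dimensional orthogonal degrees of freedom
and their slow relaxation, sampling-time correlations of a real solvated
system, multiple competing reaction tubes, or CV sets whose metric tensor
varies strongly along the path (the shipped benchmarks use identity CVs,
for which $M = I$ exactly).  Green tests here certify the machinery —
estimators, projection, reparametrization, integration, classification —
not the adequacy of any particular CV choice for a real molecule.

## Uncertainties and stationary-state calling

Profiles of the trailing 10 cycles are averaged; their pointwise standard
deviation is the reported uncertainty (`trailingProfile`,
`profileUncertainty`).  `locateStationaryStates` takes interior maxima as
transition states and interior minima as intermediates, suppressing
noise wiggles whose free-energy separation from both flanking stationary
values falls below 2 × the local pointwise SD; a suppressed wiggle is
cancelled against its closest opposite extremum, or removed alone when
its closest neighbour is an endpoint.  With zero attached uncertainty all
strict extrema are kept.

Committor validation launches unbiased shots from configurations of a
restrained transition-state ensemble; basin boxes default to per-CV
half-widths of $3\sqrt{k_BT/k}$ around the terminal CV values (a
restrained-equilibrium width; no external basin criterion is assumed),
and shots hitting the step cap are reported as unresolved rather than
silently assigned.  On the double-well benchmarks the boxes use
half-width 0.3 — the default would overlap the saddle's thermal spread
at kBT ≈ 0.6.

Dihedral conformer analysis clusters monitored angles by k-means on unit
circle embeddings (10 seeded restarts), with k chosen by mean silhouette
width over k = 2..5 and a single cluster declared when no split reaches
silhouette 0.5; wraparound at ±180° is handled by construction.
Monitored coordinates are recorded during sampling without entering the
dynamics, mirroring the separation between string CVs and analyzed
quantities.

## Problem sizes used by the shipped checks

The validation suite runs the full pipeline at desk scale: 25-image
strings, 100 cycles (60 for the six-CV relay surface), 1 000–5 000
sampler steps per image per cycle, 200 committor shots, and 75-point
integration grids.  These sizes were chosen so each end-to-end check
completes in seconds to a couple of minutes while keeping the
statistical error small relative to the quantities asserted (e.g. the
double-well barrier is recovered within twice the trailing-cycle SD, and
relay topology recovery was verified stable across independent master
seeds at 5 000 steps per image).

## Known limitations

* Identity-CV shortcuts: `meanForce = "exact"` mode (the
  zero-temperature, stiff-spring limit) and automatic initial
  configurations require identity CV sets; molecular CV sets must supply
  per-image starting configurations.
* The grid oracle is 2-D only; higher-dimensional benchmarks rely on the
  relay surface's analytic spine.
* No climbing-image or finite-temperature-string variants, no
  Voronoi-tessellation free-energy definition, no reactive-flux rates,
  no nuclear quantum corrections.
* Convergence depends on initialization quality; the optimizer exposes
  initialization (`initString`, path archives, oracle paths) but the
  sensitivity itself is not quantified here.
* The committor engine is diffusive; inertial recrossing statistics are
  outside its scope.
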