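---
title: "Models and methods in mycouptake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mycouptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycouptake)
```

This vignette is the package's account of its science: the two coupled
models, the estimation machinery, the image-analysis conventions, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## The hyphal colonisation model

Tip density $n$ (tips cm$^{-3}$) and hyphal length density $\rho$
(cm hyphae cm$^{-3}$ soil, i.e. cm$^{-2}$) satisfy

$$\partial_t n + v\,\partial_x n = b\,n, \qquad
  \partial_t \rho = n\,v - d\,\rho,$$

on the half-line $x \ge 0$ measured from the root-compartment interface
along the compartment midline, with $n = \rho = 0$ at $t = 0$. Tips are
produced at the interface at a constant rate; dimensional analysis forces
the boundary condition to be a *flux* condition, $v\,n(0, t) = k$ with
$k$ in cm$^{-2}$ s$^{-1}$ (a Dirichlet reading "$v = k$" would equate
quantities of different dimensions). Along characteristics the solution is

$$n(x,t) = \frac{k}{v}\,e^{b x / v}\ \text{ for } x < v t, \qquad
  \rho(x,t) = \frac{n v}{d}\left(1 - e^{-d (t - x/v)}\right),$$

with $\rho = n v (t - x/v)$ when $d = 0$, and both fields exactly zero
ahead of the colonisation front $x = v t$. $|v|$ reduces to $v$ here: no
retraction is modelled. Internal units are cm and s everywhere; readers
convert mm and weeks.

### Numerical cross-check

`solveGrowthNumeric` is a deliberately simple first-order upwind scheme
used as an independent check of the closed form. It marches at the fixed
step $\Delta t = \mathrm{cfl} \cdot \Delta x / v$; at the default
$\mathrm{cfl} = 1$ upwind transport is exact (pure shift), so the
advancing front is not smeared and the scheme's error comes only from the
source-term quadrature, which converges at first order. States are
interpolated linearly onto the requested output times, after which the
causality constraint ($n = \rho = 0$ for $x \ge v t$) is re-imposed — a
known property of the exact solution, not a fit to it. The length-density
update is trapezoidal in the source and implicit in the decay, so
$d > 0$ can never destabilise it. On a $400 \times 400$ grid the maximal
relative deviation from the characteristics solution is about 0.5 %, and
halving $\Delta x$ halves it.

## The soil-phosphorus uptake model

Total P, $c_{TOT} = c_s + \theta c_l = (b + \theta) c_l$ (sorbed plus
dissolved, with buffer power $b$ and mixed-phase volume fraction
$\theta$), obeys

$$\partial_t c_{TOT} = D_{eff}\,\partial_{xx} c_{TOT}
  - 2\pi r_m \lambda_h\, \rho(x,t)\, c_{TOT},$$

with the sink written against $c_{TOT}$ (taken literally from the model
formulation), a Robin root-interface condition
$D_{eff}\partial_x c_{TOT} = F_{max} c_{TOT}$ at $x=0$, and
$c_{TOT} \to c_\infty$ far from the interface. Defaults:

* `D_eff = 1.05e-8` cm² s⁻¹ — the effective diffusivity
  $D\theta f/(\theta + b)$ estimated for this soil.
* `r_m = 5e-4` cm — a 10 µm hyphal diameter, the upper runner-hypha
  range. No value is identified separately from $\lambda_h$: depletion
  profiles constrain only the product $r_m \lambda_h$, so every fit
  reports $r_m$ next to $\hat\lambda_h$.
* `F_max = 0` — hyphal-compartment-only simulations; the root sink is
  exposed for completeness but the fitted quantity here is $\lambda_h$.
* `c_inf` is arbitrary because XRF counts are uncalibrated; all fitting
  is done on far-field-normalised profiles $c_{TOT}/c_\infty$.

### Discretisation and verification

The solver is backward-Euler in time with second-order central
differences in space (finite-volume weights), the Robin condition
discretised to second order through a ghost node, and the far field
realised as a Dirichlet condition at finite $L$. The compartment is
45 mm while the four-week diffusion length $\sqrt{D_{eff} t}$ is about
1.6 mm, so truncation is immaterial once the sink is not pressed against
the boundary; the suite checks insensitivity under doubling of $L$. The
system matrix is an M-matrix, so the discrete solution inherits the
maximum principle ($0 \le c_{TOT} \le c_\infty$) and the comparison
principle (larger $\lambda_h$ never raises $c_{TOT}$), both tested.

Boundary and sink fluxes are accumulated *exactly as discretised* during
the solve, which makes the mass-balance identity
$\Delta M = \text{influx} - \text{efflux} - \text{uptake}$ hold to
round-off for every run — a much sharper audit than quadrature after the
fact. Long-time runs with geometric time steps collapse onto the scheme's
steady state, which matches the analytic two-point boundary-value
solution $c = A e^{\mu x} + B e^{-\mu x}$, $\mu = \sqrt{a/D_{eff}}$, to
better than $10^{-6}$ relative on the grids used in the tests (the
acceptance tolerance is $10^{-4}$). A resolution warning fires when
$\Delta x$ exceeds half the reaction length $1/\mu$.

## Inference

`fitGrowth` minimises $\sum(\rho_{model} - \rho_{obs})^2$ with
Levenberg–Marquardt from `n_starts` (default 16) log-uniform starting
points inside the bounds, because sparse designs make the objective
multi-modal. Strictly positive parameters are optimised in $\log_{10}$
space and zero-floored rates on an upper-bound-scaled linear scale, which
also makes the Gauss–Newton matrix dimensionless; its condition number
above $10^8$ sets the `identifiability_warning` flag. Default bounds
($k \in [10^{-6}, 10^{-2}]$, $v \in [10^{-7}, 10^{-3}]$,
$b, d \in [0, 10^{-4}]$) bracket all reported magnitudes by at least an
order of magnitude. Everything is deterministic given the seed.

Two open design points and how they are resolved:

* **The destruction rate $d$.** Reported parameter tables omit a fitted
  $d$; `fix_d = TRUE` (default) fixes it at zero, `fix_d = FALSE` frees
  it — at the cost of near-flat directions on the sparse three-position,
  two-time design, which the diagnostics flag.
* **Pooling.** Replicates can be pooled into one fit (`fitGrowth` on the
  full set) or fitted separately and summarised as mean ± sample SD
  (`fitGrowthReplicates` + `aggregateReplicates`); the mean ± SD style of
  published tables suggests the latter, so both are provided and the
  per-replicate route is used by `runStudy`. Per-replicate $R^2$ is
  averaged the same way.

`fitUptake` is a one-parameter bounded minimisation for $\lambda_h$: a
log-spaced scan (plus the $\lambda_h = 0$ endpoint) brackets the optimum
and golden-section/parabolic refinement finishes it — derivative-free,
deterministic, and robust to the many orders of magnitude spanned. The
forward model and the profile generator default to identical grids
(361 spatial points, 60 time steps over [0, 4.5] cm), so noise-free
round trips recover planted values to well under 1 %. Both a pore-space
(tomography-visible) and a total length-density field can drive the fit;
since only hyphae in air-filled pores are visible to tomography, the
pore-based $\rho$ is smaller and the fitted $\hat\lambda_h$
correspondingly larger — the two bracket the true rate.

## Skeleton morphometrics

`voxelSkeletonToGraph` uses 26-connectivity throughout. Nodes are voxels
with a neighbour count other than 2; adjacent junction voxels are merged
into one node at their centroid (deterministically), and isolated loops
are broken at their smallest-index voxel. Arc length is the sum of
inter-voxel Euclidean steps (1, $\sqrt2$, $\sqrt3$ voxel edges).
Conventions the field does not standardise are fixed as:

* **Tortuosity** is the arc–chord ratio (branch path length over
  endpoint distance), minimum 1 — the standard filament convention.
* **Orientation** uses the branch end-to-end vector (not per-segment
  tangents) against the compartment midline, folded to $[0, 90]°$
  because a filament has no direction. Angles are per-branch, not
  per-cluster averages.
* Zero-chord branches (closed loops) are excluded from both, with a
  count reported.

Under an isotropic orientation distribution the expected folded angle is
$E[\arccos|u_z|] = 1$ rad $\approx 57.3°$, which the suite reproduces by
Monte Carlo at $n = 10^4$.

## Correlative chemistry

The 3D Euclidean distance transform (compiled, separable lower-envelope
algorithm) is exact, and tested against an all-pairs brute force. Phase
labels follow the three-phase reading of tender-X-ray maps: `air` below a
total-signal threshold, `primary` above an Si threshold (which also
guards against Si signal overflow into P and Al channels), `mixed`
otherwise. Distance classes are inclusive at 50 µm ("within") and
exclusive at 200 µm ("further than"). Class statistics restrict to
mixed-phase pixels and use the pooled-variance two-sample t-test by
default (the generic two-sample form; Welch is an option) plus the
two-sample Kolmogorov–Smirnov test. Elemental high/low thresholds default
to means over the close class (`from-close-means`), never to hard-coded
count values, because count-space and concentration-space thresholds are
not interconvertible without a calibration that raw maps do not carry.
Distance histograms default to 100 µm bins, signal histograms to
1000-count bins.

## XANES linear-combination fitting

Spectra are interpolated to a common grid and edge-step normalised
(linear pre-edge subtraction, unit post-edge step). `lcfFit` solves a
non-negative least-squares problem with the sum-to-one constraint imposed
through a heavily weighted augmented row *inside* the solve —
renormalising afterwards would bias residuals. The constraint is honoured
to $10^{-6}$ and fits are idempotent. Energy alignment (edge-shift
fitting) is deliberately omitted: beamline spectra are assumed calibrated
against standards; that is a documented limitation. A near-singular
standard library triggers a condition-number warning and a small ridge
that keeps the active-set solve defined. Species grouping for trend
summaries is configuration-driven, defaulting to reduced = thiols,
oxidized = sulfonate + sulfate.

## What the synthetic data emulate — and what they do not

Every generator takes one explicit seed, attaches its planted truth to
its output, and regenerates identically from (seed, configuration).

* `genLengthDensityObs` mirrors the compartment design (13.5/28.5/43.5 mm
  at 2 and 4 weeks, three replicates) with mean-one multiplicative
  lognormal noise, default CV 10 % — the magnitude of published
  error bars on such profiles.
* `genSkeleton` grows persistent random-walk tips in a cylinder with
  per-step branching/stopping. The `inoculated` preset (persistence 0.95,
  branch probability 0.01) against `control` (0.80, 0.06) reproduces the
  observed morphological contrast: straighter, less branched AMF hyphae
  versus bushier native fungi. The test domain is a reduced cylinder
  (radius 60 µm, length 220 µm at 1.6 µm voxels) so the suite stays fast;
  dimensions are configurable up to compartment scale.
* `genXRFMaps` plants a three-phase plane with distance-coupled P
  (default amplitude 0.35 on a 60 µm scale, calibrated once in a pilot so
  the close/far mean ratio is ≈ 1.24, matching the reported count
  contrast), negatively coupled Al, neutral S, and 20 % multiplicative
  noise, on a 160² map at 6 µm pixels over a thin 3D slab so the real
  distance transform and plane registration are exercised. A `step`
  coupling profile plants exact mean contrasts for power studies.
* `genXANES` builds arctan-edge-plus-Gaussian standards at the S K-edge
  peak positions 2473 / 2480.5 / 2482 eV (thiol / sulfonate / sulfate),
  and mixtures with white noise at SNR 50 by default.
* `genPProfile` forward-simulates the uptake model and samples the
  normalised profile with additive noise.

None of this simulates soil micro-structure physics, X-ray contrast
formation, detector response, or registration error: passing tests show
the *analysis chain* is correct and well-conditioned under realistic
designs and noise, not that segmentation or calibration of real imagery
would succeed. Real data enter through the documented CSV/SWC/matrix
readers instead.

## The end-to-end replica

`runStudy` chains the stages (simulate → fit growth per replicate →
simulate and fit the depletion profile with pore and total densities →
map statistics → speciation trend) under one master seed, with per-stage
JSON caching keyed by a configuration hash. The report contains no
timestamps, so one configuration yields byte-identical reports. Default
problem sizes (10-position Monte-Carlo designs, 160² maps, 100-seed
contrasts in the acceptance tests) were chosen so the whole suite runs in
a few minutes while leaving every statistical check comfortably powered.

## Known limitations

* 1D transport only; no water flow, no sorption beyond first-order
  buffering, no pellet-dissolution kinetics.
* $\lambda_h$ and $r_m$ are not separately identifiable from profiles.
* XANES fitting assumes calibrated energies and a user-supplied standard
  library; no per-pixel speciation maps.
* Skeleton metrics presume an upstream segmentation/thinning; only thin
  (1-voxel) skeletons are accepted.
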