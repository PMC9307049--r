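# mycouptake

Quantitative tools for studying how arbuscular mycorrhizal (AMF) hyphae
colonise soil and deplete phosphorus around plant roots, combining PDE
modelling with correlative 3D image chemometrics.

Root systems trade carbon for phosphorus through fungal partners whose
hyphae extend past the root depletion zone. Measuring how fast those hyphae
take up P requires linking three very different measurements made on the
same soil volumes: hyphal length-density profiles (from tomography or
destructive counting), X-ray fluorescence (XRF) elemental maps, and X-ray
absorption near-edge (XANES) spectra. This package implements that whole
chain on a common set of containers, together with seeded synthetic-data
generators so every stage can be exercised and verified without any
imaging data.

## The models at the core

**Hyphal colonisation.** Tip density `n` (tips cm⁻³) and hyphal length
density `ρ` (cm hyphae cm⁻³) obey

    ∂t n + v ∂x n = b n,        ∂t ρ = n v − d ρ,

with zero initial condition and a constant tip flux `v·n(0,t) = k` at the
root interface. `k` (cm⁻² s⁻¹) is the root tip-production flux, `v`
(cm s⁻¹) the elongation speed, `b` (s⁻¹) the net branching rate and `d`
(s⁻¹) the net destruction rate. The package solves this exactly by the
method of characteristics (`solveGrowthClosedForm`) and numerically by a
verified upwind scheme (`solveGrowthNumeric`), and estimates `(k, v, b, d)`
from length-density observations by bounded multi-start least squares
(`fitGrowth`).

**Soil-P uptake.** Total soil phosphorus `c_TOT = c_s + θ c_l = (b + θ) c_l`
moves by effective diffusion and is consumed at hyphal surfaces:

    ∂t c_TOT = D_eff ∂xx c_TOT − 2π r_m λ_h ρ c_TOT,

with a Robin root-interface sink `D_eff ∂x c_TOT = F_max c_TOT` at `x = 0`
and `c_TOT → c∞` in the far field. `λ_h` (cm s⁻¹) is the hyphal P-uptake
rate coefficient; only the product `r_m λ_h` is identified, so the hyphal
radius `r_m` is always reported alongside it. The solver
(`solveUptake`) is a backward-Euler finite-volume scheme whose discrete
mass balance closes to round-off (`massBalance`), and `fitUptake`
estimates `λ_h` from far-field-normalised P depletion profiles.

**Image chemometrics.** `voxelSkeletonToGraph`/`computeMetrics` turn voxel
skeletons into branch graphs and the standard morphometric panel (length
density, clusters, branch counts, arc–chord tortuosity, orientation to the
compartment midline); `distanceTransform3D` is an exact Euclidean distance
transform; `classifyPhases`, `distanceClasses`, `classStatistics` and
`elementalClasses` implement the close/far-from-hyphae statistics of XRF
maps; `lcfFit` performs non-negative, sum-to-one linear-combination
fitting of XANES spectra and `speciationVsDistance` aggregates speciation
fractions along distance. `runStudy` chains everything into a
deterministic end-to-end synthetic study.

## Worked example

Simulate the compartment observation design (positions 13.5/28.5/43.5 mm,
weeks 2 and 4, three replicates, 10 % multiplicative noise), fit each
replicate and aggregate; then recover a planted uptake rate from a noisy
depletion profile:

```r
library(mycouptake)

truth <- growthParams(k = 1.02e-4, v = 2.06e-5, b_branch = 5.45e-6)
obs   <- genLengthDensityObs(truth, replicates = 3, seed = 42)
agg   <- aggregateReplicates(fitGrowthReplicates(obs, n_starts = 8, seed = 1))
agg
#> AggregateFit over 3 replicate fits (mean +/- SD)
#>   k         = 1.09 x 10-4 +/- 1.44 x 10-5
#>   v         = 2.32 x 10-4 +/- 3.68 x 10-4
#>   b_branch  = 3.7 x 10-5 +/- 5.46 x 10-5
#>   d         = 0 +/- 0
#>   r2        = 9.87 x 10-1 +/- 1.61 x 10-2

up   <- uptakeParams(lambda_h = 3.26e-6)          # planted truth
prof <- genPProfile(up, 50, noise_sd = 0.01, seed = 42)
fitUptake(prof$profile, 50, up, t_final = 4 * 7 * 24 * 3600)
#> FitResult
#>   lambda_h  = 3.24326e-06
#>   RSS = 0.00409998, R^2 = 0.7806, starts = 26, converged = TRUE
```

The aggregate recovers `k` within the replicate scatter (`r2 ≈ 0.99` per
fit); `v` and `b` carry wide SDs because the sparse six-point design
identifies them weakly — exactly the behaviour flagged by the fit
diagnostics. The uptake fit recovers the planted
`λ_h = 3.26 × 10⁻⁶ cm s⁻¹` to half a percent from a 1 %-noise profile.

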