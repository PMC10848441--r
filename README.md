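# camsnap

Occupancy and density estimation for camera-trap surveys, without individual
identification.

Long-term camera-trap monitoring programmes (the package's reference design is
a 16 km² grid of 64 cameras spaced ~500 m apart, run over summer seasons) want
two population metrics per species: how much of the landscape it uses
(**occupancy**) and how many individuals there are per unit area (**density**).
Both must correct for imperfect detection, and for unmarked animals neither can
rely on recognising individuals. `camsnap` implements the two standard answers
and everything needed to feed them from Camtrap DP or Darwin Core Archive
tables — or from a synthetic scenario generator with known truth, so every
stage is testable end to end.

## The models

**Single-season occupancy.** Daily detection histories (one record per
species, camera location and day) are summarised by N surveyed sites, T
occasions, n_t sites with a detection at occasion t, and n. sites with at
least one detection. The likelihood maximised (directly, on the logit scale,
with multi-start quasi-Newton and a Newton polish) is the zero-inflated
binomial

    L(ψ, p) = [ ψ^n. ∏_t p_t^{n_t} (1 − p_t)^{n. − n_t} ]
              × [ ψ ∏_t (1 − p_t) + (1 − ψ) ]^{N − n.}

with ψ the occupancy probability and p the per-occasion detection
probability (constant by default, per-occasion optionally). Missing effort
(camera not operational) is handled site-wise; the balanced form above is
recovered exactly when nothing is missing. Standard errors come from the
inverse observed information via the delta method, and a brute-force grid
oracle (`oracleGridFit`) is shipped for verification.

**Camera-trap distance sampling (CTDS).** Each camera is a point-transect
observer watching a sector of angle θ out to a truncation distance w, with
time discretised into snapshot moments t seconds apart. With n_k snapshot
observations at camera k during its operational time T_k,

    D̂ = 2 t Σ_k n_k / ( θ w² a Σ_k T_k P̂ )

where P̂ is the probability of detecting an available animal within w
(half-normal or hazard-rate detection function with up to two cosine
adjustments, fitted to the radial distances and AIC-model-averaged) and `a`
is the activity level — the proportion of time animals are active, estimated
as 1/(2π max f̂) from a von Mises kernel density f̂ of the observation times
of day. The CV composes by the delta method:

    CV(D̂)² = CV(ε̄)² + CV(p̂)² + CV(a)²

with the encounter-rate CV from the effort-weighted between-camera variance
estimator, the detection CV from the AIC-weighted model set, and the
activity CV from a nonparametric bootstrap.

## Worked example

Simulate the default scenario (64 cameras, 150 days, θ = 0.73 rad, w = 10 m,
t = 2 s, true density 5 / km², half-normal detection with σ = 4 m, activity
level 0.5) and run the full CTDS chain:

```r
library(camsnap)

sc   <- defaultScenario(seed = 42L)
rep1 <- simulateCtds(sc, nReplicates = 1, seed = 42L)[[1]]

avg <- fitDetectionModelSet(rep1$distances, w = sc@w)
act <- fitActivity(rep1$times, B = 199, seed = 42L)
den <- estimateDensity(rep1$counts, rep1$efforts, avg, act,
                       t = sc@t, theta = sc@theta, w = sc@w)
den
#> CTDS density: 5.489 individuals / km^2 (CV 3.4%)
#>   t = 2 s, theta = 0.73 rad, w = 10 m, a = 0.487, P = 0.2893, eps = 182.9062
```

The estimate sits within the sampling error of the true 5 / km²: the fitted
model average found P̂ = 0.289 (truth 0.306 for σ = 4, w = 10) and the
activity level 0.487 (truth 0.5). The same scenario's occupancy side:

```r
sim <- simulateOccupancy(N = 64, T = 10, psi = 0.6, p = 0.15, seed = 42L)
fitOccupancy(sim$history)
#> Single-season occupancy fit (constant p)
#>   psi = 0.5834 (SE 0.1055)
#>   p   = 0.1205 (SE 0.0244)
#>   logLik = -158.9376, N = 64, T = 10, naive = 0.422
```

Note ψ̂ = 0.58 against a naive occupancy of 0.42 — the correction for
imperfect detection at work. Finally, comparing per-species occupancy with
density over four species with perfectly concordant ranks:

```r
compareOccupancyDensity(c(0.92, 0.74, 0.31, 0.18), c(5.88, 2.59, 0.30, 0.15))
#> $rho
#> [1] 1
#> $p
#> [1] 0.08333333   # exact: 2 of the 4! rank permutations reach |rho| = 1
```

Real data enter through `readCamtrapDP()` (deployments + observations CSV) or
`readDwcArchive()` (event + occurrence tables); `groupIntoSequences()` turns
raw image timestamps into occurrence events; `runOccupancyReport()` and
`runDensityReport()` produce the per-species tables.

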