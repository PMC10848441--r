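---
title: "Methods: occupancy and camera-trap distance sampling in camsnap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy and camera-trap distance sampling in camsnap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camsnap)
```

`camsnap` estimates two complementary population metrics from camera-trap
records of unmarked animals: site occupancy corrected for imperfect
detection, and absolute density by camera-trap distance sampling (CTDS).
This vignette is the package's account of the underlying models, the choices
made where the design was genuinely open, and what the shipped validation
does and does not demonstrate.

## 1. Data model

The internal model is deliberately minimal: a deployment table (one camera at
one location over one interval, with coordinates, a trigger-sensitivity label
and the camera's horizontal angle of view) and an occurrence table (one row
per image sequence, with a timestamp, a taxon — or the sentinels `blank` /
`unknown` — an image count, and optional radial distances in metres).
`readCamtrapDP()` and `readDwcArchive()` map the two public standards onto
it; `writeCamtrapDP()` inverts the former exactly, and the round trip is
tested to identity. Timestamps are normalised to UTC on ingest; analyses
that need the local solar day (daily occasions, times of day) recover it
through a configurable fixed offset, default `+01:00` for the reference
study area. A fixed offset ignores daylight-saving transitions; for season-long
summer deployments this shifts a minority of records by one hour, which is
immaterial for daily occasions and, because the activity estimator is exactly
rotation-invariant (Section 5), immaterial for the activity level too.

Image-to-sequence grouping (`groupIntoSequences()`) chains images within a
deployment whenever consecutive timestamps are at most `gapSeconds` apart.
The grouping interval of the upstream acquisition software is rarely
published; the default is 120 s, a common camera-trap convention, and every
downstream consumer takes the parameter explicitly.

## 2. Single-season occupancy

Daily detection histories (`buildDetectionHistory()`) hold one record per
species, site and local day: 1 for a detection, 0 for an operational camera
without one, `NA` where no camera ran. A partial first or last day counts as
an occasion if the camera ran any part of it; multiple deployments at one
location are unioned into one site row, since sites are locations, not
camera units.

The likelihood is the classical zero-inflated binomial: sites are occupied
with probability $\psi$; at occupied sites, detection on occasion $t$ is
Bernoulli($p_t$). With $N$ sites, $T$ occasions, $n_t$ sites detected at
occasion $t$ and $n.$ sites ever detected,

$$L(\psi, p) = \Big[\psi^{n.}\prod_{t=1}^{T} p_t^{n_t}(1-p_t)^{n.-n_t}\Big]
\times \Big[\psi\prod_{t=1}^{T}(1-p_t) + (1-\psi)\Big]^{N-n.}.$$

Two points deserve record. First, the exponent on $(1-p_t)$ is $n.-n_t$:
detected sites contribute non-detection factors only for their own missed
occasions, which is the only dimensionally consistent reading of the
standard form. Second, `occupancyLoglik()` actually evaluates the
likelihood site-wise — a site with a detection must be occupied; a site
without one is either occupied-and-missed or unoccupied — so occasions with
missing effort simply contribute no factor (missing-at-random handling).
The balanced closed form above is recovered exactly when no cell is
missing, and the tests verify both this equality and agreement with a
brute-force enumeration of the latent occupancy states.

**Fitting.** `fitOccupancy()` maximises on the logit scale with BFGS from
five deterministic starts (naive-based, central, and three spread starts),
keeps the best, then applies damped Newton steps until the gradient norm
falls below $10^{-8}$ — quasi-Newton alone can stall in the flat $\psi$
direction when detection is weak. Standard errors are delta-method
transforms of the inverse observed information; estimates beyond logit
$\pm 8$ are flagged `boundary` and their SEs set to `NA`, since the
information matrix is meaningless there. Histories with zero or all
detections return the boundary fit with a warning rather than an error.
Constant $p$ is the default (one reported $p$ per species-year); a
per-occasion $p_t$ structure is available.

**Oracle.** `oracleGridFit()` is an independent check, not a fitting
routine: it evaluates the likelihood on a uniform grid over $(0,1)^2$ via
the sufficient statistics and, optionally, re-grids over $\pm 3$ grid steps
around the incumbent maximum. The $\pm 3$-step window matters: on the
anti-correlated $\psi$–$p$ ridge the discrete argmax of a coarse pass can
sit a few cells away from the continuous maximiser, and a $\pm 1$ window
can trap the refinement. With two refinement passes the oracle locates the
MLE far below $10^{-4}$, the agreement tolerance the test suite uses.

Fits with fewer than three detected sites are flagged unreliable in the
report tables rather than suppressed; the threshold mirrors the common
practice of shading out species-years with too few observations.

## 3. Detection functions and model averaging

Radial distances (within a truncation distance $w$, by default the species'
95th percentile — published analyses state that a truncation was applied but
rarely its value) enter a point-transect likelihood with radial density
$f(x) = g(x)\,x / \int_0^w g(u)\,u\,du$. Keys: half-normal
$g(x)=\exp(-x^2/2\sigma^2)$ and hazard-rate $g(x)=1-\exp(-(x/\sigma)^{-b})$
with $b \ge 1$ (parameterised $b = 1 + e^\eta$), each with 0–2 cosine
adjustment terms $1 + \sum_j a_j\cos(j\pi x/w)$, rescaled so $g(0)=1$ and
clipped to $[0,1]$. Field distances are read off reference markers and are
coarse, so the default likelihood bins distances into 1 m bins
(multinomial over bin integrals); the exact-distance likelihood is
available and the two agree closely in tests. Fits on fewer than 10
observations are refused. Diagnostics warn when the adjusted series leaves
$[0, 1.2]$ before rescaling or when the adjusted $g$ is non-monotonic.

Integrals of $g(u)u$ use a fixed Gauss–Legendre rule: 101 nodes for narrow
(per-bin) ranges, 401 for the full $(0,w)$ range, where the hazard-rate
shoulder needs the finer rule; the tests require agreement with adaptive
quadrature to $10^{-6}$, and the half-normal case has a closed form
($P = 2(1-e^{-1/2}) \approx 0.7869$ at $\sigma = w$) asserted to the same
tolerance.

The candidate set (`fitDetectionModelSet()`) is half-normal and hazard-rate
with 0, 1 and 2 cosine terms — six models. Akaike weights
$w_i \propto \exp(-\Delta_i/2)$ average the member detection probabilities,
and the averaged CV uses the standard model-averaging combination

$$\mathrm{cv}_P^2 = \sum_i w_i\big(\mathrm{cv}_i^2 + (P_i-\bar P)^2/\bar P^2\big),$$

which reads "the CV of all models weighted by AIC" in the only way that
accounts for both within-model sampling error and between-model spread. The
member sampling CVs come from the delta method on each fit's observed
information by default — `bootstrapCv()` offers the nonparametric
alternative (999 iterations by convention) where runtime permits.

## 4. Encounter rate, density and uncertainty

The encounter rate is observations per camera,
$\bar\varepsilon = \sum_k n_k / K$, with variance from the effort-weighted
between-camera estimator used in distance sampling
($\widehat{\mathrm{var}} = \frac{K}{K-1}\frac{1}{K^2}\sum_k (T_k/\bar T)^2
(n_k \bar T/T_k - \bar\varepsilon)^2$). A variance needs $K \ge 2$; the
density point estimate does not, and a single-camera call carries an `NA`
encounter CV instead.

Density follows the snapshot-moment estimator

$$\hat D = \frac{2t\sum_k n_k}{\theta w^2 \, a \sum_k T_k \hat P},$$

computed per m² and reported per km². The activity level $a$ enters the
denominator as effective effort $a\,T_k$: animals are only available while
active, so halving $a$ doubles $\hat D$ — the placement consistent with the
delta-method CV composition
$\mathrm{CV}(\hat D)^2 = \mathrm{CV}(\bar\varepsilon)^2 +
\mathrm{CV}(\hat p)^2 + \mathrm{CV}(a)^2$ (`deltaCV()`), which treats the
three components as independent multiplicative errors.

Two constants are survey properties, not estimables: the snapshot interval
(default $t = 2$ s) and the camera's horizontal angle of view (default
$\theta = 0.73$ rad, 42°, a typical passive-infrared trigger). Both are
plain parameters everywhere; the density scales linearly in $t$ and
$1/\theta$, so misstating them rescales $\hat D$ without affecting CVs.

## 5. Activity level

Observation times of day (one per occurrence event — the first image, the
same observation unit used elsewhere) are mapped to the circle and smoothed
with a von Mises kernel. The activity level is $a = 1/(2\pi \max\hat f)$:
if all animals are active at the daily peak, the ratio of mean to peak
density is the proportion of time active. The estimator assumes full
availability at the peak; for species active around the clock it
approaches 1.

Bandwidth: Taylor's rule-of-thumb concentration
$\big(3n\hat\kappa^2 I_2(2\hat\kappa) / (4\sqrt\pi I_0(\hat\kappa)^2)\big)^{2/5}$,
with one amendment: $\hat\kappa$ comes from the first *or second*
trigonometric moment of the data, whichever is more concentrated.
Crepuscular species have near-antipodal bimodal activity whose first moment
nearly vanishes; the raw rule would then smooth both peaks flat, while the
doubled-angle moment sees them. The density is evaluated on a 512-point
grid — fine enough that the max-finding error is far below other
uncertainty — by binned FFT convolution, with the grid anchored at the
circular mean of the data so that the estimate is *exactly* invariant under
rotation of all times (the tests assert invariance to $10^{-9}$; an
unanchored binned estimator would only be approximately invariant). An
exact kernel-mixture mode exists for cross-checking the binned one.

The bootstrap CV (999 iterations by convention) resamples times with
replacement, keeping the full-data bandwidth — standard kernel-bootstrap
practice that also avoids re-selecting a bandwidth on every resample.
Estimation is refused below 20 times (pool first) and for degenerate
all-identical times. Known limitation: the kernel smooths sharp activity
peaks, so $a$ is biased upward when activity is strongly concentrated; the
validation quantifies this against closed-form mixtures and the effect
shrinks as $n^{-2/5}$.

## 6. The synthetic scenario generator

`defaultScenario()` mirrors the reference survey: 64 cameras, 150-day
deployments, $\theta = 0.73$, $w = 10$ m, $t = 2$ s; truth defaults are
density 5 / km², half-normal detection with $\sigma = 4$ m, activity level
0.5 (a single 06:00–18:00 window), occupancy $\psi = 0.6$ with daily
$p = 0.3$. `simulateCtds()` draws, per camera and snapshot moment, presence
in the sector with probability $D\theta w^2/2$, availability with
probability $a$, a radial position from the uniform-in-area density
$2x/w^2$, and detection with probability $g(x)$ — i.i.d. across snapshots.

This independence is deliberate: the moment-based estimators under test are
exactly unbiased under it, so recovery tests have exact targets. What the
generator therefore does *not* emulate: animal-movement autocorrelation
(bursts of snapshots from one passing animal), group travel,
distance-measurement error, or under-detection close to the camera. A
`clustered = TRUE` mode multiplies presences into geometric bursts — same
mean, inflated between-camera variance — to stress variance estimators
only. Passing recovery tests consequently demonstrate correctness of the
estimators under their own assumptions, not robustness to movement
correlation in real data, where the encounter-rate CV carries the burden.

`emitCamtrapDP()` writes any simulated replicate as a Camtrap DP pair
(8×8 grid at 500 m spacing, optional blank sequences at a configurable
rate), closing the loop: generated data exercise the same I/O, grouping and
reporting paths as field data.

## 7. Pipeline and comparison

`runOccupancyReport()` fits every species-year; `runDensityReport()` runs
truncation → six-model fit → AIC average → activity → encounter rate →
density → delta CV per species, skipping species with fewer than ten
distances. Display tables round as conventionally printed (densities to two
decimals, CVs to whole percent) while a `_full.csv` sidecar keeps full
precision. `compareOccupancyDensity()` computes Spearman's rank correlation
with an exactly enumerated permutation p-value for $n \le 9$ pairs
(two-sided, average ranks on ties) and the classical approximation above;
the exact route is cross-checked against `stats::cor.test` in the tests.
Configuration is plain YAML (`readAnalysisConfig()`), validated against
module preconditions before any work starts, and every stochastic step
takes an explicit seed, so a config plus seed determines every output byte.

## 8. Validation problem sizes

The shipped validation uses: occupancy parameter recovery with 200
replicates at $N = 500$, $T = 10$ ($\psi = 0.6$, $p = 0.3$); oracle
agreement on 20 random interior fixtures at grid size 1000 with two
refinements; CTDS end-to-end recovery with 100 replicates of the default
scenario (delta-method CV compared against the empirical between-replicate
CV); activity benchmarks at $n = 5000$ (uniform and 6-hour-window truth)
and $n = 150000$ for the sharp bimodal mixture, where kernel smoothing bias
is the binding constraint; and Poisson calibration of the encounter-rate
variance over 500 draws at 60 cameras. These sizes were chosen so each
check's Monte-Carlo error sits well below the tolerance it asserts.

## 9. Known limitations

* No covariate link models beyond a binary stratification, no dynamic
  (multi-season) occupancy, no spatial autocorrelation correction — at
  500 m spacing, site independence is doubtful and $\psi$ should be read
  as an index.
* Left-truncation (under-detection near the camera, seen for some species)
  is flagged by the monotonicity diagnostic, not corrected.
* One pooled detection function per species; no camera-specific $\hat P_k$.
* The delta-method CV treats encounter rate, detection and activity errors
  as independent; shared dependence (e.g. activity timing affecting both
  availability and encounter rate) is not modelled.
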