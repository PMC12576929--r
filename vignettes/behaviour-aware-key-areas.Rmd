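---
title: "Behaviour-aware key areas from central-place-forager tracks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behaviour-aware key areas from central-place-forager tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behavKBA)
```

## The problem

Marine spatial planning for colonial seabirds usually starts from
density: pool a colony's GPS fixes, smooth them into a kernel
utilisation distribution (UD), and call the 50% isopleth the "core
area". That procedure is blind to behaviour. A commuting corridor used
by every bird in the colony can carry a small share of total fix
density — birds cross it quickly — and be cut out of the core area even
though collision or displacement risk concentrates exactly there. This
package implements the behaviour-aware alternative for central-place
foragers: classify each at-sea fix as resting, foraging or transiting
with a hidden Markov model (HMM), build behaviour-specific UDs, measure
how much of each behaviour the conventional all-behaviour core area
captures, and delineate population-level key areas per behaviour.

Because multi-colony seabird tracking data are typically
access-restricted, the package ships a synthetic track generator with
known behavioural ground truth. The generator is a first-class module:
its defaults define the study conditions under which every validation
in this package is run.

## The movement model

At-sea movement is summarised per trip as step lengths $l_t$ (planar km
per 100-s interval) and turning angles $\phi_t$ (radians). A 3-state
HMM emits, in state $s$,

$$l_t \sim \mathrm{Gamma}(\mu_s, \sigma_s), \qquad
  \phi_t \sim \mathrm{vonMises}(m_s, \kappa_s),$$

with the gamma parameterised by mean and standard deviation
(shape $=(\mu_s/\sigma_s)^2$, rate $=\mu_s/\sigma_s^2$), and hidden
states following a Markov chain with transition matrix $\Gamma$ and
initial law $\delta$. States are labelled by ascending step mean:
resting < foraging < transiting.

Default emission parameters are the colony-weighted grand means
estimated for breeding black-legged kittiwakes:

| state | step mean (km) | step sd (km) | turn $m$ (rad) | turn $\kappa$ |
|---|---|---|---|---|
| resting | 0.07 | 0.04 | 0.00 | 10.77 |
| foraging | 0.23 | 0.26 | 0.03 | 0.34 |
| transiting | 0.98 | 0.32 | 0.00 | 9.84 |

The foraging turn mean is kept at its reported 0.03 rad even though it
is effectively zero. These values are a species-and-deployment-specific
default (100-s GPS sampling on a ~0.4 kg gull); they must be overridden
for other systems.

No transition matrix is reported for kittiwakes, so the generator
constructs one: $\Gamma_{ij} = c\,\pi_j$ for $i \ne j$ and
$\Gamma_{ii} = 1 - c(1-\pi_i)$, which makes the target behavioural
proportions $\pi = (0.23, 0.48, 0.29)$ the exact stationary
distribution for any dwell scale $c$. The default $c = 0.1$ gives mean
dwell times of roughly 10–13 fixes (17–22 min at 100-s sampling),
biologically plausible bout lengths for a surface-feeding seabird. This
$\Gamma$ is a constructed stand-in, not an empirical estimate; only its
stationary law is data-anchored.

### Fitting and decoding

`fit_hmm()` maximises the scaled-forward log-likelihood directly
(quasi-Newton on a working scale: log for positive parameters,
multinomial logit for $\Gamma$ rows and $\delta$), rather than using
EM — direct MLE makes the box constraints trivial and matches common
practice for step/turn HMMs. Five seeded restarts from jittered initial
values guard against local optima; initial values default to the table
above and should be user-supplied for other species. Exactly-zero steps
have no gamma density; if any occur, a per-state zero mass is estimated
(standard zero-inflation for step-length HMMs). Series are split at
temporal gaps exceeding 3 nominal sampling intervals so a data gap is
never treated as one step. `viterbi_decode()` returns the jointly most
probable state path, with ties broken toward the lowest state index for
reproducibility. Both recursions are validated in the test suite
against exhaustive enumeration over all $3^T$ paths for short series.

Whether to pool colonies into one fit or fit per colony is left to the
caller; the pipeline default is per colony, since reported emission
estimates vary (a little) among colonies and a per-colony fit is the
conservative choice. Sampling is treated as nominally regular (the
data-collection design here), so steps are per-interval displacements
and no interpolation is applied by default; `interpolate_track()`
supports the sensitivity analysis of resampling to an exact 100-s grid.

## Trips, projection and distances

Trips are delimited by colony buffers: fixes within the 0.5 km inner
buffer are colony attendance and never enter a trip; a trip closes when
the bird dwells inside the 1 km return buffer for at least 14 min; a
trailing excursion with no qualifying return is flagged incomplete and
excluded from analysis. "Within a buffer" is closed
(distance $\le$ radius); dwell time is the elapsed time between the
first and last fix of a buffer visit, a single fix counting as one
sampling interval. Trips need at least 5 at-sea fixes (a configurable
guard against GPS jitter; the underlying field protocol states no such
minimum, so this is a documented choice). Colonies enter the analysis
only with $\ge 8$ individuals holding complete trips and $\ge 3$ tagged
individuals in every tracked year.

All planar work happens in a Lambert azimuthal equal-area projection
centred on each colony (spherical form, Earth radius 6371.0088 km,
coordinates in km). Equal-area is non-negotiable because the headline
outputs are areas in km²; a local azimuthal centre keeps distance
distortion below 0.5% at the $\le$300 km ranges relevant here (property
tested against the haversine). Great-circle distances use the haversine
with the same radius.

## Utilisation distributions and isopleths

Kernel UDs use an isotropic bivariate Gaussian kernel with standard
deviation $h$ per axis on a regular grid. The bandwidth is the
central-place "mag" rule: $h = \ln(\text{median per-trip maximum
range in km})$, floored at 0.5 km (a median range under $e$ km would
give $h \le 0$), shared across a colony's individuals so their
isopleths are comparable. The grid covers the points' bounding box
expanded by max(20% margin, $3h$) — the larger margin prevents 95% UDs
from clipping — with cell size $h/10$ by default, capped at 2000 cells
per axis. The density is renormalised on the grid, so grid mass is
exactly 1.

The $p$% isopleth accumulates cells by descending density until mass
$\ge p$; cells tied with the threshold density are all included
(deterministic and level-conservative — the area never under-covers the
level; for a perfectly uniform surface this selects the whole support).
Area is the selected-cell count times cell area, which makes the
downstream capture proportions and population grids exactly additive;
polygon boundaries are the dissolved cell outlines. For a single point
the $p$% area has the closed form $2\pi h^2 \ln\frac{1}{1-p}$, which
the tests use as an oracle (agreement within 3% at cell size $h/10$;
the residual error is grid truncation at the $3h$ margin, not cell
resolution).

Per individual, five UDs share one grid and one $h$: all fixes, each
decoded behaviour, and a "sample" control — a uniform random subsample
of all fixes sized to the rarest behaviour, which separates
behaviour-specific geometry from sample-size effects. Subsets with
fewer than 10 fixes are skipped with a logged reason.

## Capture proportions and the comparison models

The capture proportion of behaviour $b$ for one individual at level $p$
is the area share of the behaviour isopleth lying inside the
all-behaviour isopleth, computed exactly as a cell-set intersection on
the shared grid. The alternative reading — the share of the behaviour
UD's probability mass inside the all-behaviour isopleth — is
implemented behind `mode = "mass"`; area overlap is the default because
the downstream regression operates on per-individual core-area
polygons. Proportions are pulled off the boundary with
$\dot x = (x(N-1) + 0.5)/N$, where $N$ is the number of records
entering the regression (dataset-level, configurable).

`fit_beta_glmm()` fits $\dot x$ with a beta likelihood, logit link,
common precision $\phi$, and a colony random intercept integrated by
adaptive Gauss–Hermite quadrature (15 nodes by default; estimates move
by under $10^{-3}$ between 9 and 31 nodes on the recovery fixtures).
The subsample control is the reference level, so behaviour coefficients
are read as departures from a pure sample-size control. Reported
subset means are conditional on a zero random effect by default
(`mean_type = "marginal"` averages over the random-effect law instead);
the two differ by under 1% at the fitted variance, and the choice is
surfaced because reported "model estimates" rarely state which is
meant. `fit_lmm()` models $\log_{10}$ key-area size with behaviour
fixed effects (all-behaviour baseline) and a colony random intercept,
by ML with the variance ratio profiled out in one dimension, reporting
Wald 95% CIs and Nakagawa's marginal/conditional $R^2$. Both fits are
pinned in the tests to independent implementations (`glmmTMB`,
`lme4`) and to closed-form OLS/fixed-effect oracles in the degenerate
zero-variance case. Wald intervals (not profile likelihood) are used
throughout: cheap, standard, and adequate at these sample sizes. No
multiple-testing correction is applied, matching the raw-CI reporting
convention the analysis mirrors.

## Representativeness and population-level key areas

How much of a colony's space use does a tracked sample capture? For
each $k = 1..N-1$, the bootstrap repeatedly (default 50 iterations)
pools $k$ randomly chosen individuals into a level-UD and measures the
inclusion rate of the held-out individuals' fixes; a Michaelis–Menten
curve $\mathrm{inclusion} = a\,k/(b+k)$ is fitted to the mean inclusion
per $k$, and representativeness is the predicted inclusion at $k = N$
as a percentage of the asymptote $a$, i.e. $100\,N/(b+N)$. Pooling is
implemented as a point-count-weighted average of per-individual density
grids, which is algebraically identical to re-smoothing the pooled
points and keeps the bootstrap cheap. Samples of fewer than 3
individuals, or a failed curve fit, yield an unusable flag rather than
an error. Representativeness is assessed per behaviour subset, since
subsets differ in how completely a sample spans them.

The population key area scales the individual-overlap surface by
representativeness: on a common colony grid, each cell's value is
(fraction of individuals whose core isopleth covers the cell) ×
(representativeness/100) × 100%, and cells at or above the 10%
source-population threshold are dissolved into the key-area polygon.
Population estimates require $\ge 8$ tracked individuals, and colonies
under 70% representativeness are excluded from the size comparison.
All three percentages (level, threshold, exclusion) are flags with
these defaults.

## What the synthetic data do and do not show

`simulate_colony_trips()` emulates the statistical structure the
analysis assumes: gamma/von Mises emissions, Markov state persistence,
central-place trip structure (forced outbound/homing transiting legs
with von Mises heading bias, concentration 20, toward the away/home
bearing), colony attendance between trips, and 100-s timestamps. The
forced commuting legs are labelled transiting — consistent with their
kinematics — but they make central-place tracks slightly
transiting-enriched relative to the free-running chain, so
HMM-recovery experiments use free-running mode. The corridor fixture
(`simulate_corridor_tracks()`) is a deliberately stylised geometry —
tight foraging/resting clusters at a distant patch, sparse transiting
fixes strung along a shared corridor — built to test whether the
machinery reproduces the qualitative signature that motivates
behaviour-aware key areas (poor transiting capture at the 50% level,
improving with UD level; transiting key areas larger than all-behaviour
ones).

One behaviour of the bundled workflow is worth flagging: each synthetic
trip takes an independent random bearing, so ten tracked individuals
use space idiosyncratically and several colony-by-subset combinations
fall below the 70% representativeness threshold — the small-sample
safeguard triggering as designed. Real colonies, whose members share
persistent foraging grounds, reach high representativeness at
comparable sample sizes; a generator extension with shared patches
would emulate that (see the corridor fixture, which does share
structure across individuals and is representative).

What passing these tests shows: the estimators recover their generating
parameters, the geometry pipeline computes what it claims, and the
qualitative ordering emerges when the spatial structure that produces
it is present. What they do not show: that real tracks satisfy the
model. The generator has no location error, no environmental
covariates, no individual heterogeneity in emissions, no tidal or
diurnal structure, and its corridor geometry is cleaner than any real
colony's. Real-data conclusions still require the representativeness
and sensitivity checks the pipeline provides.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: a single-point UD is one
kernel; empty key areas (no cell reaching the threshold) are valid
zero-area results; reducible transition matrices, unordered timestamps
and out-of-range coordinates are errors naming the offender. All
stochastic steps take explicit seeds, and the pipeline manifest records
content hashes so identical configurations reproduce byte-identical
tables (asserted in the tests).

The bundled workflow and test suite run at deliberately desk-scale
problem sizes chosen to hold Monte-Carlo error well inside each check's
tolerance: HMM recovery at 50 series × 500 fixes (≈25,000 observations,
where step-mean recovery error is ~1%), decoded-proportion checks at
10⁵ fixes (±0.3 pp sampling error against a ±1.5 pp tolerance), the
workflow at 2 colonies × 10 individuals × 3 trips, and mixed-model
recovery at 14 colonies — the published design's colony count — with
10-seed replication.

## Known limitations

- The projection and haversine assume a spherical Earth; at 300 km
  scales the induced area error is far below the grid discretisation
  error, but the constants matter if results are compared against a
  GIS using an ellipsoid.
- Isopleth area is counted in whole cells; smooth-contour areas would
  differ by O(cell size × perimeter). The choice is deliberate (exact
  additivity with the population grid) but means areas depend weakly on
  `ud_cell_divisor`.
- The beta GLMM supports a single random intercept (colony); crossed or
  nested effects (year within colony) are out of scope.
- No location-error model: positions are taken as exact, appropriate
  for GPS but not for Argos or geolocation data.
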