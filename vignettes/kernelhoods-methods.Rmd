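---
title: "Methods: kernel intensity measures in network neighborhoods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kernel intensity measures in network neighborhoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Studies of the built environment and children's physical activity must make
two methodological choices that are known to change their conclusions: how
to quantify the availability of urban point characteristics (playgrounds,
transit stops, street intersections), and at what spatial scale to define a
child's neighborhood. `kernelhoods` implements a comparative framework that
crosses **seven point-intensity measures** with **six ego-centered
network-distance neighborhoods** and links every combination to
accelerometer-derived moderate-to-vigorous physical activity (MVPA) through
a stratified gamma log-link regression, so the sensitivity of the
association to both choices can be mapped systematically.

# Intensity measures

Point characteristics are modelled as planar point processes on the study
window $W \subset \mathbb{R}^2$.

**Simple intensity.** For a neighborhood $A$ with area $\nu(A)$,
$\hat\lambda_A = \#\{s_i \in A\} / \nu(A)$ (points per km²). It assumes a
homogeneous process and assigns points all-or-nothing.

**Kernel intensity.** The inhomogeneous intensity is estimated by a
bivariate Gaussian kernel sum
$\hat\lambda(s) = w(s) \sum_i K_\Sigma(s - s_i)$, where $\Sigma$ is the
bandwidth (covariance) matrix and $w(s)$ an edge-correction weight. The
exposure of a child is the mean of $\hat\lambda$ over the neighborhood
polygon. Six kernel variants arise from three pilot bandwidths and their
residential-density-adaptive versions:

| measure | bandwidth | default / selection |
|---|---|---|
| `fixed` | isotropic $\sigma_f$ | 500 m |
| `mse_cv` | isotropic $\sigma_{CV}$ | arg-min of an MSE-style cross-validation criterion |
| `lscv` | full matrix $\Sigma_{lscv}$ | least-squares cross-validation |
| `*_adaptive` | pilot scaled by $2000 / R_A$ | $R_A$ = residents/km² of the neighborhood |

**Edge correction.** The correction factor is
$w = 1 / \int_W K_\Sigma(u - \cdot)\,du$, the reciprocal of the kernel
mass retained inside the window. The retained mass is exact for
rectangular windows — a bivariate normal rectangle probability, evaluated
by Drezner–Wesolowsky Gauss–Legendre quadrature for correlated $\Sigma$ —
and numeric quadrature for general polygons. Interior points get weight 1;
a straight boundary doubles the weight and a right-angle corner quadruples
it. The factor can be applied per *data point* (Jones–Diggle form,
$\hat\lambda(s) = \sum_i w(s_i) K_\Sigma(s - s_i)$) or per *evaluation
location* ($w(s) \sum_i K_\Sigma(s - s_i)$). The per-point form is the
default because it conserves mass exactly — each corrected point
contributes exactly one unit, so the surface integrates back to the
observed count; the location-indexed form under-counts boundary points
(a point on a straight edge integrates to $\int_0^\infty \phi(t)/\Phi(t)\,
dt = \ln 2 \approx 0.69$ of a unit) and is provided as the `"uniform"`
option for comparison. The per-point form trades exact mass conservation
for a slight pointwise bias within ~2 kernel SDs of the boundary; interior
cells are unaffected.

**MSE cross-validation.** The criterion is evaluated in its
pairwise-distance closed form
$M(\sigma) = \sum_{i,j}\varphi_{2\sigma^2}(d_{ij}) -
2\sum_{i \ne j}\varphi_{\sigma^2}(d_{ij})$,
i.e. the integral term of the squared estimator (using the Gaussian
convolution identity) minus twice the leave-one-out term. The search grid
has 32 geometric steps over $[\text{cell size}, \text{window diameter}/4]$;
ties break toward the smaller bandwidth (less oversmoothing at equal
criterion value).

**Anisotropic LSCV.** The objective
$\mathrm{LSCV}(\Sigma) = \int \hat f^2 - \tfrac{2}{n}\sum_i \hat
f_{-i}(s_i)$ has a closed form for Gaussian kernels and is minimised over
symmetric positive-definite matrices through a log-Cholesky
parametrisation (3 free parameters), Nelder–Mead from at least five starts
(including the isotropic MSE-CV seed), keeping the best converged
objective.

*Known limitation.* Least-squares CV of a full bandwidth matrix is highly
variable, and it has spurious minima at bandwidths near the interpoint
spacing (the smallest kernel axis can collapse onto near-neighbour pairs;
we verified that an independent LSCV implementation selects essentially
the same degenerate matrices on identical data). The selector reports the
true arg-min by default, because that is what the criterion defines; a
`min_sd` floor (e.g. twice the mean nearest-neighbour distance) is
available to penalise the undersmoothing regime, but it can in turn trap
genuinely elongated samples at near-isotropic solutions, so it is not the
default. Anisotropy detection should be read comparatively — elongated
processes yield systematically more anisotropic bandwidths than isotropic
ones, and 4:1 samples reliably cross an eigenvalue-ratio of 1.5 — not as a
calibrated test of isotropy: isotropic samples of size 200 often select
elongated matrices too.

**Adaptive scaling.** $\tilde\sigma = (2000 / R_A)\,\sigma$ with pilot
density 2000 residents/km²: the bandwidth is unchanged at the pilot
density, shrinks in denser areas and widens in sparser ones. For matrix
bandwidths we scale $\Sigma$ by the squared factor so the linear kernel
spread scales exactly as in the isotropic case, keeping the three adaptive
measures commensurate. $R_A$ is floored at 100 residents/km² (configurable,
recorded when applied) so near-empty neighborhoods cannot produce unbounded
bandwidths. $R_A$ is computed per child and per distance over the service
area, and one scaled bandwidth is used to re-evaluate the kernel surface
within that area — the most literal reading of indexing the density by the
neighborhood.

# Network neighborhoods

A child's neighborhood at distance $d \in \{500, 750, 1000, 1250, 1500,
2000\}$ m is the **service area**: single-source shortest paths on the
street network from the (blurred, snapped) residence retain every edge
fragment within network distance $d$, cutting partial edges at the exact
reach point; the polygon is the union of the fragments buffered by 25 m
(a configuration knob and a documented sensitivity axis — the polygonised
service area mirrors the standard GIS workflow). Membership of any planar
point is decided exactly through the "network reach" function: for a query
point, the chord of its buffer disc on each edge gives the on-edge interval
that covers it, and the minimum network distance over interval endpoints is
the reach; a point is in the service area of distance $d$ iff its reach is
at most $d$. One pass over the edges therefore serves all six distances,
and nesting across distances is structural, not numerical.

Areas $\nu(A)$ are midpoint counts on a fine grid (resolution buffer/5 for
standalone service areas, with 4×4 sub-sampling of mask-boundary cells;
buffer/2.5 in the batched exposure builder, where the residual area noise
is far below the between-child variation). The straight-line closed form
($2 d b + \pi b^2$ for a line segment) is reproduced to better than 1%.

**Residence blurring.** To emulate privacy-preserving geocoding, homes are
displaced by bivariate Gaussian noise with standard deviation
$c / \text{density(home)}$; the default $c = 2\times10^5$
m·residents/km² gives a median displacement near 60 m in densely populated
areas (50–100 m band), and draws leaving the window are redrawn (at most
100 times). Children snapping farther than 250 m from the network are
flagged and skipped, mirroring the exclusion of off-network rural
residences. Simple-intensity counts use the buffered polygon (configurable);
whether the original workflow counted on the polygon or the raw fragments
is not determinable, and the choice is documented rather than hidden.

# Accelerometry

Outcomes are habitual MVPA minutes/day from 15-s epoch counts:

- **Non-wear**: maximal runs of ≥ 120 consecutive zero epochs (30 min) are
  excluded; runs are evaluated within calendar days and never merged across
  a non-zero epoch. Days are processed independently (non-wear does not
  span midnight; configurable).
- **MVPA cut-off**: 2298 counts per minute. On 15-s epochs this is
  $\lceil 2298/4 \rceil = 575$ counts — counts are integers, so the ceiling
  keeps the cpm threshold conservative. A 60-s re-integration mode is
  available behind a flag.
- **Valid day**: ≥ 8 h of wear time after non-wear exclusion.
- **Inclusion**: some window of ≥ 3 consecutive valid calendar days
  containing ≥ 1 weekend day. Habitual MVPA averages over *all* valid days
  (the qualifying-window-only average is a configuration option).

# Gamma log-link regression

MVPA is strictly positive and right-skewed, so we fit
$y \sim \Gamma(\nu, \mu)$ with $\log \mu = X\beta$. The IRLS estimate of
$\beta$ is the exact MLE for any fixed shape; the shape $\nu$ is then
estimated by full maximum likelihood, so the reported log-likelihood and
AIC are true likelihood quantities (a documented divergence from software
defaults that use moment estimators of the dispersion). Wald (normal)
p-values use the covariance $(1/\nu)(X^TWX)^{-1}$. Because the AIC
convention for counting the shape parameter differs across packages, both
AICs are reported side by side (`aic` counts it, `aic_mean_only` does not);
all comparisons in the pattern tables use `aic`, and only within
(stratum, layer) blocks.

The **basic models** regress MVPA on age, BMI z-score, valid wear time,
season (autumn/winter reference), parental safety concerns (no = ref) and
ISCED parental education (medium = ref) in six strata: all/boys/girls ×
school-age (6–9.9 y)/pre-school (2–<6 y). Each exposure column (one
measure × distance × layer) is then added one at a time, and the exposure
effect $\exp(\hat\beta)$, its raw p-value (no multiple-testing adjustment
across the grid, by design) and the model AIC form the pattern table.
Synthetic null cohorts can produce MVPA values of exactly zero; these are
excluded with a logged count since the gamma likelihood requires
positivity.

# The synthetic city and cohort

All validation runs on seeded synthetic data with known ground truth:

- **Street network**: a block lattice (130 m spacing ⇒ ~59
  intersections/km²) with 10% of edges removed; dropout is redrawn until
  the largest component keeps ≥ 90% of nodes. Intersections are nodes of
  degree ≥ 3 — the standard GIS convention, since "intersection" is
  otherwise undefined.
- **Residential density**: a truncated anisotropic Gaussian gradient
  (default peak 7250, floor 200 residents/km², axis ratio 1.5) — the
  simplest shape that exercises both the adaptive bandwidth and the
  anisotropic kernel. At the default 7.9 × 7.9 km window it integrates to
  ≈ 77,000 residents over 62.4 km², emulating a mid-sized town, so that
  2-km neighborhoods stay local. Tests use smaller explicit extents.
- **Point layers**: transit stops and open spaces are inhomogeneous
  Poisson draws with intensity proportional to residential density
  (4 and 3.2 points per 1000 residents; optional Neyman–Scott clustering),
  which builds in the exposure–density confounding that the adaptive
  bandwidth addresses. The spatial law of the real layers beyond their
  density correlation is unknown; these defaults are stated free
  parameters, not calibrations.
- **Cohort**: homes sampled proportional to density; 75% school-age,
  51.5% girls; stratum-specific ISCED, safety-concern and season
  probabilities matching the study's descriptive margins; wear time
  truncated-normal (11.5 ± 1.3 h). Habitual MVPA is drawn from
  $\Gamma(\nu = 8, \mu = \exp(X\beta))$ with the study's fitted
  age-group-specific coefficients as the default truth (e.g. season 1.17
  and safety 0.99 in school children; age 1.28 and safety 0.86 in
  pre-school children), intercepts calibrated to mean MVPA of ~62 and ~56
  min/day.
- **Epoch series**: a two-state wear/non-wear construction inside a
  07:00–21:00 wear window. The deterministic mode reproduces the configured
  daily MVPA to the epoch (used for exact round-trip tests); the stochastic
  mode adds Poisson jitter. Weekend = Saturday or Sunday by day-of-week
  label.

What the generator does *not* emulate: real road topology, correlated
day-to-day MVPA within children, seasonal confounding between wear time
and season, measurement error in the covariates. Passing tests therefore
demonstrate internal correctness and statistical calibration of the
machinery under the stated generative model, not external validity on any
real city.

# Simulation studies

Four packaged experiments re-run the whole stack (sizes chosen to keep a
full validation run within minutes on one core):

- `type1_experiment()`: 200 school-age cohorts of 400 with a null safety
  effect; Wald rejection at 5% must stay in [2%, 8%].
- `planted_effect_experiment()`: coverage of the season effect
  $\exp(\beta) = 1.17$ at $n = 300$, and power for the pre-school-girl
  safety effect $\exp(\beta) = 0.75$ at five times the original stratum
  size.
- `recovery_experiment()`: 50 full-pipeline replicates at $n = 400$,
  shape 8: open-space exposure measured by the fixed kernel in the 1-km
  neighborhood, a planted $\exp(\beta) = 1.10$, and Wald-CI coverage
  ≥ 90%. Blurring is disabled here so that the measured exposure is the
  generative one and coverage is interpretable as calibration.
- `stability_experiment()`: 30 replicates at the study-region scale with a
  distance-constant true effect on the 1-km fixed-kernel open-space
  exposure; in at least 80% of replicates the across-distance range of
  $\exp(\hat\beta)$ under the LSCV kernel measure must not exceed that of
  the simple intensity. The truth is deliberately a *neighborhood mean*
  (not a point evaluation) of a measure that is not one of the two being
  compared; with a window small relative to 2 km the property degenerates
  (all exposures converge to the global mean), which is why the experiment
  runs at town scale.

# Numerical choices

- Surfaces default to 25-m cells; all integrals are midpoint sums on the
  surface grid. A warning fires when the cell size exceeds half the
  smallest kernel SD.
- Kernel sums are chunked to bound memory; surface cells match an
  independently coded brute-force double loop to 1e-9 relative.
- Shortest paths come from igraph on the edge-length-weighted graph, with
  the origin inserted as a virtual vertex splitting its host edge.
- Snapping ties between equidistant edges break deterministically toward
  the lowest edge id.
- Degenerate service areas (no surface cell centre inside) fall back to
  bilinear evaluation at the origin and are flagged.
- Seeds fan out from one root seed through named streams
  (hash of the stage name), so any stage can be re-drawn independently;
  all derived seeds stay below $2^{31}$.

# Limitations

- Planar (not network-constrained) kernel densities; Euclidean kernels
  around network-defined neighborhoods.
- No per-point (Abramson-style) adaptive bandwidths; the adaptive factor
  is a single scalar per neighborhood.
- The LSCV variance pathology above.
- The multi-level daily-MVPA model and finer age stratifications are out
  of scope.
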