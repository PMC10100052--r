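---
title: "Models and methods: settlement point processes and conditional-logit mate choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conattract)
```

This vignette documents the statistical models the package implements,
the assumptions and tunable parameters behind them, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where more than one defensible option existed.

## Settlement as an inhomogeneous Poisson process

Male settlement locations within one site and year are treated as a
realisation of an inhomogeneous Poisson point process on the site window
with loglinear intensity

$$\lambda(u) = \exp\!\big(\beta_0 + \textstyle\sum_k \beta_k S_k(u)\big),$$

where each covariate $S_k$ is a 10 m raster: *hab*, a Gaussian
kernel-density surface of cumulative nest locations, and *prox.all* /
*prox.lc*, playback-proximity surfaces $e^{-d/200}$ with $d$ the distance
(m) to the nearest station midpoint (all stations, or low-song-rate
stations only). The Poisson assumption means males settle independently
given the intensity; attraction between males is expressed only through
the playback covariates, not through interaction terms. Candidate models
are the null model, each covariate alone, and *hab* plus either proximity
covariate.

**Likelihood approximation.** The process log-likelihood
$\sum_i \log\lambda(x_i) - \int_W \lambda\,du$ is approximated with the
Berman–Turner device: the window is tiled by a regular dummy grid at
spacing $s$ (default 10 m, the covariate cell size — finer dummies cannot
add covariate information), every data and dummy point $j$ receives the
counting weight $w_j = \text{tile area} / \text{points in tile}$, and the
weighted Poisson log-likelihood
$\sum_j w_j (y_j \log\lambda_j - \lambda_j)$ with $y_j = z_j/w_j$ is
maximised. The weights sum exactly to the window area. Tiles are
half-open, $[x_0, x_0+s)$, with far-edge points assigned to the last
tile, so no point is ever double-counted on a boundary.

**Fitting.** The maximisation is Newton iteration on the weighted-Poisson
score (equivalently IRLS for the log link), started at the homogeneous
fit $\beta = (\log(n/\sum w), 0, \dots)$, with step-halving on the rare
non-improving step, run until the score norm falls below $10^{-8}$.
Divergence of the linear predictor beyond 500 (separation) and singular
information are reported as errors rather than returned as estimates. The
coefficient covariance is the inverse Fisher information. Unit tests hold
this solver to agreement with `stats::glm` on the identical weighted
regression to $10^{-8}$, and the reported log-likelihood to a 1 m
fine-grid evaluation of $\sum\log\lambda - \int\lambda$ to relative
$10^{-3}$.

**Pooling across patterns.** All coefficients, including a single
intercept, are shared across the site-year patterns — the literal reading
of fitting one common model to all patterns. A
`per_pattern_intercept = TRUE` flag provides the site-year-intercept
variant for sensitivity analysis, because with one shared intercept any
real between-site density differences must be absorbed by the covariates.
The AICc sample size is the total number of settled males across
patterns; AICc sample size for point-process models is a genuinely open
convention, and the data-point count is the choice most consistent with a
small-sample correction intent (with ~50 males and at most 3 parameters
the correction is small either way).

**Effect sizes.** A coefficient is range-standardized as
$\exp(\beta \times \text{range})$, the factor by which predicted density
varies across the covariate's observed span, taking $\beta$ from the
best-supported model containing that covariate.

## Habitat attractiveness and proximity covariates

The *hab* raster is a plain Gaussian kernel sum over nest locations,
evaluated at cell centres on the intensity scale (nests per m²). Kernel
and bandwidth are tunable; the default is an isotropic Gaussian with
$\sigma = 50$ m — wide enough to span a few territories, narrow enough to
retain site-scale structure. No edge correction is applied by default:
the surface is used as a relative covariate, where a global or smooth
multiplicative distortion is absorbed by $\beta_0$ and barely affects
$\beta_{hab}$. When the settlement pattern of site $s$, year $y$ is
analysed, nests from $(s, y)$ are excluded from the estimate so the
covariate carries no information from the season being modelled;
`raster_correlation()` quantifies the (high) between-year stability this
induces. A positive floor $\varepsilon$ (default $10^{-6} \times$ the
maximum cell value) keeps powers $H^{\alpha}$ defined for negative
exponents.

Raster values are attached to points by nearest-cell lookup, not bilinear
interpolation: the covariates are defined as 10 m cell values and
interpolation would invent smoothness. Distances to playbacks are
measured to station midpoints — the midpoint of a station's two speakers
is the simulated male's territory centre.

## Preprocessing rules

* **Settlement:** a male is settled in a site-year if his observed
  presence spans ≥ 5 days (inclusive day count).
* **Territories:** singing locations < 150 m apart are linked
  (single-linkage, implemented as connected components of the
  sub-threshold graph so that exactly-150 m pairs separate without any
  epsilon fudge); locations ≥ 150 m apart are distinct territories. The
  territory centre is the centroid of member locations — the centre
  definition is a package choice, as is single linkage (the most
  permissive reading of the separation rule).
* **One point per male per site-year:** among a male's territories the
  longest tenure wins; tenure ties go to the chronologically first.
* **Nest timing:** clutch initiation = clutch completion − (clutch size
  − 1) days (one egg per day); nest initiation = clutch initiation − 7
  days; incubation spans 14 days from completion. All date arithmetic is
  day-resolution and timezone-free.
* **Choice sets:** for each female, the survey snapshot nearest in time
  to her nest initiation date defines her candidate males; ties between
  equidistant surveys resolve to the earlier one (females typically begin
  nesting within a day of arrival, so earlier information is the safer
  proxy). Already-paired males remain candidates; playbacks never enter
  the candidate set. The chosen male is the one named in an optional
  `mate_id` column, or failing that the male nearest the nest — the
  field's pairing information is not part of the nest schema, and
  territory proximity is the standard operational proxy.

## Conditional-logit mate choice

Given a choice set with habitat values $H_i > 0$ and connectivities
$C_i$, male attractiveness is $A_i = H_i^{\alpha_1} C_i^{\alpha_2}$ and
the choice probability is $p_i = A_i / \sum_j A_j$. The log-likelihood is
$\ell(\alpha_1, \alpha_2) = \sum \ln p_{chosen}$; single-candidate events
contribute exactly zero. Because only attractiveness ratios matter,
rescaling all $H$ or all $C$ by a common factor — including the overall
elevation of connectivities caused by adding males to a scene — cancels
exactly; the tests assert this numerically.

**Connectivity.** $C_i = \sum_{j \ne i} e^{-d_{ij}/\lambda_C}$ over all
other males in the site, plus playback midpoints in the
include-playbacks variant. The decay constant $\lambda_C$ is exposed
rather than hard-wired: the bare formula ($\lambda_C = 1$ m) makes $C$
astronomically small at realistic inter-male spacings (hundreds of
metres), so the default is $\lambda_C = 200$ m, matching the proximity
covariate's e-folding distance; `decay = 1` reproduces the bare formula
when wanted. Include- and exclude-playback variants differ only through
$C$, never through the candidate set, and are reported side by side.

**Fitting.** On the log scale the model is a linear conditional logit in
$(\ln H, \ln C)$; the implementation maximises the likelihood directly by
derivative-free Nelder–Mead simplex search with restarts at $-1, -0.5,
0, 0.5, 1$ per free parameter (plus a polish restart at the incumbent),
with no sign constraint on either exponent. Internally the log-covariates
are centred within each event — an exact invariance of the conditional
likelihood — which keeps every $e^s$ in range without per-event max
bookkeeping. The MLE is cross-checked in the tests against
`survival::clogit` on the long-format layout. The four models (null,
habitat-only, connectivity-only, full) fix the excluded exponents at
zero; AICc uses the number of choice events as $n$ and the number of
free exponents as $k$.

## The synthetic study

The generator produces data *from* the two models above, so recovery of
the generating parameters is a meaningful end-to-end check of the whole
chain. Its defaults emulate the study conditions the analyses assume:

* three sites in ~100 ha windows, five site-year patterns;
* latent habitat = constant floor (0.5) plus 5 Gaussian hotspots of
  s.d. 120 m and peak height 10–20, giving surfaces whose observed range
  (roughly 0.5–25) makes $\beta_{hab} = 0.109$ a strong-but-realistic
  effect (density factors of order 10 across the range);
* cumulative nests over 11 seasons at 8 expected nests/site/year, drawn
  with density proportional to the latent surface;
* playback arrays with the experiment's per-site-year high/low counts,
  stations ≥ 150 m apart, speakers 100 m apart;
* settled males from $\lambda(u) = \exp(\beta_0 + 0.109\,hab +
  1.773\,prox)$ by thinning; the dominating intensity is the cell-wise
  maximum of $\lambda$, which is exact for piecewise-constant covariates
  and valid for coefficients of either sign. By default the intercept is
  calibrated per site-year to the observed expected counts (22, 21, 1,
  1, 5 — 50 males in all), reproducing realistic between-site density
  differences;
* 59 choices by 50 females (renesters choose twice), allocated across
  site-years in proportion to male counts, each drawn from the
  conditional logit at $(\alpha_1, \alpha_2) = (0.625, -0.06)$ with
  decision dates uniform over the season (no arrival distribution is
  specified by the design, so uniform is the neutral choice, and it is
  configurable);
* raw territory-observation tables around each settled male (1–3
  jittered singing locations, occasional second territories ≥ 150 m away
  with strictly shorter tenure, and < 5-day transients), so the
  preprocessing rules are exercised on their way back to the patterns.

Every generator forks a deterministic sub-seed from the master seed per
site/year/purpose, so any subset regenerates identically in isolation.

**A deliberate distinction in the recovery experiments.** The default
per-site-year intercept calibration makes the demo realistic but means
the generative truth contains site-level density differences that a
shared-intercept fit must misattribute. Parameter-recovery and coverage
experiments therefore calibrate one *common* intercept (total expected
count 50 across the five patterns), so the generating model is exactly
the fitted model — the precondition for interpreting coverage of the
generative coefficient. The test helpers expose both constructions.

**What the generator does not emulate.** Detection error in surveys,
within-season territory shifts beyond the fabricated second territories,
temporal turnover within the settlement season (patterns are cumulative
snapshots), inter-annual return of individuals, habitat anisotropy, and
female search costs. Passing recovery tests therefore demonstrates the
estimators are correct for the stated models, not that real settlement
data satisfy those models.

## Numerical choices and degenerate inputs

* Quadrature tie-break: points on tile boundaries follow the half-open
  cell convention; far window edges belong to the last tile.
* PPM convergence: score norm < $10^{-8}$, max 100 Newton iterations,
  step-halving; separation and singular information raise errors.
* Mate-choice convergence: simplex `reltol` $10^{-10}$ with a
  $10^{-12}$ polish restart; all-single-candidate event sets (a flat
  likelihood) are refused.
* Single-candidate events return $p = 1$ and contribute 0 to $\ell$; a
  lone male with no playbacks may legitimately have $C = 0$, which never
  enters a likelihood ratio.
* AICc requires $n > k + 1$ and errors otherwise; Akaike weights are
  invariant to adding a constant to all AICc values (asserted in tests).
* Rasters are validated to finite values and positive cell sizes;
  sampling outside a raster's extent is an error, not an extrapolation.

## Problem sizes used in the validation suite

The stochastic experiments run at: 50 replicates of 2,000 choice events
for exponent recovery (mean absolute error), 200 replicates of 59 events
for median-unbiasedness at study scale, 200 replicates of 2,000 events
for null recovery, 100 replicates for model-ranking frequency, and 200
replicates of five-pattern studies (~50 males each) for Wald coverage of
$\beta_{hab}$. These sizes keep Monte-Carlo error comfortably below the
assertion margins while remaining quick to run.

## Known limitations

* Windows are axis-aligned rectangles; polygonal site masks are not
  implemented (masked cells could be added to `grid_raster` without
  changing the fitting code).
* Raster I/O is ESRI ASCII grid only, planar metre coordinates, no CRS
  transformation.
* The PPM family is Poisson-only: no Gibbs/interaction processes, no
  spatial random effects, and no edge-corrected summary statistics.
* KDE bandwidth is fixed per analysis, not data-driven; the default
  $\sigma = 50$ m is an explicit, documented stand-in.
* The conditional logit treats candidate sets as exact snapshots;
  uncertainty in who was present on the decision date is not propagated.
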