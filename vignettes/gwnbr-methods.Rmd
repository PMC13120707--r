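---
title: "Geographically weighted negative binomial models for zonal counts: methods and design"
author: "gwcrash"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geographically weighted negative binomial models for zonal counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Event counts aggregated to administrative zones — road crashes per district,
disease cases per county — routinely violate two assumptions of ordinary
count regression. First, they are **overdispersed**: the variance far exceeds
the mean, because zones differ in unmeasured ways and events cluster within
zones. Second, they are **spatially non-stationary**: the association between
a covariate (road density, rainfall, population) and the count is not one
number but varies over the map, and nearby zones resemble each other.

`gwcrash` implements the full analysis chain for this situation: spatial
autocorrelation screening (global Moran's I and local LISA), collinearity
screening (VIF), global OLS/Poisson/negative-binomial baselines with
overdispersion diagnostics, and the core method — **geographically weighted
negative binomial regression (GWNBR)** with data-driven bandwidth selection —
plus the comparison metrics (AIC, MAD, RMSE) and residual spatial diagnostics
that justify each step. A synthetic-data module generates zonal studies with
*known* spatially varying data-generating processes, so every stage of the
chain is verifiable end-to-end without access to any particular crash
database.

# Models

## Global negative binomial (NB2)

For zone $j$ with count $y_j$, exposure $t_j$ and covariates $x_{jk}$:

$$\ln \mu_j = \ln t_j + \sum_k \beta_k x_{jk}, \qquad
\operatorname{Var}(y_j) = \mu_j + \alpha \mu_j^2 .$$

$\alpha > 0$ is the overdispersion parameter; $\alpha \to 0$ recovers the
Poisson model. `fit_negbin()` maximizes the joint likelihood by alternating
iteratively reweighted least squares (IRLS) for $\beta$ with a safeguarded
one-dimensional maximization of the profile likelihood over $\log \alpha$ on
$[10^{-8}, 10^{4}]$. Convergence is declared on the score equations
($\max_k |\sum_j x_{jk}(y_j - \mu_j)/(1 + \alpha\mu_j)| < 10^{-8}$), with
log-likelihood-stall and step-size checks as fallbacks. Standard errors come
from the information matrix $X'AX$ with $A = \mathrm{diag}\,
\mu_j/(1+\alpha\mu_j)$.

## GWNBR

GWNBR lets both the coefficients and the dispersion vary with location
$(u_i, v_i)$:

$$y_j \sim \mathrm{NB}\!\left[t_j \exp\Big(\sum_k \beta_k(u_j,v_j)\,
x_{jk}\Big),\; \alpha(u_j,v_j)\right].$$

At each zone $i$ a local model is estimated by maximizing the
kernel-weighted log-likelihood

$$\ell_i(\beta, \alpha) = \sum_j w(d_{ij}) \Big[ y_j \ln(\alpha\mu_j)
- (y_j + 1/\alpha)\ln(1+\alpha\mu_j) + \ln\Gamma(y_j + 1/\alpha)
- \ln\Gamma(1/\alpha) - \ln\Gamma(y_j+1) \Big],$$

computed entirely through `lgamma` (the Gamma integral is never evaluated
directly). The local IRLS update is
$\hat\beta(u_i,v_i) = (X'WAX)^{-1}X'WAz$ with kernel weights $W$, GLM weights
$A$, and adjusted response $z_j = x_j'\hat\beta + (y_j-\mu_j)/\mu_j$ (the
form $(y_j-\mu_j)/[a_j(1+\alpha\mu_j)]$ with $a_j = \mu_j/(1+\alpha\mu_j)$,
simplified). Each local fit is warm-started from the global NB estimates,
which stabilizes small-bandwidth fits; by default $\alpha$ is re-estimated
locally at every focal zone (`global_alpha = TRUE` holds it fixed at the
global estimate). Every local fit requires at least $p+2$ zones with
positive kernel weight, otherwise it is rejected as locally unidentified;
more than 10% of failed local fits aborts the whole fit.

## Kernels and bandwidth

Two kernels are provided:

* **adaptive bisquare** (default): the bandwidth $N_k$ is a *neighbor
  count*. With $b_i$ the distance from zone $i$ to its $N_k$-th nearest zone
  (itself included at distance 0), $w = (1-(d/b_i)^2)^2$ for $d < b_i$, else
  0. Zones tied exactly at $d = b_i$ receive weight 0, deterministically.
* **fixed Gaussian**: $w = \exp(-\tfrac12 (d/b)^2)$ with $b$ a distance.

The adaptive kernel is the practical default for zonal systems whose units
differ wildly in size: it keeps the effective local sample size constant.
All distances are Euclidean on projected planar coordinates; geographic
(lon/lat) input is rejected at read time rather than silently mis-measured.

`select_bandwidth()` minimizes either the GWNBR **AIC** or the leave-one-out
**CV** score $\sum_i (y_i - \hat y_{(i)})^2$ (each zone predicted from a
local fit with its own kernel weight forced to zero) by golden-section
search. For adaptive kernels the search is over integers: the interval is
narrowed by golden sections until a handful of candidates remain, which are
evaluated exhaustively; the endpoints are always probed so monotone
objectives return a boundary optimum; every evaluation is cached and
reported. Default bounds are $[\max(p+2, \lceil 0.1n\rceil),\, n]$. The AIC-
and CV-selected bandwidths legitimately differ; the pipeline fits and
reports both.

## Effective number of parameters

GWNBR's AIC needs a model dimension. We use the geographically-weighted
regression convention $k = \operatorname{tr}(S)$, where row $i$ of the
hat-like matrix $S$ is $x_i'(X'W_iA_iX)^{-1}X'W_iA_i$, plus a dispersion
term: **+1** when $\alpha$ is global, and $\operatorname{tr}(S)/p$ when
$\alpha$ varies locally — a locally varying dispersion surface is granted
the same flexibility cost as one coefficient surface. Both choices collapse
to +1 in the wide-kernel limit, so the GWNBR AIC converges to the global NB
AIC as the bandwidth grows, a consistency property we test. Counting the
local dispersion as a flat +1 (an earlier draft) demonstrably biases
bandwidth selection toward severe overfitting, because an entire surface of
free dispersion parameters would cost nothing.

# Spatial autocorrelation machinery

**Global Moran's I** is
$I = \frac{N}{W_0}\,\frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}$ with
$z_i = x_i - \bar x$ and $W_0$ the sum of all weights. Its null expectation
is $-1/(N-1)$; the analytic variance uses the randomization assumption by
default (a normality variant is available), giving the z-score reported
alongside the two-sided 99% critical value 2.58. The optional permutation
test relabels values over zones; its p-value counts permutations at least as
extreme (two-sided around $E[I]$) and includes the observed statistic in
numerator and denominator, so it is never exactly zero.

**Local Moran (LISA)** uses $I_i = z_i \sum_j w_{ij} z_j / m_2$ with
$m_2 = \sum z^2/n$, so the average of the local statistics equals global $I$
under row-standardized weights (an identity we assert numerically).
Inference is by conditional permutation — zone $i$'s value held fixed,
neighbors drawn without replacement from the remaining $n-1$ values — with
999 permutations by default, two-sided on $|I_i|$. Significant zones are
classified High-High / Low-Low (clusters) or Low-High / High-Low (outliers)
by the quadrant of $(z_i, \mathrm{lag}_i)$; everything else is `NS`. No
multiplicity correction is applied by default, matching common
cluster-mapping practice; a Benjamini-Hochberg option exists.

**Weights.** Queen/rook contiguity is computed by vertex and edge matching
with a snap tolerance, which assumes topologically clean polygons (true of
administrative boundary files and generated lattices); k-nearest-neighbor
weights are the fallback for point-only data. Binary matrices can be
row-standardized (idempotent; island rows stay empty with a warning).
Matrices round-trip through a three-column edge-list CSV.

# Screening

`compute_vif()` regresses each covariate on all others
($\mathrm{VIF}_k = 1/(1-R_k^2)$; perfectly collinear columns report
`Inf` rather than erroring). `vif_screen()` offers two strategies:
**one_shot** (default) removes every covariate above the threshold (10 by
convention) at once — the behavior implied by screening tables that report a
single VIF column; **iterative** removes the single worst offender and
recomputes, which is statistically safer when offenders are collinear with
each other (dropping one can rescue the rest). The Moran screen flags
covariates without significant spatial pattern; it is *advisory* by default
(a warning, not an exclusion), because absence of spatial pattern is a
defensible reason to keep a covariate in a global model even if it cannot
vary meaningfully in a geographically weighted one; `strict = TRUE` enforces
exclusion.

# The synthetic-data generator

`generate_lattice(n_side)` builds a square lattice of zones — a deliberately
idealized stand-in for a national district system. Covariates come from a
simultaneous autoregressive process $x = (I - \rho W)^{-1}\varepsilon$ on
the row-standardized rook graph, giving smooth spatial clustering that
mimics how road density, rainfall or population cluster regionally.
Coefficient surfaces are linear gradients, Gaussian bumps or constants —
the standard smooth-surface convention for geographically weighted
simulation studies. Counts are drawn from the NB2 gamma-Poisson mixture, so
the variance contract $\mu + \alpha\mu^2$ holds exactly and the *true* local
coefficient and dispersion surfaces are recorded for recovery checks.

Three presets define the study conditions used throughout the tests:

* **paper_like** — 14 x 14 = 196 zones (the scale of a ~197-district
  national system): three SAR covariates with $\rho = 0.9$, standardized; a
  north-south intercept gradient of ±0.8 around $\ln 16 - 0.37$ (the 0.37
  offsets the lognormal mean inflation $e^{\sigma^2_\eta/2}$ of the
  link-scale variance, keeping the mean near 16); an east-west gradient
  0.2 → 0.8 in the first slope; a constant 0.4 second slope; a central
  Gaussian bump of height 0.5 in the third; $\alpha = 0.6$. This yields
  counts with mean ≈ 16, standard deviation ≈ 15-30, maxima of order
  100-300, and clearly positive response autocorrelation — the regime of
  district-level crash frequencies.
* **gradient** — 20 x 20 = 400 zones, slope rising 0.2 → 0.8 west to east,
  $\alpha = 0.5$: the parameter-recovery test bed.
* **constant** — intercept-only $\beta_0 = \ln 16$, constant $\alpha$: the
  moment-recovery and global-model test bed.

**What the generator does not emulate:** irregular zone geometry and
heterogeneous zone sizes, real road networks or climate fields, covariate
measurement error, spatial misalignment between where events occur and where
they are recorded, and reporting artifacts (under-registration in remote
zones). Passing tests therefore demonstrate that the estimation machinery
recovers known truth under clean spatial smoothness — not that any
particular empirical dataset satisfies those assumptions.

# Numerical choices

* All NB likelihoods via `lgamma`; means through `exp` of the linear
  predictor with overflow guarded at $10^{12}$.
* $\alpha$ bounded in $[10^{-8}, 10^{4}]$. The positive lower bound means
  the NB likelihood on underdispersed data sits *below* the Poisson
  likelihood by $O(\alpha_{\min}\sum y_j^2)$ — about $10^{-4}$ at $n$ in the
  thousands — rather than matching it to machine precision; boundary fits
  carry an explicit flag.
* IRLS uses step-halving so the weighted log-likelihood never decreases
  (monotone ascent, tested); convergence is score-based
  ($< 10^{-8}$), with relative log-likelihood ($10^{-10}$) and step-size
  fallbacks; at most 100 outer $(\beta, \alpha)$ alternations.
* Distance ties at the adaptive kernel radius get weight zero —
  deterministic regardless of sort order.
* Golden-section search in integer mode finishes with an exhaustive sweep of
  the final bracket, and always probes the bounds.
* Problem sizes in the test suite were chosen to make each statistical check
  informative at interactive runtimes: 196 zones for the full pipeline
  (mirroring the motivating zonal system), 400 for surface recovery, ~5000
  for moment and calibration checks, 200 replicates for the permutation
  type-I-error check.

# Design decisions on genuinely open points

* **Exposure.** Road length and similar size variables are often best
  treated as covariates with a free coefficient rather than as a true offset
  with coefficient 1; the default exposure is therefore $t_j = 1$, with a
  proper `offset` argument for users who want the classical
  $\ln t_j$ semantics.
* **Adaptive bandwidth semantics.** The adaptive bandwidth is a neighbor
  count, not a distance — the natural reading when selected bandwidths come
  out just below the number of zones.
* **Residual diagnostic.** Model comparison reports global Moran's I of the
  *deviance* residuals (Pearson available). The scientific question is
  whether *positive* residual clustering remains — unmodeled spatial
  heterogeneity; locally fitted models often show mild negative residual
  autocorrelation, which is a symptom of local smoothing, not of missing
  structure. The comparison table reports the conventional two-sided p;
  the package's own qualitative checks test remaining positive clustering
  one-sidedly.
* **Local significance.** Local t-statistics use a two-sided normal
  reference without multiplicity correction, matching mapping practice;
  summaries report the share of zones significant at 5%.

# Limitations

* No semi-parametric (mixed) GWNBR: every term varies locally or none does.
* Euclidean distances only — no network or travel-time metrics, no
  spherical geometry, no reprojection (input must already be planar).
* Contiguity by vertex matching requires topologically clean polygons.
* Leave-one-out CV costs one local fit per zone per candidate bandwidth;
  at a few hundred zones this is seconds, at tens of thousands it is not.
* Global Moran's I of residuals is used descriptively; its null distribution
  for fitted-model residuals is approximate.
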