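---
title: "Models and methods: grazing intensification, dung beetle diversity and dung removal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: grazing intensification, dung beetle diversity and dung removal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grazemeta)
```

# The problem this package addresses

Cattle pastures worldwide are managed at very different stocking
intensities, and dung beetles supply a key ecosystem function in them:
removing and burying dung, which recycles nutrients, controls pests and
aerates soil. `grazemeta` implements a complete analysis chain for paired
field experiments that compare a low-intensity pasture (< 2 animals/ha)
and a high-intensity pasture (> 4 animals/ha) in each of many landscapes:

1. evaporation-corrected **dung removal rates** from pat weights;
2. **community metrics** per pasture, including two functional dispersion
   indices;
3. **PCA summaries** of climate and of the paired diversity differences;
4. per-landscape **Hedges' g effect sizes** and a **random-effects
   meta-analysis / meta-regression** with spatially correlated random
   effects;
5. a **piecewise structural equation model** of the across-site
   relationships, with a region random intercept.

A synthetic-data generator emulates the full 38-landscape design with
known ground truth so that every stage can be tested by parameter
recovery without any external data.

# Dung removal rates

Each experimental pat starts as `IWwet` = 300 g of fresh dung and is
recovered after 48 h with final wet weight `FWwet` and oven-dry weight
`FWdry`. The water proportion, initial dry mass, and removal rate are

$$WP = \frac{FWwet - FWdry}{FWwet}, \qquad
  IWdry = IWwet\,(1 - WP), \qquad
  DRR = IWdry - FWdry .$$

`WP` can come from two places, exposed as an explicit mode because the
field protocol supports both readings:

* **`"control"`** (default): the mean water proportion of the
  mesh-covered control pats of the same pasture, which exist precisely to
  measure evaporation without beetle access, applied to every
  experimental pat;
* **`"unit"`**: each experimental pat's own final weights.

The two modes agree exactly when all pats share one water proportion
(this identity is part of the test suite). Negative removal (mass gain,
e.g. after rain) is retained and flagged by default; a `clamp` argument
truncates it at zero for users who prefer that. Site summaries use the
arithmetic mean and the sample SD (n − 1), because those are exactly the
ingredients of Hedges' g downstream.

# Community metrics and functional dispersion

Per pasture the package reports abundance, species richness, Pielou
evenness $J = H'/\ln S$ (reported as missing when $S \le 1$; the evenness
formula itself is an assumption, since several conventions exist), and
two functional dispersion (FDis) indices. Both are the **unweighted mean
pairwise distance between the species present** — zero for one or no
species. Abundance weighting ($n_i n_j$ pair weights) is available as an
option but off by default, staying literal to "distance between all
species present".

**FDisMorphology** works in a standardized trait space: nine linear
morphological measurements (mm) plus dry biomass (g, log-transformed
because mass spans orders of magnitude relative to linear traits), each
z-scored, then Euclidean distances. The standardization pool is the two
communities of a landscape **jointly**, so the paired pastures share one
trait space and their FDis values are comparable within the pair.
Zero-variance traits are dropped with a warning. Species trait profiles
are per-trait means over the measured individuals (at most ten per
species; missing values skipped individual-wise).

**FDisBehavior** uses a fixed phenetic tree of 12 functional groups: four
food-relocation guilds (paracoprids/tunnelers, telecoprids/rollers,
endocoprids/dwellers, kleptocoprids/kleptoparasites) crossed with three
size classes on mean body length (large > 18.0 mm, medium 10.0–18.0 mm,
small < 10.0 mm; the medium range is inclusive, so exactly 10.0 and
18.0 mm classify as medium, while large and small use strict
inequalities). The tree's root separates the within-dung behaviours
(kleptocoprid, endocoprid) from the relocators (paracoprid, telecoprid);
the second split yields the four guilds; size classes sit at the tips.
All edges default to length 1 (topology is the substantive statement;
the branch-length scale cancels in comparisons), which makes the tree
ultrametric and orders cophenetic distances as
*size split < guild split < root split*. A species' body length
(head + pronotum + elytra) determines its tip; species sharing a tip
contribute zero-distance pairs. A continuous-body-length variant of the
index is deliberately not implemented: the tips of the tree are size
classes, and that literal reading is the default and only behaviour.

# PCA summaries

Both PCAs run on the **correlation matrix** (columns z-scored), because
climate variables have heterogeneous units and the quantities of
interest are variable–axis correlations. Only axis 1 is used. Eigenvector sign is
arbitrary, so the axis is **anchored**: the climate axis is flipped so
mean annual temperature loads negatively (positive scores = colder, more
seasonal sites), and the diversity axis so the FDisBehavior difference
loads positively (positive scores = higher diversity under low-intensity
management). Climate observations are the landscapes (the paired pastures
share their climate), which is also why the diversity PCA runs on the 38
paired low-minus-high differences rather than on 76 pastures.

# Effect sizes and the meta-analytic model

Per landscape, Hedges' g compares the 10 low-intensity against the 10
high-intensity experimental pats:

$$d = \frac{\bar y_{low} - \bar y_{high}}{s_{pooled}}, \quad
  J = 1 - \frac{3}{4(n_1 + n_2 - 2) - 1}, \quad g = J\,d,$$
$$\widehat{var}(g) = J^2\left[\frac{n_1 + n_2}{n_1 n_2} +
  \frac{d^2}{2(n_1 + n_2 - 2)}\right].$$

Positive g means more removal under low-intensity management. The
random-effects model for the effects is

$$g_i = \mathbf{x}_i'\boldsymbol\beta + u_i + e_i, \qquad
  \mathbf{u} \sim N(0,\ \tau^2 R(\rho)), \qquad
  e_i \sim N(0,\ \widehat{var}(g_i)),$$

with $R(\rho)$ one of five correlation structures of great-circle
distance $d_{ij}$ (haversine, Earth radius 6371 km): identity
("none"), exponential $e^{-d/\rho}$, Gaussian $e^{-(d/\rho)^2}$,
rational quadratic $1/(1 + (d/\rho)^2)$, and spherical
$1 - 1.5(d/\rho) + 0.5(d/\rho)^3$ for $d < \rho$ (0 beyond).

Numerical choices:

* $(\tau^2, \rho)$ maximize the **restricted likelihood** (REML rather
  than a moment estimator, because the spatial structures require
  likelihood-based fitting and AICc comparison). Both parameters are
  optimized on the log scale for positivity; the structure-free profile
  uses a coarse grid plus golden-section refinement, the spatial profiles
  use Nelder–Mead from three distance-quantile starts, keeping the best.
  A boundary check maps optima at the lower edge to $\tau^2 \approx 0$.
* Coefficients are GLS at the optimum. Their covariance carries the
  Knapp–Hartung scaling factor $s^2 = \mathbf{r}'V^{-1}\mathbf{r}/(n-p)$
  (untruncated), and tests use t distributions with $df = n - m - 1$
  ($m$ moderators; $n - 1$ for the pooled mean). This small-sample
  treatment keeps the moderator t-test close to its nominal size at
  $n = 38$, which the acceptance suite verifies by simulation.
* Heterogeneity: $Q$ is the fixed-effect weighted residual sum of squares
  with $df = n - 1$ and a chi-square p-value;
  $I^2 = \hat\tau^2 / (\hat\tau^2 + \tilde s^2)$ with the typical
  within-study variance
  $\tilde s^2 = (n-1)\sum w_i / \left[(\sum w_i)^2 - \sum w_i^2\right]$,
  $w_i = 1/\widehat{var}(g_i)$.
* Structures are compared by
  $AICc = -2\,\ell_{REML} + 2k + 2k(k+1)/(n-k-1)$ with $k$ = number of
  variance/correlation parameters + 1 (2 for "none", 3 for spatial).
* Meta-regression reports per-moderator t tests, an omnibus Wald F on
  $(m, n-m-1)$ df, variance inflation factors from the inverse moderator
  correlation matrix, and pseudo-$R^2$ = proportional reduction of
  $\hat\tau^2$ against the intercept-only model under the same structure,
  floored at 0 because sampling noise can push the residual $\tau^2$
  above the null value. Collinear moderator sets (condition number
  > 10^6) are rejected with advice to summarize them first — which is
  exactly what the PCA stage is for. Whether $\rho$ should be profiled or
  fixed per structure is genuinely open; the package optimizes it jointly
  with $\tau^2$.
* Anthelmintic-use variation is not offered as a default moderator: it is
  collinear with cattle density in this design.

The paired Wilcoxon comparisons of raw metrics use the exact signed-rank
null for up to 25 untied non-zero differences and the normal
approximation with continuity correction beyond.

# Piecewise SEM

Each endogenous variable gets a linear mixed model with a biogeographical
region random intercept (REML; Satterthwaite df for the t tests —
residual-df OLS inference is the documented fallback when the random
variance is singular or the grouping has fewer than two levels).
Landscape is *not* a grouping factor: it would contribute only two
non-independent observations per cluster.

The d-separation basis set contains one claim per non-adjacent node pair,
conditioning on the union of both nodes' parents; the response is the
later node in topological order (name ties broken alphabetically) so the
set is deterministic. Pairs declared as correlated errors (`a ~~ b`) are
excluded from the basis set — the correlation is acknowledged without a
causal claim and without joint covariance estimation. Global fit is
Fisher's $C = -2\sum \ln p_i \sim \chi^2_{2k}$; an empty basis set gives
$C = 0$, $p = 1$ by convention, and p-values of exactly zero upstream
are floored at the smallest positive double. When the global p-value
falls at or below 0.05 the most significant violated claim is *reported*
as a suggested path; nothing is ever added automatically, because path
additions must be biologically plausible — a human judgment.

Standardized coefficients are $\beta_{std} = \beta\,sd(x)/sd(y)$ over the
analysis sample, with the binary regime coded 0/1 before standardization;
per-response fit is Nakagawa marginal / conditional $r^2$
(fixed vs fixed + random variance over the total).

The shipped model file (`default_sem_model()`) is a **reconstruction** of
the across-site conceptual model — management regime, cattle density,
anthelmintic use and climate driving the four community metrics, which
drive dung removal, with a direct climate → removal path and richness →
FDisBehavior — and is swappable via `run_pipeline(dag_file = ...)`. Land
history is deliberately absent. Exogenous management descriptors covary
by construction (the regime is *defined* by stocking rate), so they are
tied by correlated-error lines rather than tested for independence; the
same applies to abundance–richness and the two FDis indices, which share
underlying community processes.

# The synthetic generator

`synthetic_config()` defaults are the study conditions — fixed once to
the paired design and to effect scales realistic for worldwide field
experiments of this kind — and are not tuning knobs:

* 38 landscapes in 6 regions; 10 experimental + 5 control pats per
  pasture; 300 g pats; site water proportion uniform in [0.70, 0.85]
  (shared by the paired pastures, which sit a few km apart under the same
  weather — this also makes the fully noise-free limit exact);
* effect model $\theta_i = \gamma_0 + \gamma_1 x_i + u_i$ with
  $\gamma_0 = 0$ (no systematic removal advantage of either regime),
  $\gamma_1 = 0.4$ (a moderate, detectable diversity-moderator slope),
  $\tau = 1.5$ so $\tau^2 = 2.25$ — strong genuine between-site
  heterogeneity — and the moderator $x_i$ the z-scored FDisBehavior
  difference of the generated communities;
* replicate SD 6 g on a ~25–40 g removal scale, giving Hedges-g sampling
  variances near 0.25 and hence $I^2 \approx 0.9$;
* low-intensity richness Poisson with mean 12 from regional pools of 40
  species; high-intensity communities are a binomial thinning (retention
  0.75) plus a small immigration term (mean 0.5 species), so richness is
  clearly and consistently higher under low intensity while functional
  diversity differences stay centred near zero and can take either sign;
* guild probabilities 0.40/0.25/0.25/0.10
  (paracoprid/telecoprid/endocoprid/kleptocoprid), log-normal body
  lengths (median 12 mm, log-SD 0.45) spanning all three size classes,
  allometric trait means with 5% individual scatter, cube-law biomass;
* 13 bioclim columns built from a latitude-driven temperature gradient
  and a seasonality gradient plus noise, so the climate PCA has a
  dominant, interpretable first axis;
* one pseudo-random stream per table, each derived from the master seed,
  so adding a table never perturbs the others; pat weights are
  back-computed on the dry scale so the removal equations invert cleanly.

What the generator does **not** emulate: real species pools or their
biogeography, real Worldclim values, trait–guild correlations beyond
size, rainfall events (negative removal), or observation error in
abundance counts. Passing recovery tests therefore demonstrate that the
estimators recover the parameters of *this* statistical structure, not
that the field data satisfy it.

# Problem sizes used by the test and acceptance suites

Simulation-based checks run at sizes chosen to give informative
Monte-Carlo error on a single CPU: 500 replicates for the
type-I-error calibration of the meta-regression t-test (nominal 5%,
accepted 3–7%), 300 for slope recovery, 200 for the null-heterogeneity
and SEM global-fit calibrations, 30–40 random DAGs (plus all 25 DAGs on
three labelled nodes) for the basis-set enumeration property, and
30-replicate recovery runs in the acceptance script. The worked examples
use 8-landscape studies; the acceptance script uses the full 38-landscape
default.

# Known limitations

* The spatial meta-model estimates a single global $(\tau^2, \rho)$; no
  nugget term and no multilevel extensions.
* The d-separation tests inherit the approximations of mixed-model
  p-values; with few regions the Satterthwaite df can be small.
* Pseudo-$R^2$ is a heuristic (variance-reduction) measure and is floored
  at zero.
* Correlated errors are excluded from testing, not estimated; a
  covariance-based SEM would treat them differently.
* The evenness convention (Pielou) and the medium-inclusive size-class
  boundaries are documented decisions where the field usage varies.

# A minimal session

```{r example, eval = FALSE}
study <- generate_study(synthetic_config(seed = 1))
report <- run_pipeline(study$bundle, out_dir = "results")
print(report)
```
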