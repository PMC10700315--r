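# grazemeta

Analysis pipeline for paired grazing-intensification experiments on dung
beetle communities and the dung removal they provide.

## The scientific problem

In each of many landscapes, a field team compares two pastures: one under
low-intensity cattle management (< 2 animals/ha) and one under
high-intensity management (> 4 animals/ha). In each pasture, ten 300 g
experimental dung pats (plus five mesh-covered controls that measure
evaporation) are exposed for 48 h, the beetle community is trapped and
identified to species with guild labels and individual trait
measurements, and management covariates plus 13 bioclimatic variables are
recorded. The questions: does intensification change dung beetle
diversity and dung removal within sites, and what drives removal across
sites?

`grazemeta` implements the full chain:

* **Removal rates.** Per pat, the water proportion
  `WP = (FWwet − FWdry)/FWwet` corrects the initial dry mass
  `IWdry = IWwet (1 − WP)`, and the removal rate is
  `DRR = IWdry − FWdry` (g dry / 48 h). `WP` comes from the control pats
  (default) or from each pat's own weights.
* **Community metrics.** Abundance, richness, Pielou evenness, and two
  functional dispersion indices, each the mean pairwise distance among
  the species present: *FDisMorphology* (nine z-scored morphological
  traits + log biomass, Euclidean) and *FDisBehavior* (cophenetic
  distances on a fixed phenetic tree of 12 guild-by-size functional
  groups, with behaviour at the root).
* **Effect sizes and meta-analysis.** Per landscape, Hedges'
  `g = J (ȳ_low − ȳ_high)/s_pooled` with
  `J = 1 − 3/(4(n₁+n₂−2)−1)`; a random-effects model
  `g_i = x_i'β + u_i + e_i`, `u ~ N(0, τ² R(ρ))`, fitted by REML with
  five candidate spatial correlation structures of great-circle distance
  (none, exponential, Gaussian, rational quadratic, spherical) compared
  by AICc; heterogeneity (`Q`, `I²`), meta-regression with
  Knapp–Hartung-style t/F tests on `n − m − 1` df, VIFs and pseudo-R²;
  paired Wilcoxon comparisons of the raw metrics.
* **PCA summaries.** Correlation-matrix PCAs of climate and of the
  paired (low − high) diversity differences, orientation anchored so the
  scores have a fixed interpretation.
* **Piecewise SEM.** Component linear mixed models with a region random
  intercept, a d-separation basis set over the non-adjacent node pairs,
  Fisher's `C = −2 Σ ln pᵢ ~ χ²(2k)`, standardized coefficients, and
  Nakagawa marginal/conditional r².
* **Synthetic studies.** `generate_study()` builds a complete validated
  dataset (38 landscapes by default) with known ground truth
  (`γ₀, γ₁, τ`), and `recovery_experiment()` measures estimator bias,
  RMSE and CI coverage against it.

See the vignette in `vignettes/grazing-intensification-pipeline.Rmd` for
the models, all numerical decisions, and the generator's assumptions.

## Worked example

```r
library(grazemeta)

# the bias-corrected standardized mean difference, by hand-checkable input
hedges_g(c(2, 3, 4), c(1, 2, 3))[c("d", "J", "g")]
#> $d
#> [1] 1
#> $J
#> [1] 0.8
#> $g
#> [1] 0.8

# a small synthetic study, end to end
study <- generate_study(synthetic_config(seed = 1, n_landscapes = 8L,
                                         n_regions = 3L, pool_size = 18L,
                                         richness_low = 8))
report <- run_pipeline(study$bundle, structures = c("none", "exponential"))
print(report$pooled$best)
#> Random-effects model (REML), structure = none
#> tau^2 = 1.0342   Q = 35.58 (df = 7, p = 8.69e-06)   I^2 = 0.826
#> logLik(REML) = -11.947   AICc = 30.29
#>       term estimate     se       t df      p
#>  intercept  -0.6139 0.4059 -1.5123  7 0.1742

head(report$effects, 3)
#>   landscape_id          g     var_g n_low n_high  latitude  longitude
#> 1          L01 -0.2453401 0.1851277    10     10 -36.35343  -53.84236
#> 2          L02 -1.4640888 0.2429989    10     10  29.26803  -78.30819
#> 3          L03 -1.0280357 0.2128128    10     10  45.93785 -111.15128
```

Reading the output: each row of `effects` is one landscape's
standardized within-site difference in dung removal (positive = more
removal under low-intensity management) with its sampling variance and
the coordinates used for the spatial correlation structures. The pooled
fit says the eight true effects scatter far more than sampling error
alone would allow (`I² = 0.83`, `Q` highly significant) around a pooled
mean that is not distinguishable from zero at this sample size (`t` on
7 df, `p = 0.17`). With real or full-size synthetic data,
`report$metareg` holds the moderator analysis (climate score,
cattle-density difference, diversity score) and `report$sem` the
piecewise SEM with Fisher's C.

Field data are read from five CSV tables (`sites.csv`,
`covariates.csv`, `dungpats.csv`, `occurrences.csv`, `traits.csv`) via
`read_tables()`; the column contract is documented in
`inst/extdata/schema.csv`, and validation errors name the offending
column or row.

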