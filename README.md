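# hilltopdyn

Spatial population dynamics for insects that *hilltop*: adults leave their
natal habitat patch, aggregate to mate at topographic high points (leks),
and disperse from there to larval patches. Most metapopulation models assume
random, distance-only dispersal; `hilltopdyn` is for ecologists who want to
test that assumption against behaviour-informed alternatives in a patchily
distributed population with annual census data, and to ask what routing
dispersal through hilltops does to patch occupancy, turnover and regional
synchrony.

The package provides:

* **Connectivity indices** built on an exponential dispersal kernel
  `exp(-α d)` (α in km⁻¹, default 1):
  * `hanski_ci()` — direct patch-to-patch:
    `CI_it = Σ_{j≠i} exp(-α d_ij) A_jt`, with `A` log abundance;
  * `hilltop_ci()` — patch → hilltop → patch routed:
    `HCI_it = Σ_j exp(-α d_ij) · z(Σ_k exp(-α d_jk) A_kt)`;
  * `elevation_ci()` — hilltop-routed with elevation-weighted predicted
    adult counts `M_jt = −0.89 + 1.27·z(ln CI_jt) + 0.02·Elev_j`;
  * `hilltop_exposure()` — patch exposure to observed adult counts.
* **Hierarchical Bayesian models** (JAGS via `rjags`), with WAIC model
  comparison: a Poisson GLMM of adult counts on hilltops
  (`fit_moth_glmm()`, `compare_moth_models()`), a log-normal model of
  next-year caterpillar counts against hilltop exposure
  (`fit_hilltop_to_patch_model()`), and a Gompertz AR(2) log-linear
  time-series model of patch censuses with climate covariates, patch random
  intercepts and patch-specific variances (`fit_ts_model()`,
  `compare_ts_models()` — a nine-structure grid, each
  connectivity-containing structure fitted with CI, HCI and ECI).
* **A stochastic metapopulation simulator** (`simulate_metapop()`,
  `run_experiment()`): Poisson demographic noise around the fitted model's
  predictions, connectivity recomputed each year from the simulated state
  and standardized with scalers frozen on the observed data, empirical
  climate replayed; summarized as occupancy, colonization and extinction
  rates and regional synchrony.
* **Synthetic-data generators** (`make_bodega_like_scenario()`,
  `gen_bundle()`) emulating the full survey design — 12 patches, 7
  hilltops, 15 census years, 10/15/20 bushes per patch-year — so the whole
  pipeline is testable end to end without field data.

Inputs are plain CSV (patches, hilltops, long-format censuses, climate,
moth counts); see `read_landscape()`, `read_census()`, `read_climate()`,
`read_moths()`.

## A worked example

```r
library(hilltopdyn)

# a synthetic study system: 12 patches, 7 hilltops, 15 census years
b <- gen_bundle(make_bodega_like_scenario(42))
A <- log_abundance(b$census$panel)          # ln(mean count per bush + 1)

# which model structure explains adult counts on hilltops?
frame <- build_moth_frame(b$moths$panel, b$landscape, b$census$panel)
compare_moth_models(frame, sampler_config(seed = 1))$table
#>                                 model_structure   waic delta_waic
#> 1                        Connectivity+Elevation 231.39     0.0000
#> 2 Connectivity+Elevation+Connectivity:Elevation 233.61     2.2173
#> 3                                  Connectivity 233.91     2.5180
#> 4                                     Elevation 236.22     4.8303
#> 5                                Intercept only 236.25     4.8581
```

The generating structure (connectivity + elevation, the data were simulated
with both effects) attains the lowest WAIC; the intercept-only model sits
4.9 WAIC behind.

```r
# fit the full time-series model with the direct (Hanski) index
ci    <- hanski_ci(b$landscape, A)
spec  <- ts_model_spec(connectivity_kind = "CI")
tsf   <- build_ts_design(b$census$panel, b$climate, ci, spec)
fit   <- fit_ts_model(tsf, spec, sampler_config(seed = 2))
waic(fit$pointwise_loglik)
#> WAIC 139.78  (lppd -45.44, p_waic 24.45, n = 156)

round(unlist(ts_posterior_means(fit)[c("a0", "a1", "a2", "b_precip",
                                       "b_temp", "b_int", "b_conn")]), 3)
#>       a0       a1       a2 b_precip   b_temp    b_int   b_conn
#>    1.304    0.444   -0.254    0.374    0.254    0.157    0.293
```

The posterior means sit near the generator's truth (1.0, 0.5, −0.2, 0.4,
0.3, 0.3, 0.3): direct density dependence ~0.44, delayed density dependence
negative, climate effects comparable to the connectivity effect.

```r
# simulate the fitted model under the three dispersal modes
ex <- run_experiment(b$landscape, ts_posterior_means(fit), b$climate,
                     b$census$panel, sim_config(n_reps = 300, seed = 1))
ex$medians
#>   kind occupancy colonization extinction synchrony
#> 1   CI     0.978            1    0.02424     0.398
#> 2  HCI     0.994            1    0.00599     0.527
#> 3  ECI     0.989            1    0.01205     0.452
```

Each row is the median over 300 replicate trajectories of 15 years under
one connectivity index, with a shared seed schedule (with `b_conn = 0` the
three rows would be identical). The dispersal-contrast experiment proper
uses `make_contrast_scenario()`, whose clustered topology separates the
dispersal modes much more sharply — see the methods vignette
(`vignettes/hilltopdyn-methods.Rmd`), which also documents the model
formulations, priors, scaling conventions and known limitations.

A thin command-line wrapper over the same workflows is installed at
`inst/exec/hilltopdyn` (`synth`, `indices`, `moth-models`, `ts-grid`,
`simulate`, driven by a YAML config; see `run_config()`).

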