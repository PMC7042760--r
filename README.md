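# pollinet

Quantitative plant–pollinator network analysis along environmental
gradients.

Ecologists studying mutualistic interactions on elevational or land-use
gradients record flower visits on standardized transect walks and ask how
the architecture of the resulting interaction networks — who visits whom,
and how exclusively — changes with temperature, land use and resources.
pollinet implements that full analysis chain for count-valued bipartite
networks:

- **Assembly** of one plant × pollinator count matrix per transect walk
  from long-format records, with the field-standard filters (pollinator
  groups kept, minimum of five interaction events per network, optional
  pooling of replicated walks per site).
- **Specialization and structure indices.** Species-level specialization
  d′ — the Kullback–Leibler divergence of a species' partner use from
  partner availability, `d = Σ (a_k/A) ln((a_k/A)/q_k)`, standardized
  between its integer-achievable extremes to [0, 1]; community
  (abundance-weighted) means and coefficients of variation; network-level
  complementary specialization H₂′ (two-dimensional entropy standardized
  between marginal-constrained extremes); weighted nestedness (WNODF);
  and signed dependence asymmetry.
- **Null models.** Fixed-marginal (Patefield) sampling of random networks
  and z-score standardization of any metric, used for "standardized
  nestedness" and "standardized robustness".
- **Robustness** to species loss: secondary-extinction curves under random
  removal orders and the area-under-curve robustness R.
- **Land-use intensity**: the composite index averaging standardized
  biomass-removal, input, vegetation-dissimilarity and landscape
  components.
- **Gradient models**: linear mixed-effects models (random site
  intercepts) of each metric against elevation, AICc comparison against
  land-use intensity, Nakagawa-style semipartial R², intraspecific and
  trait/taxon models with crossed or nested random effects, backward
  elimination for robustness predictors, and a five-part sensitivity
  suite.
- **Piecewise path analysis**: DAGs of component mixed models,
  d-separation basis sets, Fisher's C (`C = −2 Σ ln p ~ χ²₂ₖ`), AICc
  ranking over all optional-path combinations, and block-wise variable
  preselection.
- **A synthetic-study generator** with known ground truth (Dirichlet-
  multinomial foraging preferences whose concentration falls with
  temperature), so every stage is testable end to end without field data.

## Worked example

```r
library(pollinet)
library(dplyr)

study <- simulate_gradient_study(seed = 1)
#> <synthetic_study> 18 sites, 87 walks, 2772 interaction events (a1 = 0.2, seed = 1)

networks <- build_networks(study$interactions) |>
  filter_networks(min_interactions = 5)
#> filter_networks: removed 2 network(s) with fewer than 5 interactions.

metrics <- network_metrics(networks) |> left_join(study$sites, by = "site_id")
metrics[1:3, c("walk_id", "m", "H2_prime", "wnodf", "dep_asym",
               "mean_dprime_pollinators")]
#>   walk_id     m H2_prime wnodf dep_asym mean_dprime_pollinators
#> 1 s01_w01   249    0.862 11.0    0.550                    0.671
#> 2 s02_w01    73    0.911 10.7    0.291                    0.724
#> 3 s02_w02    36    0.752  5.56   0.0881                   0.660
```

Each row describes one walk's network: `m` interaction events, network
specialization `H2_prime` in [0, 1] (high = pollinators partition the
plants), weighted nestedness on the 0–100 scale, dependence asymmetry
(positive = pollinators depend more on plants than vice versa) and the
abundance-weighted community mean of pollinator d′.

The gradient stage fits the mixed model and prints slope, SE,
containment df, t and the fixed-effect R²:

```r
fit_metric_vs_elevation(metrics, "mean_dprime_pollinators")
#> <lmm_fit> mean_dprime_pollinators (nlme), n = 85, groups = 18
#>          term  estimate std_error df statistic   p_value
#> 1 (Intercept)  0.741346  7.62e-02 67     9.729 1.928e-14
#> 2   elevation -0.000121  2.55e-05 16    -4.745 2.197e-04
#> random sd = 0.08, residual sd = 0.137, R2(fixed) = 0.336, AICc(ML) = -73.6312
```

Pollinator communities in this simulated study lose about 0.12 units of
d′ per 1,000 m of elevation (t = −4.7 on 16 df): communities are more
specialized where it is warm, the structure the generator encodes.
Robustness and null standardization work per network:

```r
robustness(networks$network[[2]], "pollinator", n_orders = 100, seed = 1)
#> <extinction_result> walk s02_w01, removing pollinators: R = 0.6322 (MC se 0.00651, 100 orders)

standardize_metric(networks$network[[2]], wnodf, n_null = 200, seed = 1,
                   metric_name = "wnodf")
#> <null_ensemble> wnodf: observed = 10.71, null 24.05 +/- 3.337, z = -3.999
```

The walk's network retains 63% of the area under the extinction curve and
is significantly *less* nested than expected under fixed marginal totals
(z ≈ −4). Fitted objects support `tidy()`, `glance()` and `autoplot()`;
`sem_model()` / `sem_fit()` / `exhaustive_path_search()` run the path
analysis (see the methods vignette in `vignettes/`).

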