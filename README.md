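# herdlife

Genetic evaluation of longevity in beef cattle with Bayesian random
regression animal models (RRM).

Longevity — how long a cow stays productive in the herd after her first
calving — is a sex-limited, late-recorded trait, and culling happens for
genetically different reasons (natural death, structural problems,
disease, fertility, performance, or no recorded reason at all).
`herdlife` implements the full evaluation chain for yearly longevity
indicators recorded from 2 to 15 years of age:

* **Trait construction.** Quality control of cow life-history records and
  coding of three binary longevity definitions per cow and age:
  traditional longevity (TL: 1 while alive, 0 after culling), functional
  longevity without missing codes (FLa: 1 if calved at that age, 0
  otherwise) and with missing codes (FLb: 0 only after culling, `NA` while
  alive without a calving record), plus the seven culling-reason groups.
* **The model.** Single- or multiple-trait linear RRM on the binary codes,

  y = Xb + Hq + Za + Wp + e,

  where every effect is a Legendre polynomial regression on standardized
  age: fixed year-season-of-birth curves and an embryo-transfer contrast
  (b), and random herd-year-season (q), additive genetic (a) and permanent
  environmental (p) coefficient vectors with coefficient covariance
  matrices Rq, G0, Rp. Additive coefficients are correlated through the
  pedigree, a ~ N(0, G0 ⊗ A); the residual variance is homogeneous or has
  one class per age. A Gibbs sampler (RcppArmadillo) draws location
  effects block-wise from their Gaussian full conditionals, covariance
  matrices from inverted-Wishart conditionals, and residual classes from
  scaled inverse chi-square conditionals.
* **Pedigree machinery.** Pruning to ancestors of phenotyped animals,
  Meuwissen–Luo inbreeding, and Henderson's sparse A⁻¹ with inbreeding
  (plus a dense tabular oracle for testing).
* **Model choice and diagnostics.** DIC = D(θ̄) + 2pD, posterior model
  probabilities PMP_s = exp(−Δ_s/2)/Σ exp(−Δ_r/2), and the Geweke
  convergence diagnostic.
* **Genetic parameters.** Age-wise covariances φ = T Rq T′, Σ = T G0 T′,
  θ = T Rp T′; heritabilities h²_j = σ²a_j / (σ²a_j + σ²q_j + σ²p_j +
  σ²e_j) with per-draw posterior SEs; genetic correlations within and
  between traits; windowed averages (all ages vs 3–12 years).
* **Selection metrics.** EBV = T â over ages, relative breeding values
  standardized to mean 100 / SD 5, top-fraction sire sets and
  commonly-selected percentages, observed daughter metrics, expected
  daughter longevity (EDL = b0 + b1·RBV) and its prediction accuracy.
* **Synthetic data.** A seeded simulator of pedigrees, true breeding
  values and life histories with the statistical structure the model
  assumes, so every stage is testable without proprietary data.

## Worked example

Simulate a small pedigreed population, build the traditional-longevity
panel, fit a quadratic RRM and derive parameters and sire metrics:

```r
library(herdlife)

cfg <- sim_config(n_founders = 40, n_generations = 2,
                  offspring_per_mating = 4, seed = 2025)
ped <- simulate_pedigree(cfg)
tv  <- simulate_true_values(ped, cfg)
lh  <- simulate_life_histories(ped, tv, cfg)

qc    <- apply_quality_control(lh$records)
panel <- build_longevity_panel(qc$records, "TL")
panel
#> <longevity_panel> definition: TL - 180 cows x 14 ages; 0 missing codes

des <- build_design(list(TL = panel), qc$records,
                    rrm_spec(order = 2, residual_structure = "homogeneous"))
fit <- gibbs_fit(des, ped,
                 chain_config(length = 4000, burn_in = 2000, thin = 5,
                              seed = 2025))

genetic_parameters(fit)$h2 |> head(4)
#> # A tibble: 4 x 6
#>   trait   age  mean     se  lower upper
#>   <chr> <int> <dbl>  <dbl>  <dbl> <dbl>
#> 1 TL        2 0.244 0.0548 0.147  0.358
#> 2 TL        3 0.200 0.0565 0.108  0.323
#> 3 TL        4 0.168 0.0599 0.0775 0.306
#> 4 TL        5 0.150 0.0616 0.0621 0.303
```

The posterior mean heritability of staying in the herd is about 0.15–0.24
at these ages, with 95% credible intervals from the per-draw transform.
Sire selection at 4 years:

```r
st  <- sire_ebv_table(fit)
sel <- dplyr::filter(st, age == 4) |> dplyr::mutate(rbv = rbv(ebv))
om  <- observed_daughter_metrics(qc$records, ped)
j   <- dplyr::inner_join(sel, om, by = "sire_id") |>
  dplyr::filter(n_daughters.x > 5)

edl <- fit_edl(j$rbv, j$avg_culling_age, label = "avg_culling_age",
               age_at_selection = 4)
edl
#> <edl_model> avg_culling_age : EDL = -13.348 + 0.21864 x RBV

prediction_accuracy(predict(edl, j$rbv), j$avg_culling_age)
#> [1] 0.699
```

Each RBV point (one fifth of a genetic standard deviation) is worth about
0.22 years of expected daughter herd life in this simulated population,
and the EDL predicts the observed daughter culling age with a Pearson
correlation of 0.70 across the 12 eligible sires. `plot_heritability()`,
`plot_correlations()` and `autoplot()` visualize the results;
`run_pipeline()` chains all stages into an output directory of delimited
text artifacts.

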