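# twinrisk

Classical twin-design analysis of an age-dependent dichotomous endpoint
observed through an administrative register window, under right
censoring and the competing risk of death.  The motivating setting is a
national twin register linked to a knee-arthroplasty register: tens of
thousands of twin pairs, a late-onset surgical endpoint (total knee
arthroplasty for primary knee osteoarthritis), follow-up restricted to
a 13-year window, and entry at whatever age each twin had when the
window opened.

The package is for epidemiologists and biostatisticians who want the
whole chain in one tested place:

* **Liability-threshold biometrics.** A dichotomous trait is modelled
  as a thresholded standard-normal liability; twin-pair liabilities are
  bivariate normal with correlation `rho_MZ = a² + d² + c²`,
  `rho_DZ = a²/2 + d²/4 + c²`.  `fit_model()` fits saturated, ACE,
  ADE, AE, CE, DE and E models by (optionally IPC-weighted)
  bivariate-probit maximum likelihood, sex-stratified or sex-adjusted;
  `compare_models()` ranks them by likelihood-ratio tests and AIC.
  Broad-sense heritability `H = clip(2(rho_MZ − rho_DZ), 0, 1)` and
  the closed-form identities `A = 2(rMZ − rDZ)`, `C = 2rDZ − rMZ`,
  `E = 1 − rMZ` are exposed directly (`falconer_H()`,
  `ace_from_correlations()`).
* **Tetrachoric correlations** by full maximum likelihood
  (`fit_tetrachoric()`), built on an in-package Genz quadrature for the
  bivariate normal orthant (`bvn_orthant()`, ~1e-15 accuracy).
* **Concordance.** Pair-count tables, case-wise/proband-wise
  concordance `2C/(2C + D)`, within-pair independence screens, and the
  age-indexed proband-wise concordance function with pair-bootstrap
  bands (`concordance_function()`).
* **Competing risks on the age scale.** Aalen–Johansen cause-specific
  cumulative incidence with delayed entry (`aalen_johansen()`),
  censoring-distribution Kaplan–Meier, and inverse probability of
  censoring weights (`ipc_weights()`).
* **A synthetic twin-cohort generator** (`simulate_cohort()`,
  `default_scenario()`) with known A/D/C/E structure, sex-specific
  lifetime risks, Weibull onset after age 50, Gompertz mortality and a
  13-year observation window — so every estimator is testable without
  register access.
* **A pipeline** (`run_pipeline()`, `twinrisk_cli()`) that turns a
  config into the full report bundle: cohort summary,
  concordance/tetrachoric table, model grids, incidence and
  concordance curves, age-resolved heritability, as TSV + JSON.

## Worked example

Tetrachoric correlation of a published-style pair-count table
(10 concordant-affected, 52 discordant, 4701 concordant-unaffected
female MZ pairs):

```r
library(twinrisk)
fit_tetrachoric(pair_counts(n_cc = 10, n_d = 52, n_uu = 4701))
#> Tetrachoric fit (full_ml): rho = 0.7286 (se 0.0653), thresholds = 2.4296 / 2.4296
#>   logLik = -358.1594; converged: TRUE
```

The correlation 0.73 says that the latent liabilities of these MZ
co-twins are strongly correlated even though only 10 pairs are
concordant-affected: with a prevalence of 0.72% the threshold sits at
2.43 liability SDs, so concordant pairs are rare even under strong
familial resemblance.

Simulate a cohort with known structure and fit the model grid:

```r
p <- simulation_params(n_mz = 5000, n_dz_ss = 5000, n_dz_os = 0,
                       a2 = 0.18, d2 = 0, c2 = 0.61, e2 = 0.21,
                       lifetime_risk_F = 0.1, lifetime_risk_M = 0.1,
                       gompertz_a = 0, window_length = Inf,
                       birth_year_range = c(1997, 1997), seed = 1)
pairs <- assemble_pairs(simulate_cohort(p))$pairs
fits <- list(sat = fit_model(model_spec("sat"), pairs),
             ACE = fit_model(model_spec("ACE"), pairs),
             CE  = fit_model(model_spec("CE"),  pairs),
             E   = fit_model(model_spec("E"),   pairs))
fits$ACE
#> Biometric ACE model (adjusted): logLik -5191.76, AIC 10391.51, 10000 pairs
#>   A=0.237 D=0.000 C=0.579 E=0.184  H=0.237
#>   rho_MZ=0.816 rho_DZ=0.698  cwc_MZ=0.582 cwc_DZ=0.468  prev F=0.1022 M=0.1010
compare_models(fits)$aic
#>   model n_parameters    logLik      AIC
#> 1   ACE            4 -5191.757 10391.51
#> 2   sat            4 -5191.757 10391.51
#> 3    CE            3 -5202.099 10410.20
#> 4     E            2 -5907.827 11819.65
```

The generating values A = 0.18, C = 0.61, E = 0.21 are recovered within
sampling noise at 10,000 pairs (A is the noisiest component: the MZ–DZ
correlation difference is doubled).  ACE and the saturated model tie
(with one zygosity pair of correlations, ACE is just-identified), CE
fits significantly worse (LR = 20.7 on 1 df, p = 5.4e-06), and the AIC
ranking agrees.

Full pipeline from a config:

```r
run_pipeline(run_config(seed = 1), out_dir = "out")    # registry-scale default
# or: Rscript -e 'twinrisk::twinrisk_cli()' --seed 1 --out out
```

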