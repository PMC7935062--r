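# flpscape

Tools for quantifying and analysing **female-limited plumage polymorphism
(FLP)** — the co-occurrence, within a bird species, of a male-like
(*androchrome*) female morph and a distinct (*heterochrome*) morph — on
phylogenies, with hummingbirds as the motivating radiation.

The package covers the full analysis chain:

* **Specimen scoring & classification** — ordinal androchromy classes (1–4)
  binarised into morphs; a species *exhibits* FLP when ≥ 10% of its females
  are androchromic **and** the female score distribution rejects
  unimodality, and *lacks* FLP when ≥ 19 females were sampled without
  meeting that rule (19 females give an 85% chance of catching a morph at
  10% frequency, since `1 − 0.9^18 = 0.85`). An eight-matrix sensitivity
  grid varies the thresholds.
* **Hartigan's dip test** — the dip statistic
  `D(F_n) = min over unimodal G of sup |F_n − G|` computed to near machine
  precision (Rcpp), with a uniform-bootstrap calibration and seeded jitter
  for tied ordinal scores.
* **Mk models & ancestral states** — three-state (monochromic, dichromic,
  FLP) continuous-time Markov models under ER/SYM/ARD constraints,
  maximum-likelihood fitting (Felsenstein pruning in C++), small-sample
  AICc selection (ΔAICc < 2 best set), marginal ancestral-state
  reconstruction, independent-origin counts, and root-state stability under
  random tip pruning.
* **Discriminant androchromy scores** — per-species PCA + linear
  discriminant separating androchrome males from Class-1 females
  (leave-one-out validated), LD1 projections standardised to the training
  centroids (±1), OLS slopes of relative bill length on LD1 at a
  Bonferroni-corrected α, and Blomberg's K with permutation p-values.
* **Phylogenetic GLS** — Brownian-covariance regressions of the binary FLP
  state on social (migration, dominance, body size) and climate predictor
  sets, `b = (X'V⁻¹X)⁻¹X'V⁻¹y`, with optional exclusion of monochromic
  species.
* **Synthetic data** — a fully seeded generator (Yule trees, Mk tip states,
  ordinal score mixtures, two-cluster patch colours with plantable
  bill-length slopes, Brownian covariates with plantable FLP effects) so
  every stage can be exercised and calibrated without museum data.

Everything is tidyverse-shaped: tibbles in and out, `tidy()`/`glance()`
methods for fitted objects, `autoplot()`/`plot_*()` figures.

## A worked example

```r
library(flpscape)

# a synthetic 30-species study: tree, specimens, colours, covariates
study <- simulate_flp_study(simulation_spec(n_species = 30), seed = 42)

# classify species from female score distributions
s <- summarize_species(study$specimens, n_boot = 300, seed = 1)
cls <- classify_species(s, study$dichromatism)
dplyr::count(cls, status)
#> # A tibble: 2 × 2
#>   status               n
#>   <fct>            <int>
#> 1 FLP                  3
#> 2 no_FLP_dichromic    27

# fit Mk models to the classified states and reconstruct ancestral states
states <- classification_to_states(cls)
tr <- prune_to_data(study$tree, names(states))
fits <- lapply(c("ER", "SYM", "ARD"), function(m)
  fit_mk_model(tr, states, m, seed = 1))
select_models(fits)
#>   model   logL k n_tips aicc delta_aicc in_best_set
#> 1    ER -13.21 1     30 28.6      0.000        TRUE
#> 2   SYM -11.10 3     30 29.1      0.552        TRUE
#> 3   ARD  -9.39 6     30 34.4      5.870       FALSE

asr <- marginal_asr(tr, states, attr(select_models(fits), "fits")[[1]]$q_matrix)
count_independent_origins(asr, "FLP")
#> [1] 3

# phylogenetic regression of FLP on social covariates
fit <- run_flp_models(study$covariates, study$tree, "social",
                      exclude_monochromic = TRUE)
tidy(fit)
#>          term estimate std_error statistic p_value
#> 1 (Intercept)   1.2178    0.7647      1.59   0.129
#> 2   migratory   0.5465    0.3560      1.54   0.142
#> 3   dominance  -0.6299    0.3771     -1.67   0.112
#> 4 body_length  -0.0635    0.0579     -1.10   0.287
```

The generating process gave 7 of the 30 species a true polymorphism; the
conservative decision rule (which demands both a ≥ 10% androchrome
proportion and a significant dip test on 30 females) recovers 3 of them and
assigns the rest to the well-sampled no-FLP class. The equal-rates model is
preferred by AICc (with SYM inside the ΔAICc < 2 set), and the
reconstruction counts three independent FLP origins on this small tree.
With no planted covariate effects, no social predictor is significant — as
it should be.

`run_pipeline(pipeline_config(simulation = simulation_spec(...)), out_dir)`
chains all stages and writes CSV artefacts, a manifest (seeds, checksums,
stage timings) and a human-readable report.

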