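# sees

Tools for the **Subjective Evidence Evaluation Survey (SEES)** — an
18-item instrument with which the analysis teams of a many-analysts
study rate, on a 4-point ordinal scale, the subjective evidence their
analysis provided for the hypothesis (8 items) and the methodological
appropriateness of the study (10 items), plus a prior-plausibility item
answered before seeing the data. The package is aimed at project
leaders of many-analysts studies who want to report what their teams
*believed*, alongside the usual spread of effect sizes.

## What it does

* **Instrument and responses** — the SEES ships as a machine-readable
  schema (`load_instrument()`); raw CSV exports are recoded into
  ordinal codes with reverse coding of the counter-indicative items
  SE_4–SE_7 and explicit handling of the "not applicable / I do not
  know" option (`recode_responses()`, `validate_responses()`).
* **Consensus model** — a hierarchical Bayesian cultural-consensus
  (latent truth rater) model for ordinal ratings. Item *i* has a
  latent consensus location *T<sub>i</sub>*; team *k* responds through
  ordered category thresholds *γ<sub>c</sub>* shifted by its scepticism
  *β<sub>k</sub>*, with item-specific dispersion *λ<sub>i</sub>*:

  P(X<sub>ki</sub> = c) = Φ((γ<sub>c</sub> + β<sub>k</sub> − T<sub>i</sub>)/λ<sub>i</sub>) − Φ((γ<sub>c−1</sub> + β<sub>k</sub> − T<sub>i</sub>)/λ<sub>i</sub>)

  with *T<sub>i</sub>* ~ N(μ<sub>s</sub>, σ<sub>s</sub>²) pooled per
  subscale. Fitting (`fit_consensus()`) uses an adaptive
  Metropolis-within-Gibbs sampler with extra moves along the model's
  invariance ridges; summaries (`summarize_consensus()`,
  `plot_consensus()`) report posterior medians, 95% credible intervals,
  thresholds, per-team scepticism and per-item consensus labels.
* **Synthetic data & recovery** — `simulate_responses()` and
  `recovery_experiment()` generate tables from the generative model and
  quantify how well consensus is recovered at a given panel size.
* **Belief updating** — `summarize_beliefs()`, `agreement_rate()`,
  `classify_change()`, `group_descriptives()` for the prior-vs-final
  plausibility comparisons.
* **Bayesian correlations** — `pearson_bf()` (exact likelihood,
  quadrature) and rank-based `spearman_bf()` (latent-normal Gibbs) with
  directional Bayes factors BF₊₀ / BF₀₊ under a stretched-beta prior.
* **Delphi screening** — `delphi_screen()` applies the expert-panel
  inclusion rule (median ≥ 6 and IQR ≤ 2, with an advisory
  high-support flag) used during instrument development.

## Worked example

Simulate a 42-team panel from the generative model and fit the
consensus model to its subjective-evidence subscale:

```r
library(sees)

cfg   <- simulation_config(K = 42, items = 8, seed = 2026)
tab   <- simulate_responses(draw_truth(cfg), cfg)
fit   <- fit_consensus(tab, sees:::.synthetic_instrument(8),
                       "subjective_evidence", model_config(seed = 1))
summarize_consensus(fit, sees:::.synthetic_instrument(8))
```

```
<sees_summary> subscale 'subjective_evidence'
  overall consensus -0.87 [-1.23, -0.58], item-SD 1.11
  thresholds: -1.50, 0.05, 1.45
 item_id median  lower  upper consensus_label
  item_1  0.721  0.276  1.314           cat_3
  item_2 -1.392 -2.161 -0.876           cat_2
  ...
  item_6 -2.865 -4.241 -1.885           cat_1
```

Consensus locations only mean something relative to the thresholds:
`item_1` sits between the second and third threshold, so its consensus
label is the third response category, while `item_6` falls below the
first threshold (lowest category). The overall marker −0.87
[−1.23, −0.58] is the posterior of the mean item location — the
panel's overall leaning on this subscale.

Belief updating and the Delphi rule work on plain data frames:

```r
beliefs <- data.frame(team_id = 1:6,
                      prior = c(2, 3, 3, 4, 2, 3),
                      final = c(3, 3, 4, 4, 2, 4))
summarize_beliefs(beliefs)
#> <sees_beliefs> 6 complete pairs
#>   mean plausibility 2.83 -> 3.33; agreement 66.67% -> 83.33%
#>   increased 50%, decreased 0%, unchanged 50%

delphi_screen(matrix(c(2L,3L,4L,8L,8L,8L,9L,9L,9L,9L), ncol = 1,
                     dimnames = list(NULL, "SE_8")))
#>   item_id median iqr pct_high          decision
#> 1    SE_8      8   4       70 high_support_flag
```

A thin command-line front end with `fit`, `simulate`, `recover`,
`beliefs`, `corr`, `delphi` and `report` subcommands lives at
`inst/cli/sees.R`:

```sh
Rscript inst/cli/sees.R fit --responses responses.csv --out results/
```

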