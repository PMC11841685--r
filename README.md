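# icusurv

Survival analysis of in-ICU mortality from multimodal patient data:
structured SAPS-II severity factors, radiology-report features (finding
labels, transformer-pooled token embeddings, a graph-convolutional
encoding over a finding concept graph) and chest X-ray image features,
combined by early average fusion inside a DeepSurv-style neural Cox
model.

## Who this is for

Biostatisticians and ML researchers studying whether unstructured
text/image information improves ICU mortality prediction over structured
severity scores, and who need a fully testable, seeded pipeline that runs
without access to credential-restricted clinical databases.

## The model

The Cox proportional-hazards form

    S_i(t | x_i) = S0(t)^exp(psi(x_i))

is shared by everything in the package: `S0` is the Breslow baseline
survival, `psi` the log relative hazard. Two risk functions are
implemented:

* **Linear**: `psi(x) = x beta`, fitted by Newton–Raphson maximization of
  the Breslow/Efron partial likelihood with Wald hazard-ratio inference
  (`fit_linear_cox()`).
* **Neural (DeepSurv-style)**: per-modality MLP heads (SAPS 15→15, labels
  14→14, text 768→32, image 1024→32), elementwise averaging of the
  text/image hidden features, concatenation with the SAPS block, and a
  dropout-regularized risk head, trained by minimizing the batchwise
  negative Cox partial likelihood with Adam (`train_risk_model()`).

Evaluation follows the bootstrap protocol: resample the cohort with
replacement, split 70/10/20, train with early stopping, score the
held-out concordance index (C-index); 200 replicates give the mean and
percentile 95% CI, and models sharing a master seed are compared by a
paired Wilcoxon signed-rank test.

A seeded synthetic cohort generator (including a SAPS-II scorer with the
standard 0–163 point table) emulates the statistical structure of the
study data — correlated radiograph findings, embeddings carrying planted
label signal, Weibull event times with ~22% in-ICU mortality and
calibrated administrative censoring — so every stage is testable at desk
scale.

## Worked example

```r
library(icusurv)

co <- generate_cohort(cohort_config(n_subjects = 800, seed = 1))
deep <- function(mods) list(
  name = paste(mods, collapse = "+"), type = "deepsurv",
  config = fusion_config(mods, max_epochs = 15, patience = 5,
                         learning_rate = 0.002))

r_saps  <- bootstrap_experiment(co, deep("saps"), n_replicates = 20, seed = 1)
r_multi <- bootstrap_experiment(co, deep(c("saps", "text", "image")),
                                n_replicates = 20, seed = 1)
r_saps
#> saps: mean C-index 0.6395 (95% CI 0.5683-0.7295, 20 replicates)
r_multi
#> saps+text+image: mean C-index 0.7766 (95% CI 0.6285-0.8875, 20 replicates)

cmp <- compare_models(r_saps, r_multi)
cat(sprintf("mean diff %.4f, p %.3g, %s\n",
            cmp$mean_difference, cmp$p_value, cmp$direction))
#> mean diff 0.1371, p 0.000151, saps+text+image > saps
```

The saps-only model sees only structured severity factors; the multimodal
model additionally receives text and image embeddings that carry the
cohort's planted finding signal through independent noise, so its mean
test C-index is substantially higher — the synthetic analogue of the
multimodal advantage, significant under the paired signed-rank test.

A configuration-driven grid (several feature settings, CoxPH
counterparts, subgroup breakdowns by radiographic finding, and the
multivariate hazard-ratio table over the 13 findings) runs via
`run_experiment(demo_experiment_config())`, writing `results.csv`,
`comparisons.csv`, `subgroups.csv`, `hr_table.csv` and a provenance
block. A thin command-line front end is in `inst/cli/icusurv.R`.

## Package layout

* `R/` — SAPS-II scorer, synthetic cohort generator, Cox machinery,
  feature encoders (pooling, concept-graph GCN), fusion network,
  evaluation, experiment orchestration.
* `inst/extdata/` — the versioned SAPS-II point table, the default
  finding concept graph, the demo experiment profile.
* `vignettes/multimodal-icu-survival.Rmd` — the methods vignette: model,
  assumptions, generator design, numerical choices, limitations.
* `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (exhaustive pair enumeration, finite differences,
  grid search, hand-expanded likelihoods, the `survival` package).
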