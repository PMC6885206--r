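# clustsig

Discovery and cross-cohort transfer of small gene-expression signatures
that isolate a minority cluster of patients with divergent overall
survival — the situation met in chronic lymphocytic leukemia (CLL),
where a group of roughly 5% of patients follows a much more aggressive
course than cohort-level markers suggest.

## What it computes

The pipeline combines four pieces of machinery:

1. **Per-gene clusterization.** For each gene *g*, a two-component
   univariate Gaussian mixture is fitted by EM under the equal-variance
   (E) and varying-variance (V) parameterizations and the better model
   is chosen by BIC = 2ℓ − m·log n (larger is better). Samples get hard
   cluster labels.
2. **Survival screen.** Each gene's binary label enters a Cox
   proportional-hazards model of overall survival; the label is coded
   1 for the cluster with the higher observed death hazard.
   Likelihood-ratio p-values (whose null tail stays calibrated for
   small clusters) are Benjamini–Hochberg adjusted across all tested
   genes and genes with *q* < 0.05 are selected.
3. **Multivariate signature.** A K = 2 mixture is fitted on the
   selected genes jointly, with BIC selection over the
   spherical/diagonal covariance families Σ_k = λ_k·A_k ∈
   {EII, VII, EEI, VEI, EVI, VVI} (det A_k = 1). The component with the
   higher observed hazard is the adverse cluster. The fitted object is
   frozen.
4. **Transfer.** A validation cohort measured on another platform is
   placed in the training space by parametric empirical-Bayes batch
   adjustment (ComBat-style location/scale shrinkage), then scored with
   the frozen mixture: each sample gets a posterior probability of
   belonging to the adverse cluster, a hard call at 0.5, and a
   borderline flag for posteriors in [0.4, 0.6].

A synthetic-cohort generator with planted ground truth (minority
fraction, signature shift, true hazard ratio, batch effects) backs the
whole test suite, so every stage is validated against known answers.

## Worked example

```r
library(clustsig)

## paired synthetic cohorts: 450-sample training, 107-sample validation,
## 2000 genes, 3 signature genes shifted 2.5 log2 units in ~4.5% of
## patients, true HR 4.86, platform batch effects on validation
pair <- generate_paired_cohorts(
  synthetic_config(seed = 71001),
  synthetic_config(n_samples = 107, seed = 71002))

screen <- screen_genes(pair$train$expression, pair$train$survival)
#> 31 gene(s) skipped (small_cluster=31)
print(screen)
#> Gene screen: 2000 genes, 1969 tested, 3 selected at q < 0.05
#> Selected genes:
#>      gene family  n1  n2   hr        p       q
#>  gene0001      E 435  15 5.65 2.15e-06 0.00141
#>  gene0002      E  15 435 5.64 9.36e-07 0.00122
#>  gene0003      E 434  16 5.51 1.24e-06 0.00122

sig <- fit_signature(pair$train$expression, pair$train$survival,
                     genes = selected_genes(screen))
print(sig)
#> Expression signature model
#>   genes: gene0001, gene0002, gene0003
#>   mixture: K = 2, family EII (BIC -2093.75)
#>   adverse cluster: component 2, 16/450 samples (3.56%)
#>   training survival: HR 5.51 (95% CI 3.14-9.67), p = 2.74e-09

## place the validation cohort in the training space, then apply the
## frozen model
joint <- cbind(pair$train$expression, pair$valid$expression)
batch <- rep(c("train", "valid"), c(450, 107))
adj <- combat_adjust(joint, batch)
calls <- apply_signature(sig, adj$adjusted[, batch == "valid"])
mean(calls$adverse)
#> [1] 0.02803738
```

The screen recovers exactly the three planted genes; the multivariate
mixture isolates an adverse cluster of 3.6% of training patients with a
5.5-fold death hazard; and the frozen model, applied to the
batch-adjusted validation cohort, flags 2.8% of its samples — every one
of them a true member of the planted minority. `run_pipeline()`
wraps the same sequence (plus covariate-adjusted Cox models,
Kaplan–Meier tables and a reproducibility manifest) into one call.

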