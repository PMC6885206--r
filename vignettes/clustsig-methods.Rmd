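---
title: "Model-based discovery and transfer of minority survival signatures"
author: "clustsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based discovery and transfer of minority survival signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustsig)
```

## The problem

In heterogeneous malignancies such as chronic lymphocytic leukemia
(CLL), a small fraction of patients — a few percent — can follow a
sharply worse clinical course that is invisible to cohort-level
regression on individual markers. The package implements a pipeline
that hunts for such groups directly in the geometry of gene
expression: each gene is asked whether it splits the cohort into two
plausible Gaussian clusters; the genes whose splits align with
survival are combined into a small multivariate signature; and that
signature, frozen, is applied to an independent cohort measured on a
different platform.

The stages are:

1. **Per-gene clusterization** (`screen_genes()`): a two-component
   univariate Gaussian mixture per gene, equal-variance (E) and
   varying-variance (V) parameterizations fitted by EM and compared by
   BIC.
2. **Survival screening**: a Cox proportional-hazards model of overall
   survival on each gene's binary cluster label; Benjamini–Hochberg
   adjustment across all tested genes; selection at *q* < 0.05.
3. **Multivariate signature** (`fit_signature()`): a two-component
   mixture on the selected genes jointly, with BIC selection over the
   spherical/diagonal covariance families EII, VII, EEI, VEI, EVI,
   VVI; the component with the higher observed death hazard is the
   adverse cluster.
4. **Transfer** (`combat_adjust()`, `apply_signature()`): the
   validation cohort is batch-adjusted into a common expression space
   by parametric empirical Bayes, then scored with the frozen training
   parameters — posterior cluster membership only, never a refit.

## The mixture model

Each covariance is decomposed as $\Sigma_k = \lambda_k A_k$, with
volume $\lambda_k > 0$ and a diagonal shape matrix $A_k$,
$\det A_k = 1$. The family code fixes which pieces are shared: VEI,
for instance, is $\Sigma_k = \lambda_k A$ — per-component volume,
common shape, axis-aligned. Rotated (ellipsoidal) families are
deliberately out of scope: the screen is univariate and the signature
stage selects among diagonal geometries; the M-step dispatch is the
natural extension point if rotations are ever needed.

The free-parameter count for BIC is $(K-1) + Kd$ plus the
family-specific covariance count (e.g. $K + (d-1)$ for VEI). BIC is
used in the model-based-clustering convention
$\mathrm{BIC} = 2\ell - m\log n$ — **larger is better**. This is the
opposite sign of `stats::BIC()`; `bic()` documents it prominently
because silently mixing the two conventions is a classic error.

### Numerical choices

* **Initialization** is deterministic: a hard partition from Ward
  agglomerative clustering, shared across all candidate families so
  the BIC comparison is start-for-start fair. Seeded k-means restarts
  are available (`nstart`); for univariate fits the restart pool uses
  the contiguous splits of the sorted sample, which are both
  deterministic and far more diverse than repeated k-means. For very
  small univariate samples (n ≤ 10) every bipartition is tried, making
  the returned fit the constrained global maximizer.
* **Convergence**: relative log-likelihood change below `tol`
  (default 1e-8, `max_iter` 500). The screen uses `tol = 1e-5` — the
  default tolerance of the reference model-based-clustering
  implementation — because hard labels stabilize orders of magnitude
  before the tighter tolerance pays for itself; the definitive
  signature fit keeps 1e-8.
* **Variance floor**: component variances are kept at or above
  $10^{-8}\times$ the data variance by clamping the volume parameter —
  a constrained M-step, so EM monotonicity and the family structure
  survive. A fit whose final M-step needed the clamp is flagged
  `degenerate`; `select_model()` never lets a clamped fit (whose
  likelihood is floor-inflated) beat an honest one. Clamped fits are
  still returned when nothing better exists, which is exactly right
  for data with genuinely tied groups.
* **VEI M-step** has no joint closed form; volume and shape are
  alternated to relative change < 1e-8 (at most 100 inner iterations),
  warm-started from the previous EM iteration so the generalized EM
  ascent property holds.

## Survival machinery

Cox models are maximized by Newton–Raphson on the partial likelihood
via the survival package's fitter, with Efron tie handling by default
(Breslow available; they coincide without ties). Inference is Wald:
$\mathrm{HR} = e^{\hat\beta}$ with 95% limits
$e^{\hat\beta \pm 1.959964\,\mathrm{se}}$, matching the HR/CI/p
reporting style of prognostic studies. Monotone likelihoods (all
events on one side) are flagged rather than silently reported.
Kaplan–Meier curves use the product-limit estimator.

The adverse cluster is always coded 1 in the Cox design, so reported
hazard ratios are above 1 by construction; a study that coded the
reverse would report the reciprocal (an HR of 4.9 for adverse = 1 is
the same fit as 0.21 for adverse = 0), and `adjusted_cox()` keeps this
coding for the covariate-adjusted model too.

The two cohorts of a transfer study often define overall survival from
different origins (diagnosis versus assay date). The package treats
the time origin and unit as metadata owned by the caller
(`read_survival(time_unit=)`): it cannot reconcile the two clocks and
does not try; the transferred quantity is the cluster assignment, and
the validation Cox model is interpreted on the validation cohort's own
clock.

## Batch adjustment

`combat_adjust()` implements the parametric empirical-Bayes
location/scale adjustment: genes are standardized by pooled mean and
variance, per-batch per-gene location ($\hat\gamma_{gb}$) and scale
($\hat\delta^2_{gb}$) estimates are shrunk toward moment-matched
normal and inverse-gamma priors through the coupled posterior fixed
point (to relative change < 1e-6, at most 200 iterations), and the
adjusted values are returned to the pooled scale. The implementation
agrees with the Bioconductor reference to ~1e-8 on shared inputs and
additionally exposes every estimate and hyperparameter, which the
reference keeps internal.

Two modes matter for transfer. The default **joint** mode pools both
cohorts for standardization, which is the common published usage. The
**reference** mode (`ref_batch=`) standardizes against one batch and
leaves it untouched — arguably the right choice when a frozen model
was trained on that batch, and the mode in which planted batch
hyperparameters are actually identified (pooled standardization mixes
the perturbed batch into the scale, biasing recovered prior
parameters; the package's tests therefore assess hyperparameter
recovery in reference mode). With the study's cohort imbalance
(450 vs 107) the joint-mode shift of the training space is small
relative to the signature separation, and either mode transfers the
signature; the run log records whichever was used.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions so that every stage
can be validated against known truth: a 450-sample training cohort and
107-sample validation cohort of 2000 genes; a minority cluster drawn
Bernoulli(0.045) per sample; three signature genes whose minority mean
is shifted by 2.5 log2 units; and survival with hazard
$h_0\exp(\beta\,\mathbb{1}[\text{minority}])$, $e^\beta = 4.86$.

Defaults a scientist should know about, with the reasoning:

* **noise_sd = 0.5** (log2): gene-wise residual SD of RMA-normalized
  arrays is typically 0.3–0.6; 0.5 makes a 2.5 log2-unit shift a
  clearly bimodal, signature-quality gene — five within-cluster SDs —
  matching the visually separated clusters such screens select in
  practice. Larger noise produces smeared splits that absorb tail
  samples of the majority and attenuate the hazard contrast; such
  genes would not survive a real screen either.
* **baseline_hazard = 0.08/yr**: an exponential overall-survival model
  with median about 8–9 years, a realistic CLL figure for the
  chemoimmunotherapy era.
* **censor_rate = 0.04/yr**: independent exponential censoring giving
  roughly 30% censored observations at these hazards.
* **Survival is exponential** (constant hazard), the simplest model
  consistent with a proportional-hazards truth; a Weibull `shape`
  switch exists for sensitivity work.
* **Batch effects** on the paired validation cohort: additive
  $\gamma_g \sim N(0, 0.5^2)$ and multiplicative
  $\delta_g^2 \sim \mathrm{IG}(3, 2)$ (mean 1), the standard
  location/scale model of cross-platform differences.
* Randomness is consumed in fixed per-block order (labels, baselines,
  expression, covariates, survival, batch) with sub-seeds derived from
  the single config seed, so any cohort is bit-reproducible from its
  configuration.

What the generator does **not** emulate: probe-level intensities and
RMA itself, correlated gene modules, heavy-tailed or bimodal null
genes, informative censoring, and cohort differences beyond gene-wise
location/scale. Passing tests therefore demonstrate correctness of the
machinery under the stated generative model, not performance on any
particular real dataset.

## Screening design choices

* The per-gene Cox covariate uses **hard labels** (the study's
  "single-gene clusters"), not posteriors; posteriors are available
  from the fit for anyone wanting a soft variant.
* The adverse group per gene is the cluster with the higher observed
  event hazard (events per person-time), which makes per-gene HRs
  comparable; expression means break exact ties.
* Genes are **skipped** — excluded from the BH family, with the reason
  recorded — when variance is zero, the smaller cluster has fewer than
  `min_cluster = 3` samples (a Cox fit on 1–2 subjects is noise), or
  the mixture fit fails outright. Skipping, not imputing, keeps the
  q-value family honest.
* BH runs once across all tested genes; there is no per-chromosome or
  per-batch stratification.
* The per-gene test statistic is the **likelihood-ratio** test of the
  cluster term, not the Wald test, although hazard ratios and
  confidence intervals are still reported Wald-style. The reason is
  calibration where it matters: BH operates on the extreme tail of the
  null p-values, and for a rare binary covariate (minor cluster of
  10–20 samples out of 450) the Wald tail is several-fold
  anti-conservative at $p \sim 10^{-4}$ while the LRT stays nominal —
  enough to flood a 2000-gene screen with spurious selections.
* One caveat the package cannot remove: every gene is tested against
  the *same* survival realization, so the per-gene p-values are
  dependent across genes. Under a complete null the family-wise
  rejection rate of the screen can exceed the independence
  approximation $1-e^{-q}$ in cohorts whose survival draw happens to
  be "lucky" for many splits at once. This is a property of any
  shared-outcome screen, including the original design.

## Signature and transfer choices

* The adverse component of the multivariate signature is identified by
  observed hazard, not by size; in these data the adverse component
  happens to be the minority (~4–6%), and its size is logged for
  comparison.
* Hard calls use posterior > 0.5, with a **borderline flag** for
  posteriors in [0.4, 0.6] — cases near the cluster boundary (like a
  52.8% posterior) deserve individual review, and the sensitivity
  helper `sensitivity_drop()` quantifies how much any single case
  moves the fit.
* Transfer order is fixed: collapse probes → intersect genes by symbol
  (unresolvable symbols abort; no fuzzy matching) → batch adjust →
  predict with frozen parameters.
* `write_signature()`/`read_signature()` serialize the model as JSON
  at full double precision; a round trip reproduces posteriors to
  machine precision, which the tests assert at 1e-12.

## Problem sizes used by the test suite

The suite exercises the pipeline at the study scale it emulates:
25 replicate screens of 2000 genes × 450 samples for signature
recovery plus 20 all-null screens; 50 draws of n = 2000, d = 3 for
family selection under a VEI truth; 200 replicates for Cox
calibration; 500 replicates of m = 1000 for FDR control; and one full
450/107 discovery-and-transfer run with batch effects. These sizes
keep the whole suite in the tens of minutes on a single core while
leaving each rate estimate stable enough to compare against its
expected value.

## Known limitations

* K is fixed at 2 throughout; the search over K that general
  model-based clustering performs is out of scope.
* Only spherical/diagonal covariance families are implemented.
* No time-varying covariates, stratified Cox, or proportional-hazards
  diagnostics; the Cox layer is intentionally the standard fitter
  behind a stable interface.
* The nonparametric ComBat variant and covariate-aware standardization
  are not implemented (the transfer use case adjusts platform only).
* Gene intersection across platforms is by exact symbol; probe-level
  reconciliation belongs upstream.
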