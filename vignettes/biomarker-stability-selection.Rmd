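---
title: "Stability selection and permutation-calibrated evaluation of MODS biomarker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability selection and permutation-calibrated evaluation of MODS biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modspanel)
```

## The problem

Multi-organ dysfunction syndrome (MODS) develops in roughly 30–40% of
severely injured trauma patients, typically 48 hours or more after
admission. Immunological readouts taken in the first hours to days after
injury — neutrophil and monocyte surface markers, stimulation responses,
cell frequencies — are candidate early predictors, but a typical discovery
cohort is small (tens of patients) while the feature table is wide (a few
hundred measurements across several sampling time points). Ordinary
regression overfits such tables badly, and a single penalized fit is
unstable: which features it keeps can change completely under a slightly
different patient sample.

`modspanel` implements a pipeline built for exactly this regime:

1. **Preprocessing** — keep only patients followed at every time point,
   drop features with more than 70% missing values, impute remaining gaps
   with the per-feature minimum, autoscale, and optionally integrate the
   time-point tables into one wide matrix.
2. **Stability selection** — repeat a cross-validated LASSO and Elastic-Net
   logistic fit over many random 75/25 patient subsamples and keep the
   features that are selected unusually often.
3. **Permutation-calibrated evaluation** — score the nominated panel by the
   distribution of test-set AUCs of an unpenalized logistic model over many
   random 65/35 splits, against the same distribution under permuted
   outcome labels.

A seeded synthetic-cohort generator with planted effects stands in for
clinical data, so every stage is testable with known ground truth.

## The selection model

For outcome $y_i \in \{0,1\}$ and standardized features $x_i \in
\mathbb{R}^p$, the penalized logistic fit solves

$$
\min_{\beta_0,\,\beta}\; -\frac{1}{n}\sum_i \ell(y_i, \beta_0 + x_i^\top\beta)
\;+\; \lambda\left(\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\right),
$$

with $\ell$ the Bernoulli log-likelihood. The mixing parameter $\alpha$
blends the penalties: $\alpha = 1$ is the LASSO, $\alpha = 0.5$ the
Elastic Net; both are run side by side by default. (Elastic-Net notation
varies across the literature in which factor multiplies which norm; this
package fixes the convention above — $\alpha$ on the L1 term — so that
$\alpha = 1$ is exactly the LASSO, and all documentation and code use it
consistently.) The penalty strength $\lambda$ is tuned on each training
draw by 10-fold cross-validation over a descending grid of 100 log-spaced
values from $\lambda_{\max}$ (the smallest penalty that zeroes every
coefficient, computed from the KKT condition) down to
$\lambda_{\max}/1000$. Held-out binomial deviance is the default tuning
loss (`measure = "auc"` is available); the two are asymptotically aligned
here and deviance is smoother at small n.

Stability selection then repeats, `n_iterations = 100` times: draw a
random stratified 75% training sample, tune $\lambda$, fit, and record
which coefficients are nonzero. A feature's **appearance frequency** is
the number of iterations in which it was kept. The selection threshold is
the empirical upper quartile (type-7 quantile, R's default interpolation)
of the full frequency vector, zeros included; features **strictly above**
it are selected. For the integrated all-time-points analysis the
`stringent` preset raises the quantile to 0.90, since quadrupling the
feature pool at fixed n raises the background selection rate. The LASSO
and Elastic-Net selections are combined by union by default (intersection
by flag), with per-method provenance retained.

Two open design points are fixed as follows. The penalty is re-tuned
inside every subsampling iteration — tuning is part of the procedure whose
stability is being measured, so it must see only that iteration's training
data. And the Elastic-Net $\alpha$ is fixed at 0.5 rather than tuned,
keeping the two methods interpretable as fixed, distinct selectors.

## Evaluation against a permutation null

The selected panel (optionally augmented with a clinical score such as
NISS or PS14) is refit as an ordinary, unpenalized logistic model over
`n_resamples = 1000` random stratified 65/35 train/test splits; each test
set contributes one ROC AUC, computed by the Mann–Whitney midrank
formula (ties get half credit, and the statistic is invariant under any
strictly increasing transform of the scores). The same procedure is run
`n_permutation_resamples = 1000` more times with the outcome labels freshly
permuted before every resample. The empirical p-value is the fraction of
permuted AUCs exceeding the mean real AUC; the bias-corrected variant
$(k+1)/(n+1)$ is reported alongside. The confidence interval on the real
AUC is its empirical 2.5/97.5 percentile range — purely descriptive of the
resampling distribution.

Two caveats are documented rather than hidden:

* **Selection optimism.** Features are selected once, on the full table,
  and then held fixed during evaluation resampling. The evaluation
  therefore measures the panel's stability, not an unbiased generalization
  estimate; a fully nested re-selection per resample would be needed for
  the latter and is out of the default path.
* **Conservative p-values.** Each permuted AUC carries both
  permutation-level noise (the spurious association a random labeling
  induces at n = 61) and split-level noise, whereas the real mean has the
  split noise averaged away. Under a true null the real mean therefore
  exceeds the permuted 95th percentile in well under 5% of cohorts — in
  simulations at the package's study conditions, in fewer than 1% — so a
  small p-value is trustworthy, but the test's effective level is below
  its nominal one.

Perfect separation of a small panel at n = 61 is common; the evaluator
then falls back to a ridge-stabilized fit (tiny L2 penalty), which leaves
the score ordering — the only thing the AUC uses — well defined. Fallbacks
are counted in the result and the run manifest.

## The synthetic cohort generator

`study_spec()` encodes the study conditions the pipeline is designed for:
61 patients, MODS prevalence 0.35, three time points with 68/68/67
features. Features are group-conditional Gaussians: a planted marker with
effect size $d$ (standardized mean difference) is $N(d\,y_i, 1)$, noise
features are independent of outcome with within-block correlation 0.5 in
blocks of 5 (one shared latent factor per block), and clinical scores are
generated once per patient and replicated at every time point. Defaults:
three planted markers at $d = 1.5$ (one at the first time point, two at
the third, echoing the monocyte/CD62L/CD63 panel structure), and three
clinical scores — NISS at $d = 0.8$, PS14 at $d = 1.1$, ISS at $d = 0.7$ —
chosen through the binormal identity $\mathrm{AUC} = \Phi(d/\sqrt{2})$ to
give univariate AUCs near 0.71, 0.78 and 0.69, the plausible range for
anatomical severity scores. Missingness is MCAR at 5% per immune feature,
with three noise features raised to 80% so the >70% filter is exercised;
clinical scores stay complete (their per-time-point copies must remain
identical for the integration collapse).

Integration of 68+68+67 = 203 columns with three clinical scores repeated
at each time point collapses the six redundant copies, giving the 61 × 197
wide matrix; the collapse keys on exact name-and-value equality and is
recorded in the result.

What the generator does **not** emulate: longitudinal within-patient
kinetics (time points are independent blocks), heavy-tailed or skewed
assay distributions, informative (outcome-dependent) missingness — an MNAR
switch exists but is off by default — and correlation between clinical
scores and immune features. Passing tests on these cohorts therefore
demonstrate that the machinery recovers planted structure under the
assumed model, not that any particular clinical dataset will behave the
same way.

## Numerical and degenerate-input choices

* The missingness filter is strict (`> 0.70`): a feature missing exactly
  70% of entries is retained.
* Autoscaling uses the sample standard deviation (denominator $n-1$);
  zero-variance features are an error naming the feature, never a silent
  drop.
* Imputation and scaling are computed once on the full table before
  resampling, replicating the original design; because that leaks test
  information into the training folds, `fold_preprocess = TRUE` recomputes
  both inside every training draw. The default reproduces the published
  procedure; the flag quantifies the leakage when wanted.
* Splits and folds are stratified by outcome by default — at n = 61 and
  prevalence 0.35, unstratified 10-fold CV frequently produces single-class
  folds. `stratified = FALSE` mimics fully random splitting.
* Every stage derives its own RNG seed from the master seed and a stage
  tag, so reruns are byte-identical and stages can be re-run in isolation.
  Failed iterations (e.g. a single-class draw in unstratified mode) are
  redrawn with a fresh derived seed, counted, and capped at five times the
  iteration budget.

## Scale of the shipped checks

The package's own test suite exercises the pipeline at deliberately modest
sizes — 200 no-signal cohorts at 200+200 resamples for null calibration,
50 planted cohorts at 50 selection iterations for marker recovery, and one
full run at the original settings (100 iterations, 1000+1000 resamples) —
sizes chosen so the whole suite completes on a laptop-class single core
while keeping the binomial error bands on the checked proportions tight
enough to be meaningful.

## Limitations

Beyond the evaluation caveats above: minimum-value imputation is crude
(model-based imputation is deliberately out of scope); the upper-quantile
threshold adapts to the frequency distribution rather than controlling any
formal error rate (no per-family error guarantee as in complementary-pairs
stability selection); and the pipeline's headline outputs are
resampling distributions, not parameter estimates with analytic standard
errors.
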