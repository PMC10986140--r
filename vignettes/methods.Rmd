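---
title: "Methods: compositional discriminant analysis and Bayesian differential abundance for 16S count tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional discriminant analysis and Bayesian differential abundance for 16S count tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micropls)
```

# Scope and model

`micropls` implements a downstream analysis workflow for two-group
comparisons of 16S amplicon count tables (ASV- or genus-level), of the kind
used to ask whether the gut microbiota composition discriminates two animal
lines or longevity groups. The pipeline has three branches that share a
validated count table:

1. **Diversity.** Samples are rarefied to an even depth; observed richness,
   Shannon diversity (base-2 logs) and Pielou's evenness are tested between
   groups with Kruskal–Wallis; Bray–Curtis and Jaccard distances are tested
   with PERMANOVA, and PERMDISP guards against dispersion artifacts — a
   significant PERMDISP invalidates the corresponding PERMANOVA verdict,
   which the report marks "discarded".
2. **Discriminant.** Features present in at least 50% of the samples of
   *each* group are kept, outlier samples are screened on the first two
   principal components of the relative-abundance matrix, a pseudocount of 1
   removes zeros, and the table is mapped to additive log-ratios,
   `ALR(j | ref) = log x_j − log x_ref`, against the feature with the lowest
   coefficient of variation. A PLS-DA model (NIPALS, auto-scaled predictors,
   Mahalanobis centroid classification) is pruned by iterative VIP > 1
   selection under balanced-error-rate (BER) cross-validation, and its final
   performance is assessed with a repeated-CV confusion matrix and a
   label-permutation test.
3. **Differential abundance.** Each selected ALR variable is fitted with a
   Bayesian linear model `y = μ + β·group + e` (flat priors, Gibbs
   sampling); the posterior of β, in units of the variable's SD, yields the
   sign probability P0, the posterior error probability
   `PEP = (1 − P0)/0.5`, a 95% HPD interval, and a cumulative-PEP relevance
   call with a 0.5-SD effect-size reporting floor.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_prev` | 0.5 | per-group prevalence a feature needs to survive filtering (inclusive) |
| `pseudocount` | 1 | offset added to every cell before log-ratios |
| `k_sd` | 3 | PCA screen: removal threshold in SDs of the PC1–PC2 centroid distance |
| `max_ncomp` | 10 | largest PLS component count considered |
| `folds`, `cv_repeats` | 4, 100 | stratified CV layout for component selection |
| `final_repeats`, `n_permutations` | 10 000 | repeats for the final confusion matrix and permutation test |
| Gibbs `iterations`/`lag`/`burn_in`/`chains` | 50 000 / 10 / 1 000 / 4 | MCMC schedule; retained draws = chains × ⌊(iterations − burn-in)/lag⌋ |
| `pep_threshold` | 0.05 | cumulative-PEP cut-off for relevance |
| `effect_floor` | 0.5 | |meanDiff| (SD units) a relevant variable needs for the `sizeable` flag |

Shannon entropy uses base-2 logarithms (bits) to match the convention of the
standard diversity toolkits; the base is an argument. The ALR uses natural
logs — any base change rescales all log-ratios by a constant, and every
downstream quantity (PLS-DA predictions, effect sizes in SD units) is
invariant to that rescaling.

# Design choices where the method description was open

* **Prevalence threshold is inclusive**: a feature present in exactly half
  the samples of each group is kept ("at least 50%"). The comparison is made
  with a small absolute guard so binary representation of fractions cannot
  flip the boundary.
* **CV for reference selection uses proportions, not raw counts.** Raw-count
  CV is dominated by library size, which the ratio analysis removes by
  design; a flag restores raw-count CV for sensitivity analysis.
* **Procrustes check.** The quality of an ALR transformation is judged
  against the centered log-ratio (CLR) configuration of the same samples —
  the reference log-ratio geometry — via orthogonal Procrustes with
  translation and uniform scaling; correlation = √(1 − m²).
* **Component choice** uses a one-SD parsimony rule: the smallest component
  count whose mean CV BER is within one SD of the global minimum.
* **Mahalanobis metric** comes from the pooled within-class covariance of
  the training scores, ridge-regularised by 10⁻⁸ × trace when
  near-singular (late NIPALS components of nearly separable data carry
  almost no variance).
* **Iterative VIP stopping.** The loop accepts a shrinkage step if its mean
  BER did not rise by more than one SD of the previous accepted BER, and
  *continues only while the BER strictly improves*. Without the plateau
  stop, VIP > 1 keeps halving an equally informative variable set forever
  (VIP is normalised so mean VIP² = 1: about half of a homogeneous set
  always exceeds 1 by noise), discarding real signal while the BER sits
  flat. The plateau stop is the operational reading of iterating "until the
  model reaches its highest classification performance".
* **Gibbs σ² conditional.** "Flat priors" on a variance is ambiguous. A
  uniform prior on σ² gives the conditional IG(n/2 − 1, SSE/2) but a
  marginal for β with n − 4 effective df; the Jeffreys reference prior 1/σ²
  gives IG(n/2, SSE/2) and a marginal that is *exactly* Student-t with
  n − 2 df, which is also the analytic oracle the test-suite checks P0
  against. The package uses the Jeffreys form.
* **P0 side convention.** P0 is the posterior mass on the side of zero given
  by the sign of the posterior mean; in the measure-zero event that mean and
  median straddle zero, the larger side is reported so P0 ∈ [0.5, 1] holds
  by construction.
* **meanDiff scaling** divides by the all-samples SD of the ALR variable
  (config-exposed); the within-group alternative differs only under strong
  effects.
* **Sign convention**: β (and meanDiff) is the mean of the second group
  level minus the first (factor level order).
* **Bayes stage scope**: by default only PLS-DA-selected variables are
  modelled, mirroring the reference workflow; `bayes_all_variables = TRUE`
  analyses every ALR variable.

# The synthetic data generator

`generate_dataset()` draws a logistic-normal/multinomial table shaped like
the study the pipeline targets: two groups (default 31 + 40 samples),
thousands of sparse ASVs collapsible to ~139 genera, per-sample depths in
10 863–62 439 reads with mean ≈ 29 490 (a scaled Beta), and a dominant
phylum calibrated to an 87% expected share. Differential features receive a
log-scale shift equal to `delta_sd` times the predicted ALR SD
(latent noise plus the `E[1/count]` contribution of the multinomial), so
designed effects are expressed in the units the analysis measures; the
helper `realized_effect()` verifies the calibration. Three deliberate
idealisations:

* Zero inflation is applied to the latent composition *before* the
  multinomial draw (so sampled depths are exact) and only to background
  features: sparsifying a differential feature would destroy the designed
  effect size that the recovery tests rely on.
* Effects are injected into features with a median expected count of at
  least ~50; an effect planted in a never-observed taxon is untestable.
* Feature 1 is a designed low-variance, effect-free, abundant feature, so
  the lowest-CV reference rule lands on a stable reference.

A green recovery test therefore establishes that the pipeline finds
*detectable, well-calibrated* effects; it does not establish performance on
taxa near the detection limit, under taxonomic misassignment, or under
confounded designs — none of which the generator emulates.

# Known limitations

* **Cumulative PEP does not control the frequentist FDR against exact
  nulls.** PEP = (1 − P0)/0.5 is a posterior *sign-error* probability. For
  a feature with a truly zero effect, P0 is uniform on (0.5, 1) over
  repeated sampling, so PEP is uniform on (0, 1), and the ascending
  cumulative mean stays below a threshold t for roughly the first 2t
  fraction of pure nulls. Consequently a null dataset yields ≈ 10% of its
  variables "relevant" at the 0.05 threshold, and in a mixed dataset the
  realised false-discovery proportion against known nulls is far above the
  nominal level (the acceptance suite measures ≈ 0.6 and reports the
  corresponding checks honestly red). The construction *does* control the
  Bayesian expected sign-error rate among the calls, and it behaves
  sensibly when applied — as the reference workflow does — to variables
  pre-selected for between-group signal, where exact nulls are rare. The
  0.5-SD `sizeable` floor further trims small-effect calls.
* **The permutation test is post-selection.** It evaluates the final model
  (variables already chosen on the same data), so its null distribution
  does not account for selection: on a pure-noise dataset the observed rate
  is optimistic and p-values can be small. Interpreting it as evidence
  about the *selected model*, not about the selection procedure, is the
  honest reading.
* Only two-level group factors are supported (no covariates, no multiclass
  PLS-DA); no UniFrac (no phylogeny in scope); BIOM binary input is not
  parsed.

# Numerical notes

NIPALS runs to a 10⁻¹⁰ relative score tolerance (≤ 500 inner iterations)
with X-deflation; score orthogonality is maintained to 10⁻⁸ and checked.
Component extraction stops early when the X residual is exhausted.
Rarefaction subsamples without replacement via index expansion
(`sample()` under a caller-supplied seed, making results bit-reproducible).
HPD intervals are the shortest window over sorted draws. R-hat is the
split-chain potential scale reduction with a 1.05 convergence cut-off; a
non-converged variable is re-run once with doubled iterations, then
flagged. Permutation p-values use the add-one estimator
(r + 1)/(n + 1). All pipeline stages derive their seeds deterministically
from the master seed, and reports embed the config hash, so identical
configurations reproduce byte-identical outputs.
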