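---
title: "Two-step multi-omics modelling of drug sensitivity"
author: "twoStepOmics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step multi-omics modelling of drug sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twoStepOmics)
```

## The modelling problem

Pharmacogenomic screens characterize panels of cancer cell lines with
several heterogeneous omics layers — somatic mutation calls, recurrent
copy-number aberrations, promoter hypermethylation events, tissue
lineage, basal gene expression and pathway activation scores — and
measure each line's sensitivity to a drug as the area under its
dose-response curve (AUC; lower AUC means more sensitive). Fitting one
classifier on the concatenation of all layers tends to let a single,
structurally favourable layer (typically expression) dominate, hiding
complementary signal in the sparser discrete layers.

`twoStepOmics` addresses this with late integration. In a **first
step**, one model is trained per data type, each adapted to that type's
structure. In a **second step**, the continuous output vectors of the
surviving first-step models — at most six numbers per cell line — are
the only inputs to a suite of thirteen classification algorithms.
Because every input arrives on the same `[0, 1]` scale, no layer can
dominate for structural reasons, and the weight each integration
algorithm assigns to each input is directly interpretable as the
contribution of that data type. Exhaustive ablation refits quantify
redundancy between layers, and cross-fold stability counts surface
candidate biomarkers.

## Response binarization and cross-validation

Cell lines are labelled responders when their AUC is at or below the
lower quartile of the training response and non-responders at or above
the upper quartile; quantiles use linear interpolation between order
statistics (R type 7) so that labelled counts are exactly reproducible.
Under the default `quartile_exclude_middle` policy, lines strictly
between the thresholds are excluded from training and scoring; an
alternative `quartile_full` policy dichotomizes the middle band at the
threshold midpoint instead, which is useful when every line must carry
a label (e.g. for cross-study comparisons). Both conventions are
implemented because screening literature is split on whether the
inter-quartile band should be modelled; exclusion is the default here
since the modelled-line counts it produces match the quartile
convention of comparable studies.

The 10-fold partition is stratified on the responder label with a
user-set seed. Stratification is a deliberate design choice — with
only a few dozen labelled lines per class, unstratified folds
occasionally lose a class entirely — and the assignment rule keeps
fold sizes within one cell line of each other. Inside the
cross-validation loop, the quartile thresholds are recomputed on the
response of every non-test cell line and applied to that fold's test
cells, so no test response ever influences a threshold. A test cell
whose AUC falls between the fold's thresholds still receives
predictions but is excluded from that fold's scoring; this is why a
model's effective fold count can drop below ten, a phenomenon the
ablation reporting handles explicitly.

## First-step models

**Discrete layers** (mutation, CNV, hypermethylation, tissue). Features
are first count-screened: a genomic feature must show at least 15
training instances of each of two states (for ternary CNV columns the
split is aberrant, i.e. any non-zero state, versus neutral), a tissue at
least 10 members. Each surviving feature is tested with a two-sided
two-sample *t*-test of the *continuous* pre-binarization AUC between
carriers and non-carriers, at significance level α = 0.05 with
Bonferroni correction by the number of features actually tested in that
fold. The pooled-variance Student form is the default (Welch is a
configuration switch); with zero variance in both groups the p-value is
defined as 1 for equal means and 0 otherwise. Features that are present
and absent in exactly the same training cells are redundant: only the
smallest-p representative (earlier column on ties) enters clustering,
though the full significant set is reported. Training cells are then
sorted into at most 2^n clusters by their presence/absence pattern over
the n retained features (n is capped at 10, keeping the smallest
p-values, so cluster counts stay below 1024); each non-empty cluster
predicts its mean *binarized* responsiveness, and a test cell receives
the prediction of the cluster matching its own pattern. Patterns unseen
in training fall back to the overall training responder fraction — the
same value the trivial single-cluster model predicts when no feature is
significant. The tissue model forms n + 1 clusters: the pooled
non-significant tissues first, then one cluster per significant tissue.

**Continuous layers.** For expression, a principal component analysis
(centered, unscaled — RMA expression already lives on a common log
scale) is fitted on the training cells only and the scores of the first
7 components (fewer if the rank is lower) are regressed on the 0/1
labels by least squares; 7 components is the package default, balancing
information against the stability of the downstream fit. The pathway
model regresses the labels on the 11 pathway activation scores
directly, retaining per-pathway coefficient p-values for reporting.
Raw outputs of both models are min-max normalized to `[0, 1]` with
training bounds (test values clipped), and an accuracy-optimal cutoff
binarizes them.

**Cutoff search.** Candidates are the midpoints between consecutive
sorted unique normalized training predictions, extended by 0 (predict
every line a responder) and a sentinel value of 2 (predict none), so
the chosen cutoff is never beaten by either constant classifier. Ties
select the smallest candidate so responders are not under-called. The
same search supplies the binarization cutoff of the discrete models'
fraction-valued outputs.

Any first-step model whose training output is constant — it found no
statistically significant structure — is flagged and removed before
integration.

## Second-step integration

The surviving first-step outputs form the input matrix of thirteen
algorithms: a Gaussian naive Bayes classifier; a shallow feed-forward
network (one hidden layer of 10 units, weight decay 0.1); linear-kernel
SVMs at box constraints 1 and 0.1; bagged trees (a forest with
`mtry = p`, 100 trees) and gradient-boosted trees (30 rounds, depth 3);
and linear and logistic regressions, each unregularized and with
ridge/lasso/elastic-net penalties whose strengths are selected by an
internal 5-fold cross-validation on the training fold. The roster lives
in a data-driven registry (`algorithmRegistry()`) so entries can be
swapped. Inputs are z-scored on training statistics before fitting so
that extracted coefficients are comparable across slots; absolute
standardized coefficients (linear models, SVMs) or impurity/gain
importances (tree ensembles) are rescaled to a maximum of 1. The naive
Bayes classifier and the neural network expose no importances and
report an explicit "not available" marker. Score-producing algorithms
are binarized by the same normalization-plus-optimal-cutoff routine as
the continuous first-step models; the naive Bayes classifier emits hard
labels directly and is therefore the one model without a ROC-AUC.

Evaluation uses accuracy, precision, recall, F1 and the false discovery
rate, plus a rank-based (Mann-Whitney, midrank ties) ROC-AUC.
Zero-denominator metrics are reported as missing and excluded from fold
averages rather than silently coerced to 0.

## Ablation studies and stability

All subsets of one to three inputs are removed and each reduced model
is refitted per fold — 41 subsets when all six layers survive, 25 when
five do. A subset is computable in a fold only when every removed slot
actually survived there, so subsets touching a rarely significant layer
accumulate few folds; records computed in fewer than five folds are
excluded from analysis. Per algorithm and subset, the test metric
(ROC-AUC; accuracy for naive Bayes) is averaged over the computed folds
and divided by the full model's average — values near 1 mean the
removed information was redundant, values above 1 are reported
unclipped. The heatmap export keeps algorithms as rows and subsets in
canonical order as columns.

A discrete feature found significant in at least 7 of the 10 folds is
flagged stable; its direction is sensitivity when the responder
fraction is higher among carriers, resistance otherwise, and the
stability table attaches the mean and SD of the relative importance of
the feature's source model.

## The synthetic data generator

Because the pipeline targets screens that cannot ship with the package,
every stage is exercised on simulated panels. The default generator
draws 300 cell lines with 500 mutation (10% event rate), 300 CNV and
300 hypermethylation features (8%), 12 unevenly sized tissues, 500
expression genes driven by 6 latent factors — the first coupled to
tissue, emulating the documented overlap between lineage and
genome-wide expression — and 11 pathway scores mixing those latent
factors with pathway-own components. The response is a baseline of 0.7
AUC plus Gaussian noise of SD 0.1, shifted by planted drivers whose
effect sizes are expressed in noise-SD units. Three standard scenarios
are fixed: a null world, a single 2-SD mutation driver carried by 30%
of lines, and a two-driver world (strong mutation and pathway drivers
over weak 1.2-SD drivers in the remaining discrete layers so that all
six first-step models survive every fold and the full 41-subset
ablation grid is computed).

The generator reproduces the structural features that matter to the
method — sparsity, redundancy (optional duplicated driver columns),
layer coupling, a known responder fraction of one half — but not the
marginal distributions, gene identities or linkage structure of real
panels. Passing tests therefore demonstrate correctness of the
machinery and sensible statistical behaviour (type-I error control,
power, chance-level null predictions), not clinical performance on any
real screen.

## Numerical and design notes

* Cell-line ordering after alignment is lexicographic in the C locale,
  making runs independent of input file order.
* Ternary CNV columns are tested and clustered on presence/absence;
  the reported per-cluster state is the modal non-zero value, so
  deletion-dominated clusters are distinguishable from amplifications.
* Collinear predictors in the least-squares fits are dropped by the QR
  pivot (with a message); predictions are unchanged versus a
  deduplicated fit.
* Penalized fits with a single surviving input column fall back to the
  unpenalized fit, where the regularization path is moot.
* A second-step fit that fails to converge is replaced by a
  majority-class fallback and flagged, never silently dropped.
* Every stochastic stage (partition, network initialization, bagging,
  boosting, inner CV folds) derives its own sub-seed from the master
  seed, so a run is byte-identical under a fixed configuration; test
  suites rely on this.
* Problem sizes in the shipped tests (150-300 cell lines, tens to
  hundreds of features per layer, 200 null replicates) were chosen as
  the smallest panels at which the statistical properties under test
  are comfortably observable.

## Known limitations

* The per-fold Bonferroni correction controls the family-wise error
  within each data type's test family; no correction is applied across
  the (at most four) discrete layers jointly.
* The quartile policy models only the response extremes; effects
  confined to the inter-quartile band are invisible by construction.
* Importance scores of correlated inputs are diluted (lasso-type
  penalties concentrate weight on one of several redundant inputs);
  the ablation studies, not the raw weights, are the reliable tool for
  attributing contribution — this is precisely why they exist.
* With fewer than about 8 labelled lines per class and fold, several
  algorithms degenerate; the routine refuses to run below 10 labelled
  lines per class.

## A minimal session

```{r example, eval = FALSE}
sim <- generateDataset(plantedMutationSpec(seed = 3))
bundle <- runTwoStep(sim$dataset, twoStepConfig(seed = 4))
summarizeRun(bundle)
stabilityTable(bundle)
writeRunBundle(bundle, "two_step_out")
```
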