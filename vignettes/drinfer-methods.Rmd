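---
title: "Methods: imbalance-aware inference of dietary-restriction-related genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imbalance-aware inference of dietary-restriction-related genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drinfer)
library(dplyr)
```

## The problem

Dietary restriction (DR) is the most robust pro-longevity intervention known,
but only a small minority of ageing-related genes carry curated DR
annotations. Treating "annotated DR-related" versus "not annotated" as a
binary classification problem over ageing-related genes lets heterogeneous
evidence — pathway membership, ontology annotations, interaction-network
topology, expression profiles — be weighed by a classifier, and the
classifier's confident *false positives* (genes annotated NotDR but predicted
DR with high probability) become testable hypotheses of unrecognised
DR-relatedness: absence of evidence in the literature is not evidence of
absence.

Two features of this setting drive the whole design. First, the class ratio
is roughly 1:10, so plain accuracy is useless and every training step must be
imbalance-aware. Second, the features come from many weakly overlapping
sources, so genes have block-wise missingness and the pipeline must either
impute or intersect.

## Feature construction

`drinfer` builds each feature family from plain-text inputs:

* **Membership matrices** (`membership_matrix()`): one binary column per
  pathway/gene set; 1 iff the gene belongs.
* **Ontology matrices** (`propagate_annotations()`, `go_matrix()`): direct
  gene-to-term annotations are closed under the *true-path rule* — a gene
  annotated to a term is annotated to every ancestor up to the root — and the
  closed set becomes binary columns. Genes with no annotation at all are
  dropped from this matrix (they carry no information in this family).
  Propagation is idempotent, and cycles abort with a named edge.
* **Pathway influence** (`influence_profile()`, `influence_matrix()`): for a
  directed pathway graph, the influence of a reference node $r$ on a target
  $t$ is $1 - |S_{-r}(t)|/|S(t)|$, where $S(t)$ is the set of source nodes
  (zero in-degree; all nodes if the graph has none) from which $t$ is
  reachable and $S_{-r}(t)$ the same after deleting $r$. The value is 1 when
  every upstream route passes through $r$, decays as independent routes
  appear, and is 0 for nodes not downstream of $r$. A gene's pathway feature
  is its mean influence over the other members. The source-reachability-loss
  form was chosen because it is the simplest formula reproducing the
  qualitative behaviour the feature family is meant to capture (sole-route
  control = 1, diluted control < 1, upstream/no control = 0), and it is
  isolated behind `influence_profile()` so an alternative is a drop-in.
  Treating *all* nodes as sources in fully cyclic graphs keeps the ratio
  well defined without arbitrary edge deletion.
* **PPI adjacency** (`adjacency_features()`): rows are labelled genes in the
  network; columns add the unlabelled first neighbours, so interactions with
  non-ageing genes still act as features.
* **PPI graph measures** (`graph_measures()`): 18 per-gene measures. The
  standard ones (degree, closeness, betweenness, eigenvector, eccentricity,
  k-core, local clustering, subgraph centrality) delegate to igraph;
  the rest — leverage, Markov (mean-first-passage), maximum neighbourhood
  component, Laplacian (closed-form energy drop), diffusion degree,
  semilocal, geodesic k-path ($k = 3$ reachability count), lobby index
  (h-index over neighbour degrees), topological coefficient — are computed
  from their literature definitions and unit-tested against hand-computed
  values on small graphs. Degenerate conventions are explicit: isolated
  nodes score 0 for closeness, clustering, leverage, topological coefficient
  and DR-ratio; Markov centrality is 0 in singleton components. The
  **DR-ratio** is the fraction of a gene's direct neighbours that carry the
  minority DR label (0 for isolated nodes) — the one label-aware measure.
* **Merging** (`merge_datasets()`, `impute_5nn()`, `intersect_complete()`):
  sources are concatenated over the union of genes with missingness where a
  gene lacks a source. 5NN imputation defines nearness as the *mean* squared
  difference over features known in both genes — the mean rather than the
  sum, so genes with different missingness patterns remain comparable —
  draws neighbours from training instances only, imputes continuous features
  by the neighbour mean and binary ones by the mode, with ties broken
  towards 0 (the majority value of sparse annotations). Fewer than 5
  eligible neighbours fall back to all available, then to the column's
  training mean/mode, each with a warning.

## Preprocessing inside the folds

Binary features pass a minimum-occurrence filter: keep a feature only if at
least $t$ training genes carry it, with $t$ tuned over $\{3, 4, 5\}$ in the
inner CV. Continuous features pass a top-1000 univariate one-way-ANOVA-F
filter, then a greedy absolute-correlation filter at 0.99 (the earlier column
of a correlated pair is kept — the tie-break is unspecified in the source
design, so determinism decides). A nominally continuous column realizing
only the values $\{0, 1\}$ is routed to the binary branch. Absolute (not
signed) correlation is used: two perfectly anti-correlated features are as
redundant as two correlated ones.

One deliberate deviation from the original study design: there the
correlation and univariate filters ran once on the whole dataset, which leaks
test-fold information into feature selection. Here *every* filter is fitted
on training instances only, inside each fold, which is the consistent reading
of the design's own rule that tuning must not touch the test set. Plans are
fitted objects (`dr_plan`), so this is enforced structurally, and every fold
of a `dr_eval` records exactly which gene ids its plan and undersample saw —
the leakage tests assert the intersection with the test fold is empty.

## Classification and evaluation

The evaluation is a nested cross-validation: a stratified 10-fold outer loop
estimates generalisation; inside each outer-training set a stratified 5-fold
inner loop scores every (hyperparameter, occurrence-threshold) configuration
by mean **Gmean** $= \sqrt{\text{sensitivity} \times \text{specificity}}$ and
the argmax (ties: first in grid order) is refitted on the full outer-training
set and evaluated on the untouched fold. Per-fold AUC uses the Mann–Whitney
rank statistic; aggregates are fold means. Classification uses a fixed 0.5
threshold. Folds are assigned on *sorted* gene ids, so instance order never
changes results for a fixed seed; a grouped variant keeps all members of a
group (e.g. proteins of one gene) in one fold, stratifying by the group's
modal label.

The built-in engine is a balanced bagging of decision trees: each of
`n_trees` members is fitted (rpart, no surrogate splits) on an independent
undersample — all minority genes plus an equal-size majority draw — and a
random feature subspace of size $\lceil\sqrt{p}\,\rceil$; ensemble
probability is the mean of member probabilities. This handles imbalance
internally. The xgboost adapter has no internal balancing, so the engine
undersamples its training set once per fold; `easy-ensemble` bags boosted
members over independent undersamples. A CatBoost name is recognised for
completeness but errors, as no R backend is available; the xgboost adapter
covers the gradient-boosting role.

Imputation-versus-undersampling subtlety: undersampling applies to *training*
data only; test folds keep the natural 1:10 ratio so the reported metrics
reflect the deployment class distribution.

## Importance, enrichment, candidates

Feature importance refits the chosen configuration on 100% of the genes —
the target is relevance, not generalisation, which the nested CV already
measured. Impurity importance averages each member tree's Gini-decrease
sums; permutation importance measures the mean drop in training-set Gmean
over `n_repeats = 10` column permutations (Gmean, not raw accuracy, to match
the pipeline's selection metric; repeats were unspecified in the source
design, 10 is the conventional default). Negative drops are floored at 0;
both rankings are min-max rescaled to $[0, 100]$ and a constant raw vector
rescales to all-0 with a warning.

Enrichment of binary features uses a pooled-variance two-proportion z-test
(degenerate pooled proportions give $p = 1$), Welch's t-test for continuous
features (robust to unequal variances; the source design said only
"t-test"), and Benjamini–Hochberg adjustment whose family defaults to *all*
features of the matrix — adjusting only a top-5 shortlist would understate
multiplicity; the family is configurable because the original choice is
unrecoverable.

Candidate inference filters the evaluation's probability vector to
majority-annotated genes at or above the 0.5 threshold and ranks them by
probability (ties by gene id). For two models, each probability vector is
min-max normalized over its *own* full gene set — normalizing before
intersecting, since each model's probability distribution occupies a
different range and raw averages would be dominated by the wider one — then
the common genes' normalized scores are averaged and majority genes with
mean $> 0.8$ reported with both per-model ranks. Only min-max plus
arithmetic mean is implemented; it reproduces the published fusion
arithmetic exactly at 3 decimals.

## The synthetic-data module

Because the original inputs are snapshots of curated databases, the package
ships generators that emulate their *statistical* structure — they are the
test substrate, not biology:

* labels with an exact `round(minority_fraction * n)` minority count
  (default 0.10, the observed order of imbalance);
* sparse Bernoulli binary matrices (default positive rate 0.05, typical of
  pathway membership) with a planted subset whose minority-class rate is
  multiplied by `enrichment_odds`;
* layered single-root DAGs with occasional double parents, annotations left
  unpropagated so closure is exercised downstream;
* directed pathway DAGs over a random order (guaranteeing a source node) and
  preferential-attachment PPI graphs (hub-dominated degrees; the exact
  degree law is not asserted);
* Gaussian matrices with planted standardized mean shifts.

One integer seed drives everything through fixed per-artifact sub-streams,
so different artifact kinds over the same genes are jointly reproducible.
What the generators do *not* emulate: correlated annotation blocks, ontology
term-frequency laws, tissue structure, or any real biology — so passing
tests demonstrate the pipeline's statistical and structural correctness, not
biological validity of any particular prediction.

## Problem sizes and numerical choices

The test suite runs the full pipeline at 2,000 genes / 1:10 imbalance for
signal recovery (planted odds 8, Gmean must exceed 0.7 and all planted
features must enter the top twice-the-planted-count importance ranks) and 20
repeats of a 150-gene permuted-label pipeline for null calibration (mean AUC
within 0.5 ± 0.05); oracle-equivalence suites cover 100 random digraphs for
the influence formula, exhaustive-distance imputation, textbook BH, and
exhaustive filter recomputation. These sizes make the Monte-Carlo bounds
tight enough to be meaningful while keeping a full run in minutes on one
core.

Numerical conventions worth knowing: Gmean inputs are validated to $[0,1]$;
AUC is undefined (NA) for a single-class fold, which stratification
prevents; zero-variance columns correlate as 0; min-max rescales error on
constant vectors (candidate fusion) or warn-and-zero (importance); all
ranking tie-breaks are lexicographic on gene/feature id.

## Known limitations

* The influence formula is a reconstruction from qualitative behaviour, not
  a published equation; alternative formulas slot in behind
  `influence_profile()`.
* The per-pathway aggregation yields one influence column per pathway; a
  published variant appears to have produced several columns per pathway by
  an unstated expansion, which is not reproduced.
* Benchmark numbers from the original curated-database snapshots are not
  reproducible without those snapshots; the package's claims are therefore
  arithmetic identities plus behaviour on synthetic data.
* `easy-ensemble` uses gradient-boosted members rather than AdaBoost ones.
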