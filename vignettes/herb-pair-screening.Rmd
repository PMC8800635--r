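---
title: "Screening effective herb pairs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening effective herb pairs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Traditional Chinese medicine prescriptions combine many herbs, and clinical
practice suggests that certain unordered herb pairs ("coupled herbs") act
synergistically in treating a disease. Given a corpus of electronic
prescription records and public pharmacological knowledge (herb compounds
with oral bioavailability, herb protein targets, herb-regulated symptoms, a
protein–protein interaction network, disease genes and disease symptoms),
the task is to screen, among the frequently co-prescribed *core* herbs,
those pairs whose joint biology points at the disease — and to characterise
how the members of a screened pair complement each other.

`herbpair` implements that screening pipeline end to end:

1. build the herb co-occurrence network from prescriptions and extract core
   herbs by degree-coefficient thresholding;
2. compute five pair-level effectiveness features;
3. label each candidate pair by its Apriori lift over the prescriptions;
4. train classifiers mapping biology to label under stratified
   cross-validation, select the KNN neighbourhood size by pooled AUROC, and
   screen pairs at the Youden-optimal cutoff;
5. test whether screened pairs preferentially bridge herbs with different
   pathway-enrichment profiles (complementarity).

Because the motivating clinical data are private, the package ships a
seeded synthetic generator with *planted* effective pairs, so every stage
is testable against a known ground truth.

## Core herb extraction

Prescriptions define a weighted co-occurrence network: nodes are herbs and
the weight of edge $(u, v)$ is the number of prescriptions containing both.
`extract_core()` retains herbs whose weighted degree $s(v) = \sum_u w(u,v)$
satisfies $s(v) \ge \lambda \cdot \overline{s}$, with degree coefficient
$\lambda = 1.9$ by default.

The reference procedure for this step (a proprietary "hierarchical network
extraction") is not published, so the rule above is a documented stand-in
that consumes the same single published parameter. Three design points:

* **One thresholding pass is the default.** The retained set
  $\{v: s(v) \ge \lambda\overline{s}\}$ is nested in $\lambda$, so the core
  size is non-increasing in the coefficient — a property we consider
  essential for a screening parameter and which repeated re-thresholding
  destroys: after pruning, survivor degrees drop and the rule cascades,
  with the stopping rule then producing non-monotone, near-degenerate
  cores.
* **Deeper refinement stays available** (`max_iterations`, `threshold =
  "fixed"` converges to a weighted degree-core; `"adaptive"` recomputes the
  mean each pass and prunes most aggressively).
* **Fallback:** if a pass would retain fewer than `min_core_size` herbs
  (default 1), the previous herb set is returned — a uniform complete graph
  therefore returns all of its nodes, while a star collapses to its hub.

## The five pair features

For an unordered pair $(a, b)$ of core herbs:

* **Manhattan distance** between the herbs' binary prescription incidence
  rows — the number of prescriptions containing exactly one of the two.
  Low values mean the herbs are prescribed jointly rather than
  interchangeably.
* **Jaccard symptom similarity** $J(S_a \cup S_b, S_{\mathrm{disease}})$
  between the pair's pooled regulated-symptom set and the disease symptom
  set. The union is used for the pair aggregation: a couple is read as
  covering the union of its members' indications.
* **OB sum**: summed oral bioavailability (percent) over the deduplicated
  union of the two herbs' compounds. A molecule shared by both herbs
  counts once — its bioavailability does not double by being sourced
  twice.
* **RWR score**: a random walk with restart is run on the
  confidence-weighted protein interaction network from the disease genes
  (uniform seed vector, restart probability $r = 0.75$), solving
  $p = (1-r) W p + r q$ with $W$ the column-normalized weighted adjacency
  restricted to seed-containing components. The feature is the stationary
  probability mass on the union of the pair's targets. The iterative
  solver stops when the L1 change falls below `tolerance` (default
  1e-10); an exact direct solver is available and the two agree to well
  below 1e-8 on all tested graphs.
* **GoSim**: Wang-method semantic similarity on the biological-process
  ontology, with edge contributions 0.8 (`is_a`) and 0.6 (`part_of`) —
  the standard constants of the method, exposed in `semantic_model()`.
  Gene–gene similarity is the best-match average (BMA) over the genes'
  term sets; the pair-versus-disease score is the BMA over annotated gene
  pairs. BMA (not max, not plain average) is the default aggregation in
  the established GO-similarity tool lineage.

Genes and targets missing from the network or the annotation are dropped
with a warning rather than an error: incompleteness of public databases is
the norm, and a hard failure would make every realistic run abort.

## Labels: Apriori lift as supervision

Since only the pair level is of interest, 2-itemset statistics are counted
directly (identical to the corresponding Apriori level, and trivially
checkable against a brute-force recount). A pair is labeled effective when

* lift $= \dfrac{\mathrm{supp}(ab)}{\mathrm{supp}(a)\,\mathrm{supp}(b)} \ge 1$
  (positive association), and
* $\mathrm{supp}(ab) \ge 0.05$ (the support floor).

The motivating study does not publish its support/confidence/lift cutoffs;
both gates are configuration (`labeling_params()`) with the above
defaults. Pairs containing a never-prescribed herb have undefined lift and
are excluded from labeling.

## Classification and screening

Five model families are provided behind one interface (`fit_predict()`):
the KNN screening model (implemented in the package, Euclidean distances
on z-scored features, uniform or inverse-distance votes, distance ties
broken by ascending training row index) and four comparison models
delegated to standard implementations (RBF-SVM and Gaussian naive Bayes
via e1071, gradient-boosted trees via xgboost, logistic regression via
`glm`).

Evaluation is stratified 10-fold cross-validation. Standardization
statistics are fitted inside each training fold only — the test fold never
influences the transform, which a dedicated perturbation test verifies.
Out-of-fold scores are pooled into a single ROC (with ~100 candidate
pairs, per-fold ROCs would be too coarse); AUROC uses the Mann–Whitney
form, so ties count one half. `select_k()` picks the neighbourhood size
maximizing pooled AUROC (ties to the smaller k). The screening cutoff
maximizes Youden's $J = TPR - FPR$, ties resolved toward the higher
threshold (fewer retained pairs). "Best cutoff" criteria are not named in
the motivating study; Youden's J is the standard ROC choice.

## Complementarity analysis

Each core herb's target set is tested against a gene-set collection by the
upper-tail hypergeometric test with Benjamini–Hochberg correction
(`enrich_targets()`, significant at $q < 0.05$). The herb-by-set matrix of
overlap counts is filtered — a set is kept when at least one herb's count
strictly exceeds that herb's upper quartile (Q3, linear-interpolation
convention; the quartile and its direction are configurable since the
source text does not specify which quartile) — and clustered
agglomeratively (Ward linkage on Euclidean distances of log1p counts, the
usual choice for right-skewed count profiles; both configurable). Finally
a one-sided Fisher exact test asks whether screened pairs bridge herbs in
*different* clusters more often than excluded pairs. The gene universe
defaults to the interaction-network node set and is configurable.

## The synthetic generator

`generate_cohort()` + `generate_knowledge_base()` emulate, with opaque
identifiers, the *shape* of the real inputs: a cohort of prescriptions
(defaults mirror the motivating cohort: 442 herbs, 3697 prescriptions,
23.17 herbs per prescription on average, 18 core herbs, 234 disease
symptoms), heavy-tailed herb frequencies, herb→compound→target structure
with a shared compound pool, a connected scale-free protein network with
confidences in [0.9, 1], disease genes placed on high-degree nodes, a
single-rooted biological-process DAG with `is_a`/`part_of` edges, and a
gene-set collection.

The ground truth is a set of **planted pairs** among the core herbs (at
most two per herb, to avoid saturating any herb's prescription margin).
One dial, `signal_strength` $s$, controls every channel:

* each prescription carries a *treatment-module block* (one planted pair,
  drawn jointly) with probability $\pi = \min(0.95, 0.45\,s)$; at most one
  block per prescription;
* all other herbs enter **independently** with per-herb Bernoulli
  probabilities scaled to the target prescription size; core herbs'
  probabilities are additionally damped by the mean-field focus factor
  $1 - \pi(1 - \mathrm{block\_focus})$, representing the displacement of
  the rest of the core community by module-centred prescribing;
* planted herbs draw targets from within two hops of the disease genes
  (weights decaying steeply with hop distance, because in a scale-free
  network the 2-hop shell of hubs covers most of the graph), symptoms
  from the disease symptom set, and compounds with weight increasing in
  OB — each with probability $\min(0.85, 0.3\,s)$.

Independent inclusion is the load-bearing choice: it makes every pair's
lift exactly 1 in expectation at $s = 0$, so zero-signal labels are pure
sampling noise and carry no structure any feature could track. Mechanisms
that fix the prescription size (sampling herbs without replacement) make
lift systematically frequency-dependent, which the Manhattan feature can
read off — inflating the apparent null AUROC. A residual, irreducible
version of this circularity remains in the design itself: the Manhattan
feature and the lift label are computed from the *same finite records*, so
even at zero signal their shared counting noise produces mildly
above-chance apparent AUROC on single cohorts. The package's null check
therefore evaluates the **mean** cross-validated AUROC over three
generator seeds.

Problem sizes used throughout the tests and the acceptance script — 30
herbs with a 15-herb core, 1000 prescriptions averaging 8 herbs, a
400-node network with 30 disease genes, a 140-term ontology — are chosen
as the smallest configuration in which all candidate-pair statistics rest
on counts of at least a few dozen events, so that the planted structure,
not counting noise, dominates.

What the generator does **not** emulate: real pharmacological content
(identifiers are opaque), dosage and preparation, compound–compound
interactions, correlated physician styles, longitudinal structure, or
expression-derived seed weights. Passing tests therefore demonstrate that
the pipeline recovers planted structure of the stated form at the stated
strength — not that any particular real herb pair is effective.

## Numerical conventions and degenerate inputs

* RWR: isolated seed nodes become absorbing states (probability mass 1 on
  themselves) with a logged message; seeds absent from the network raise
  an error only if *none* remain.
* Wang similarity of a term with itself is exactly 1; terms with no common
  ancestor score 0.
* Duplicate prescription herbs collapse with a warning; empty herb sets
  are rejected.
* Interaction files in the raw 0–1000 score dialect are detected by any
  score exceeding 1 and rescaled.
* Zero-variance features are left unscaled (scale 1) with a warning.
* If the rarer class holds fewer members than the requested folds, the
  fold count is reduced with a warning; single-class data are an error.
* All writers order their output lexicographically, so equal objects give
  byte-identical files; the pipeline writes atomically (temp file +
  rename) and records md5 checksums in its manifest.

## Known limitations

* The core-extraction rule is a stand-in; only its single published
  parameter is anchored.
* Lift-based supervision inherits co-prescription habit: a habitual but
  ineffective pair would be labeled positive in real data. The classifier
  can only correct this insofar as biology disagrees with habit.
* The Manhattan-versus-lift circularity described above biases apparent
  AUROC upward on any single cohort, including real ones.
* BMA GoSim over large gene sets is quadratic in set sizes; profiles are
  cached per run, which is adequate at the hundreds-of-genes scale.
* In the generator, the module-focus displacement that creates the lift
  contrast also flattens the *frequency* contrast of non-planted core
  herbs at high signal, so degree-based core extraction is most
  informative on low-to-moderate-signal cohorts; the pipeline and tests
  therefore treat extraction and pair screening as separable stages.
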