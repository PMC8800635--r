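# herbpair

Screening effective "coupled herbs" — unordered herb pairs that act
together against a disease — from clinical prescription records and public
pharmacological knowledge. The package is aimed at network-pharmacology
researchers who have (or can emulate) a prescription corpus plus
herb→compound→target annotations, and want a tested, reproducible pipeline
from raw records to a ranked, biologically characterised list of candidate
pairs.

## The method

For the core herbs of the prescription co-occurrence network (weighted
degree `s(v) ≥ λ·mean(s)`, degree coefficient `λ = 1.9`), every candidate
pair `(a, b)` is described by five effectiveness features:

| feature | definition |
|---|---|
| `manhattan` | prescriptions containing exactly one of `a`, `b` (L1 distance of incidence rows) |
| `jaccard` | `J(S_a ∪ S_b, S_disease)` on regulated-symptom sets |
| `ob_sum` | summed oral bioavailability over the deduplicated union of the pair's compounds |
| `rwr` | stationary mass of a random walk with restart (`r = 0.75`) from the disease genes, summed over the pair's targets in the confidence-weighted PPI network |
| `gosim` | Wang-method GO biological-process similarity (edge weights 0.8 / 0.6, best-match-average aggregation) between pair targets and disease genes |

Supervision comes from the prescriptions themselves: a pair is labeled
effective when its Apriori lift
`supp(ab) / (supp(a)·supp(b)) ≥ 1` with pair support `≥ 0.05`. A
k-nearest-neighbour classifier (k selected by pooled out-of-fold AUROC
under stratified 10-fold cross-validation, compared against SVM, GBDT,
Gaussian naive Bayes and logistic regression) maps biology to label, and
pairs scoring above the Youden-optimal cutoff are screened in. Finally,
hypergeometric enrichment of each herb's targets, quartile filtering and
Ward clustering of the herb-by-pathway profile, and a one-sided Fisher
test ask whether screened pairs preferentially join herbs from *different*
pathway clusters (complementarity).

A seeded synthetic generator (`generate_cohort()`,
`generate_knowledge_base()`) emulates all inputs with planted effective
pairs, so the whole pipeline is testable without any private data. See
`vignette("herb-pair-screening")` for the full methods account.

## Worked example

```r
library(herbpair)

cohort <- generate_cohort(cohort_params(
  n_herbs = 30, n_core = 15, n_prescriptions = 1000, mean_herbs_per_rx = 8,
  n_symptom_vocab = 100, n_disease_symptoms = 30,
  effective_pair_fraction = 0.12, signal_strength = 2, rng_seed = 1))
kb <- generate_knowledge_base(
  knowledge_params(compounds_per_herb = c(5, 12), ppin_nodes = 400,
                   n_disease_genes = 30, n_compound_pool = 200,
                   effective_pair_fraction = 0.12, signal_strength = 2,
                   rng_seed = 1001),
  sprintf("H%03d", 1:30), cohort$truth)
cohort$truth
#> Synthetic truth: 15 core herbs, 13 planted pair(s)
#>   planted 13 pair(s) with treatment-module probability 0.900 (signal 2.00)

features <- featurize_pairs(cohort$truth$core_herbs, cohort$records,
                            kb$profiles, kb$net, kb$dag, kb$disease)
labels <- assign_labels(mine_pair_associations(cohort$records,
                                               cohort$truth$core_herbs))
#> assign_labels: 14 positive / 91 negative pair(s)

tab <- merge(features, labels[, c("herb_a", "herb_b", "label")])
x <- as.matrix(tab[, c("manhattan", "jaccard", "ob_sum", "rwr", "gosim")])
sel <- select_k(x, tab$label, seed = 1)
sel$best_report
#> Cross-validation report: knn model, 10 folds
#>   pooled AUROC 0.966; Youden cutoff 0.154 (J = 0.791)

screen <- screen_pairs(tab[, c("herb_a", "herb_b")],
                       sel$best_report$scores, sel$best_report$cutoff)
screen
#> Screened pairs: 18 retained at cutoff 0.1538
```

The pooled AUROC (0.966 here) measures how well the five biological
features predict the lift label out of fold; the Youden cutoff turns the
scores into a screened pair list (18 of 105 candidate pairs retained, 12
of the 13 planted pairs among them — a recall of 0.92 against the
generator's ground truth).

The same run, end to end with all intermediate files and a checksummed
manifest, is one call:

```r
run_pipeline(list(workspace = "herbpair_workspace"))
```

or, from a shell, `Rscript inst/cli/herbpair.R run --workspace ws --seed 1`.

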