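test_that("cohort generation is deterministic and respects cardinalities", {
  p <- cohort_params(n_herbs = 20L, n_core = 8L, n_prescriptions = 50L,
                     mean_herbs_per_rx = 5, n_symptom_vocab = 30L,
                     n_disease_symptoms = 10L, rng_seed = 1L)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a, b)
  expect_length(a$records, 50L)
  expect_true(all(vapply(a$records, function(r) length(r$herbs) > 0,
                         logical(1))))
  expect_true(all(vapply(a$records, function(r) !anyDuplicated(r$herbs),
                         logical(1))))
  expect_true(all(unlist(lapply(a$records, `[[`, "herbs")) %in%
                    sprintf("H%03d", 1:20)))
  expect_error(cohort_params(n_herbs = 5L, n_core = 9L), "n_core")
})

test_that("planted pairs co-occur above background at strong signal", {
  w <- compact_world(1L, 2)
  truth <- w$cohort$truth
  counts <- mine_pair_associations(w$cohort$records, truth$core_herbs)
  key <- paste(counts$herb_a, counts$herb_b)
  planted <- key %in% paste(truth$planted_pairs$herb_a,
                            truth$planted_pairs$herb_b)
  expect_gt(mean(counts$support_pair[planted]),
            mean(counts$support_pair[!planted]))
})

test_that("record symptoms over-represent the disease symptom set", {
  w <- compact_world(1L, 2)
  sym <- unlist(lapply(w$cohort$records, `[[`, "symptoms"))
  frac_disease <- mean(sym %in% w$cohort$truth$disease_symptoms)
  # disease symptoms are 30 of 100 vocabulary terms; uniform draws would put
  # ~0.3 of symptom mentions in the disease set
  expect_gt(frac_disease, 0.5)
})

test_that("knowledge bases are deterministic, valid and well-connected", {
  w1 <- compact_world(2L, 2)
  kp <- knowledge_params(compounds_per_herb = c(5L, 12L), ppin_nodes = 400L,
                         n_disease_genes = 30L, n_compound_pool = 200L,
                         effective_pair_fraction = 0.12,
                         signal_strength = 2, rng_seed = 1002L)
  again <- generate_knowledge_base(kp, sprintf("H%03d", 1:30),
                                   w1$cohort$truth)
  expect_identical(again$net$edges, w1$kb$net$edges)

  kb <- w1$kb
  for (prof in kb$profiles) {
    expect_gte(nrow(prof$compounds), 1L)
    expect_gte(length(intersect(prof$targets, kb$net$nodes)), 1L)
  }
  # disease genes sit inside the connected network
  g <- igraph::graph_from_data_frame(
    kb$net$edges[, c("protein_a", "protein_b")], directed = FALSE,
    vertices = kb$net$nodes)
  comp <- igraph::components(g)
  giant <- which.max(comp$csize)
  expect_true(all(comp$membership[kb$disease$disease_genes] == giant))
  expect_s3_class(kb$dag, "ontology_dag")  # constructor enforces DAG + root
  expect_true(all(lengths(kb$dag$annotations) >= 1L))
  expect_error(generate_knowledge_base(kp, character(), w1$cohort$truth),
               "empty herb list")
})

test_that("a degenerate OB interval pins every compound's OB", {
  w <- compact_world(3L, 1)
  kp <- knowledge_params(ob_range = c(30, 30), ppin_nodes = 100L,
                         n_disease_genes = 10L, n_compound_pool = 50L,
                         n_terms = 30L, rng_seed = 5L)
  kb <- generate_knowledge_base(kp, sprintf("H%03d", 1:30), w$cohort$truth)
  obs <- unlist(lapply(kb$profiles, function(p) p$compounds$ob_percent))
  expect_true(all(obs == 30))
})

test_that("every generated artifact survives a round-trip through the readers", {
  w <- compact_world(1L, 2)
  dir <- withr::local_tempdir()
  f <- function(name) file.path(dir, name)

  write_prescriptions(w$cohort$records, f("rx.jsonl"))
  expect_length(read_prescriptions(f("rx.jsonl")), 1000L)

  write_ppin(w$kb$net, f("ppin.tsv"))
  expect_equal(read_ppin(f("ppin.tsv"), 0)$edges, w$kb$net$edges,
               tolerance = 1e-12)

  write_herb_profiles(w$kb$profiles, f("profiles.jsonl"))
  back <- read_herb_profiles(f("profiles.jsonl"))
  expect_equal(names(back), names(w$kb$profiles))
  expect_equal(back$H001$targets, w$kb$profiles$H001$targets)

  write_obo_subset(w$kb$dag, f("onto.obo"))
  dag2 <- read_obo_subset(f("onto.obo"))
  expect_equal(nrow(dag2$terms), nrow(w$kb$dag$terms))
  expect_equal(nrow(dag2$edges), nrow(w$kb$dag$edges))

  write_gene_annotations(w$kb$dag$annotations, f("ann.tsv"))
  expect_equal(read_gene_annotations(f("ann.tsv")), w$kb$dag$annotations)

  write_gmt(w$kb$gene_sets, f("sets.gmt"))
  gs <- read_gmt(f("sets.gmt"))
  expect_setequal(names(gs), names(w$kb$gene_sets))
  expect_setequal(gs$PW001, w$kb$gene_sets$PW001)

  write_disease_context(w$kb$disease, f("disease.json"))
  expect_equal(read_disease_context(f("disease.json")), w$kb$disease)
})

test_that("the planted-vs-background gap grows with signal strength", {
  signals <- c(0, 1.5, 3)
  gaps <- array(NA_real_, c(3, length(signals), 5),
                dimnames = list(NULL, NULL,
                                c("manhattan", "jaccard", "ob_sum", "rwr",
                                  "gosim")))
  for (si in seq_along(signals)) {
    for (seed in 1:3) {
      w <- compact_world(seed + 40L, signals[si], n_prescriptions = 400L,
                         n_herbs = 20L, n_core = 10L, ppin_nodes = 200L)
      ft <- suppressWarnings(featurize_pairs(
        w$cohort$truth$core_herbs, w$cohort$records, w$kb$profiles,
        w$kb$net, w$kb$dag, w$kb$disease))
      key <- paste(ft$herb_a, ft$herb_b)
      planted <- key %in% paste(w$cohort$truth$planted_pairs$herb_a,
                                w$cohort$truth$planted_pairs$herb_b)
      for (feat in dimnames(gaps)[[3]]) {
        gap <- mean(ft[[feat]][planted]) - mean(ft[[feat]][!planted])
        if (feat == "manhattan") gap <- -gap  # closeness, not distance
        gaps[seed, si, feat] <- gap
      }
    }
  }
  mean_gaps <- apply(gaps, c(2, 3), mean)
  for (feat in dimnames(gaps)[[3]]) {
    expect_gt(mean_gaps[3, feat], mean_gaps[1, feat])
    # at zero signal the planted pairs are indistinguishable from background
    expect_lt(abs(mean_gaps[1, feat]), abs(mean_gaps[3, feat]) * 0.5)
  }
})
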