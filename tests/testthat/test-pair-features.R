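test_that("Manhattan distance counts symmetric-difference prescriptions", {
  records <- make_records(list(c("u", "v"), c("u", "v", "w"), c("v", "w")))
  m <- incidence_matrix(records)
  expect_equal(manhattan_distance(m, "u", "v"), 1L)  # rows (1,1,0) vs (1,1,1)
  expect_equal(manhattan_distance(m, "v", "v"), 0L)
  # rows (1,1,0) vs (0,1,1) -> 2
  m2 <- incidence_matrix(make_records(list("a", c("a", "b"), "b")))
  expect_equal(manhattan_distance(m2, "a", "b"), 2L)
  # disjoint herbs each in k records -> 2k
  m3 <- incidence_matrix(make_records(list("a", "a", "b", "b")))
  expect_equal(manhattan_distance(m3, "a", "b"), 4L)
  expect_error(manhattan_distance(m, "u", "zzz"), "zzz")
})

test_that("Manhattan distance satisfies the triangle inequality", {
  cohort <- generate_cohort(cohort_params(
    n_herbs = 10L, n_core = 4L, n_prescriptions = 30L, mean_herbs_per_rx = 4,
    n_symptom_vocab = 20L, n_disease_symptoms = 5L, rng_seed = 5L))
  m <- incidence_matrix(cohort$records)
  herbs <- rownames(m)
  trios <- utils::combn(herbs[1:8], 3L)
  for (i in seq_len(ncol(trios))) {
    d_ab <- manhattan_distance(m, trios[1, i], trios[2, i])
    d_bc <- manhattan_distance(m, trios[2, i], trios[3, i])
    d_ac <- manhattan_distance(m, trios[1, i], trios[3, i])
    expect_lte(d_ac, d_ab + d_bc)
  }
})

test_that("pair symptom Jaccard follows the set definition", {
  dis <- disease_context("G1", c("y", "z", "w"))
  pa <- herb_profile("a", NULL, symptoms = c("x", "y"))
  pb <- herb_profile("b", NULL, symptoms = c("y", "z"))
  expect_equal(jaccard_symptom_similarity(pa, pb, dis), 0.5)  # {x,y,z} vs {y,z,w}
  same <- disease_context("G1", c("x", "y"))
  expect_equal(jaccard_symptom_similarity(pa, herb_profile("b", NULL), same), 1)
  disj <- disease_context("G1", c("q", "r"))
  expect_equal(jaccard_symptom_similarity(pa, pb, disj), 0)
  empty <- herb_profile("e", NULL)
  expect_equal(jaccard_symptom_similarity(empty, empty, dis), 0)
})

test_that("pair OB sum deduplicates shared compounds", {
  h1 <- herb_profile("h1", data.frame(compound_id = c("c1", "c2"),
                                      ob_percent = c(30, 40)))
  h2 <- herb_profile("h2", data.frame(compound_id = c("c2", "c3"),
                                      ob_percent = c(40, 50)))
  empty <- herb_profile("e", NULL)
  expect_equal(ob_sum(h1, h2), 120)
  expect_equal(ob_sum(h2, h1), 120)  # order invariance
  expect_equal(ob_sum(empty, empty), 0)
  expect_equal(ob_sum(h1, empty), 70)
})

test_that("RWR propagation matches hand-solved cases at r = 0.75", {
  lone <- ppin(data.frame(protein_a = character(), protein_b = character(),
                          confidence = numeric()), nodes = "A")
  expect_equal(suppressMessages(rwr_propagate(lone, "A"))[["A"]], 1)

  ab <- ppin(data.frame(protein_a = "A", protein_b = "B", confidence = 1))
  for (solver in c("iterative", "direct")) {
    p <- rwr_propagate(ab, "A", rwr_params(0.75, solver = solver))
    expect_equal(unname(p[c("A", "B")]), c(0.8, 0.2), tolerance = 1e-9)
  }
  abc <- ppin(data.frame(protein_a = c("A", "B"), protein_b = c("B", "C"),
                         confidence = 1))
  p <- rwr_propagate(abc, "A", rwr_params(0.75, solver = "direct"))
  expect_equal(unname(p[c("A", "B", "C")]), c(0.775, 0.2, 0.025),
               tolerance = 1e-9)
  expect_error(rwr_propagate(ab, "Z"), "seed")
})

test_that("RWR pair scores sum target probabilities", {
  ab <- ppin(data.frame(protein_a = "A", protein_b = "B", confidence = 1))
  dis <- disease_context("A", "s1")
  all_t <- herb_profile("x", NULL, targets = c("A", "B"))
  none <- herb_profile("y", NULL, targets = "Q")
  only_b <- herb_profile("z", NULL, targets = "B")
  expect_equal(rwr_pair_score(ab, dis, all_t, all_t), 1, tolerance = 1e-9)
  expect_equal(rwr_pair_score(ab, dis, none, none), 0)
  expect_equal(rwr_pair_score(ab, dis, only_b, none), 0.2, tolerance = 1e-9)
})

test_that("Wang similarity matches the two-term case and basic identities", {
  dag <- two_term_dag()
  expect_equal(wang_term_similarity(dag, semantic_model(), "A", "B"),
               1.8 / 2.8)
  expect_equal(wang_term_similarity(dag, semantic_model(), "B", "B"), 1)
  expect_error(wang_term_similarity(dag, semantic_model(), "A", "zzz"),
               "unknown")
  # no common ancestor (hand-built forest, bypassing root validation)
  forest <- structure(list(
    terms = data.frame(id = c("X", "Y"), name = c("X", "Y"),
                       namespace = "biological_process"),
    edges = data.frame(child = character(), parent = character(),
                       relation = character()),
    annotations = list()), class = "ontology_dag")
  expect_equal(wang_term_similarity(forest, semantic_model(), "X", "Y"), 0)
})

test_that("Wang similarity is symmetric and relabel-invariant on random DAGs", {
  model <- semantic_model()
  for (seed in c(1L, 2L, 3L)) {
    dag <- random_dag(12L, seed)
    ids <- dag$terms$id
    pairs <- replicate(6, sample(ids, 2L), simplify = FALSE)
    for (p in pairs) {
      s12 <- wang_term_similarity(dag, model, p[1], p[2])
      s21 <- wang_term_similarity(dag, model, p[2], p[1])
      expect_equal(s12, s21)
      expect_equal(s12, oracle_wang_sim(dag, model, p[1], p[2]))
    }
    # relabeling: reverse the id alphabet
    relabel <- stats::setNames(sprintf("Q%03d", rev(seq_along(ids))), ids)
    dag2 <- ontology_dag(
      data.frame(id = unname(relabel[ids]), name = ids,
                 namespace = "biological_process"),
      data.frame(child = unname(relabel[dag$edges$child]),
                 parent = unname(relabel[dag$edges$parent]),
                 relation = dag$edges$relation))
    for (p in pairs) {
      expect_equal(
        wang_term_similarity(dag, model, p[1], p[2]),
        wang_term_similarity(dag2, model, relabel[[p[1]]], relabel[[p[2]]]))
    }
  }
})

test_that("gene-set GoSim aggregates by best-match average", {
  dag <- two_term_dag(annotations = list(g1 = "A", g2 = "B", g3 = "B"))
  expect_equal(gosim_pair_score(dag, semantic_model(), "g2", "g3"), 1)
  expect_equal(gosim_pair_score(dag, semantic_model(), "g1", "g2"), 1.8 / 2.8)
  # unannotated genes are skipped with a warning; fully unannotated errors
  expect_warning(s <- gosim_pair_score(dag, semantic_model(),
                                       c("g1", "nope"), "g2"), "skipping")
  expect_equal(s, 1.8 / 2.8)
  expect_error(suppressWarnings(
    gosim_pair_score(dag, semantic_model(), "nope", "g2")), "no annotated")
  # sets annotated only in another namespace are treated as unannotated
  mixed <- ontology_dag(
    data.frame(id = c("A", "B", "M"), name = c("A", "B", "M"),
               namespace = c("biological_process", "biological_process",
                             "molecular_function")),
    data.frame(child = "B", parent = "A", relation = "is_a"),
    annotations = list(g1 = "A", g2 = "M"))
  expect_error(suppressWarnings(
    gosim_pair_score(mixed, semantic_model(), "g1", "g2")), "no annotated")
})

test_that("featurize_pairs produces one canonical row per unordered pair", {
  w <- compact_world(1L, 2, n_prescriptions = 200L, n_herbs = 12L,
                     n_core = 6L, ppin_nodes = 150L)
  herbs <- w$cohort$truth$core_herbs
  ft <- suppressWarnings(featurize_pairs(herbs, w$cohort$records,
                                         w$kb$profiles, w$kb$net, w$kb$dag,
                                         w$kb$disease))
  expect_equal(nrow(ft), choose(6, 2))
  expect_true(all(ft$herb_a < ft$herb_b))
  expect_true(all(ft$jaccard >= 0 & ft$jaccard <= 1))
  expect_true(all(ft$rwr >= 0 & ft$rwr <= 1))
  expect_true(all(ft$gosim >= 0 & ft$gosim <= 1))
  expect_true(all(ft$manhattan >= 0 & ft$manhattan == round(ft$manhattan)))
  expect_true(all(is.finite(as.matrix(ft[, -(1:2)]))))

  two <- suppressWarnings(featurize_pairs(herbs[1:2], w$cohort$records,
                                          w$kb$profiles, w$kb$net, w$kb$dag,
                                          w$kb$disease))
  expect_equal(nrow(two), 1L)
})

test_that("planted pairs outscore background on the RWR feature at strong signal", {
  cf <- compact_features(1L, 2)
  tab <- cf$table
  expect_gt(mean(tab$rwr[tab$planted]), mean(tab$rwr[!tab$planted]))
})
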