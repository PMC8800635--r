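test_that("prescription files round-trip in both dialects", {
  records <- list(rec("r1", c("A", "B"), c("s1", "s2")),
                  rec("r2", "C", "s3"),
                  rec("r3", c("B", "C"), character()))
  for (ext in c("jsonl", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_prescriptions(records, path)
    back <- read_prescriptions(path)
    expect_length(back, 3L)
    for (i in 1:3) {
      expect_setequal(back[[i]]$herbs, records[[i]]$herbs)
      expect_setequal(back[[i]]$symptoms, records[[i]]$symptoms)
      expect_identical(back[[i]]$record_id, records[[i]]$record_id)
    }
  }
})

test_that("duplicate herbs collapse with a warning and empty records are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,herbs,symptoms", "r1,A;A;B,s1"), path)
  expect_warning(records <- read_prescriptions(path), "duplicate")
  expect_setequal(records[[1]]$herbs, c("A", "B"))

  writeLines(c("record_id,herbs,symptoms", "r1,,s1"), path)
  expect_error(read_prescriptions(path), "empty herb set")
})

test_that("malformed and empty prescription files raise informative errors", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"id":"r1","herbs":["A"],"symptoms":[]}', "{not json"), path)
  expect_error(read_prescriptions(path), "line 2")
  writeLines(character(), path)
  expect_error(read_prescriptions(path), "empty")
})

test_that("a cohort-sized synthetic prescription file parses quickly", {
  cohort <- generate_cohort(cohort_params(
    n_herbs = 442L, n_core = 18L, n_prescriptions = 3697L,
    rng_seed = 7L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_prescriptions(cohort$records, path)
  elapsed <- system.time(back <- read_prescriptions(path))[["elapsed"]]
  expect_length(back, 3697L)
  expect_lt(elapsed, 1)
})

test_that("PPIN reader applies the confidence threshold and STRING dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tprotein_b\tcombined_score",
               "A\tB\t950", "B\tC\t800", "A\tA\t999"), path)
  net <- read_ppin(path, min_confidence = 0.9)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$protein_a, "A")
  expect_equal(net$edges$confidence, 0.95)

  all_edges <- read_ppin(path, min_confidence = 0)
  expect_equal(nrow(all_edges$edges), 2L)  # self-loop still dropped

  writeLines(c("protein_a\tprotein_b\tcombined_score",
               "A\tB\t0.93", "B\tC\t-1"), path)
  expect_error(read_ppin(path), "negative")

  writeLines(c("protein_a\tprotein_b\tcombined_score",
               "A\tB\t0.93", "B\tC\t0.85"), path)
  native <- read_ppin(path, min_confidence = 0.9)  # already-normalized dialect
  expect_equal(native$edges$confidence, 0.93)
})

test_that("PPIN round-trips and duplicate edges keep the maximum confidence", {
  net <- ppin(data.frame(protein_a = c("A", "B", "B"),
                         protein_b = c("B", "A", "C"),
                         confidence = c(0.91, 0.97, 0.95)))
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$edges$confidence[net$edges$protein_a == "A"], 0.97)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ppin(net, path)
  expect_equal(read_ppin(path, 0)$edges, net$edges)
})

test_that("GMT files parse by definition and round-trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines("S1\tdesc\tG1\tG2", path)
  sets <- read_gmt(path)
  expect_setequal(sets$S1, c("G1", "G2"))
  write_gmt(sets, path)
  expect_equal(read_gmt(path)$S1, c("G1", "G2"))
  writeLines("S1\tonly-desc", path)
  expect_error(read_gmt(path), "line 1")
})

test_that("simplified OBO parses is_a/part_of and round-trips counts", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "name: root", "namespace: biological_process",
               "", "[Term]", "id: B", "name: child",
               "namespace: biological_process", "is_a: A ! root",
               "", "[Term]", "id: C", "name: part",
               "namespace: biological_process",
               "relationship: part_of A ! root"), path)
  dag <- read_obo_subset(path)
  expect_equal(nrow(dag$terms), 3L)
  expect_equal(dag$edges$relation[dag$edges$child == "B"], "is_a")
  expect_equal(dag$edges$relation[dag$edges$child == "C"], "part_of")
  out <- withr::local_tempfile(fileext = ".obo")
  write_obo_subset(dag, out)
  back <- read_obo_subset(out)
  expect_equal(nrow(back$terms), nrow(dag$terms))
  expect_equal(nrow(back$edges), nrow(dag$edges))
})

test_that("cyclic ontologies and multi-root namespaces are rejected", {
  terms <- data.frame(id = c("A", "B"), name = c("A", "B"),
                      namespace = "biological_process")
  cyc <- data.frame(child = c("A", "B"), parent = c("B", "A"),
                    relation = "is_a")
  expect_error(ontology_dag(terms, cyc), "cyclic")
  terms3 <- data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                       namespace = "biological_process")
  expect_error(
    ontology_dag(terms3, data.frame(child = "C", parent = "A",
                                    relation = "is_a")),
    "exactly one root")
})

test_that("herb profiles validate OB and round-trip", {
  profs <- list(
    H1 = herb_profile("H1", data.frame(compound_id = c("c1", "c2"),
                                       ob_percent = c(30, 55)),
                      targets = c("G1", "G2"), symptoms = "s1"),
    H2 = herb_profile("H2", NULL, targets = "G3"))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_herb_profiles(profs, path)
  back <- read_herb_profiles(path)
  expect_equal(back$H1$compounds$ob_percent, c(30, 55))
  expect_equal(back$H2$targets, "G3")
  expect_equal(nrow(back$H2$compounds), 0L)
  expect_error(herb_profile("bad", data.frame(compound_id = "c", ob_percent = 130)),
               "OB")
  expect_error(herb_profile("bad", data.frame(compound_id = c("c", "c"),
                                              ob_percent = c(10, 20))),
               "duplicate")
})

test_that("gene lists, annotations and disease contexts round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_list(c("G2", "G1", "G1"), path)
  expect_equal(read_gene_list(path), c("G1", "G2"))

  ann <- list(G1 = c("T1", "T2"), G2 = "T1")
  write_gene_annotations(ann, path)
  expect_equal(read_gene_annotations(path), ann)

  dc <- disease_context(c("G1", "G2"), c("s1", "s2"), "toy")
  jpath <- withr::local_tempfile(fileext = ".json")
  write_disease_context(dc, jpath)
  expect_equal(read_disease_context(jpath), dc)
  expect_error(disease_context(character(), "s"), "non-empty")
})
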