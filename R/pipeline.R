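# End-to-end orchestration: simulate -> network -> core -> features ->
# labels -> train -> screen -> enrich, from one declarative config.

#' Default pipeline configuration
#'
#' Returns the fully populated configuration used when keys are omitted. The
#' method constants default to their published values (degree coefficient
#' 1.9, restart probability 0.75, 10 folds, lift threshold 1.0, q < 0.05).
#' The bundled synthetic cohort block is a compact demonstration world (30
#' herbs, 15 core, 1000 prescriptions, strong planted signal) sized so a
#' full run completes in seconds.
#'
#' @return Nested named list of configuration blocks.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    workspace = "herbpair_workspace",
    cohort = list(n_herbs = 30L, n_core = 15L, n_prescriptions = 1000L,
                  mean_herbs_per_rx = 8, n_symptom_vocab = 100L,
                  n_disease_symptoms = 30L, effective_pair_fraction = 0.12,
                  signal_strength = 2, core_weight = 4, freq_sd = 0.35),
    knowledge = list(compounds_per_herb = c(5L, 12L),
                     targets_per_compound = c(1L, 3L),
                     ob_range = c(5, 95), ppin_nodes = 400L, pa_edges = 2L,
                     n_disease_genes = 30L, effective_pair_fraction = 0.12,
                     signal_strength = 2, n_compound_pool = 200L,
                     n_terms = 140L, n_gene_sets = 25L),
    extraction = list(lambda_degree = 1.9, min_core_size = 2L,
                      max_iterations = 1L),
    rwr = list(restart_prob = 0.75, tolerance = 1e-10, max_iter = 10000L,
               solver = "iterative"),
    semantic = list(w_is_a = 0.8, w_part_of = 0.6,
                    namespace = "biological_process"),
    labeling = list(min_support = 0.05, lift_threshold = 1.0),
    classification = list(k_grid = c(3L, 5L, 7L, 9L, 11L, 13L),
                          n_folds = 10L, weighting = "uniform"),
    enrichment = list(q_cutoff = 0.05, quartile = 0.75,
                      n_herb_clusters = 5L, n_set_clusters = 7L))
}

# Recursively merge user values over defaults, rejecting unknown keys.
merge_config <- function(defaults, user, path = character()) {
  errors <- character(0)
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      errors <- c(errors, sprintf("unknown configuration key '%s'", full))
      next
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      sub <- merge_config(defaults[[key]], as.list(user[[key]]),
                          c(path, key))
      defaults[[key]] <- sub$config
      errors <- c(errors, sub$errors)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  list(config = defaults, errors = errors)
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or accepts a list), fills in all defaults, rejects
#' unknown keys, and checks every range constraint, reporting all violations
#' at once rather than the first only.
#'
#' @param config Path to a YAML config file, or a (possibly partial) named
#'   list; `NULL` yields the full default configuration.
#' @return Normalized configuration list of class `pipeline_config`.
#' @export
validate_config <- function(config = NULL) {
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    if (!file.exists(config)) hp_stop("config file '%s' does not exist", config)
    yaml::read_yaml(config) %||% list()
  } else {
    as.list(config)
  }
  merged <- merge_config(default_config(), user)
  errors <- merged$errors
  cfg <- merged$config
  check <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  check(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed),
        "seed: must be an integer")
  check(is.numeric(cfg$rwr$restart_prob) && cfg$rwr$restart_prob > 0 &&
          cfg$rwr$restart_prob <= 1,
        "rwr.restart_prob: must lie in (0, 1]")
  check(cfg$extraction$lambda_degree > 0,
        "extraction.lambda_degree: must be > 0")
  check(cfg$labeling$min_support >= 0 && cfg$labeling$min_support <= 1,
        "labeling.min_support: must lie in [0, 1]")
  check(cfg$labeling$lift_threshold >= 0,
        "labeling.lift_threshold: must be >= 0")
  check(cfg$classification$n_folds >= 2,
        "classification.n_folds: must be >= 2")
  check(length(cfg$classification$k_grid) >= 1,
        "classification.k_grid: must be non-empty")
  check(cfg$enrichment$q_cutoff > 0 && cfg$enrichment$q_cutoff < 1,
        "enrichment.q_cutoff: must lie in (0, 1)")
  check(cfg$enrichment$quartile >= 0 && cfg$enrichment$quartile <= 1,
        "enrichment.quartile: must lie in [0, 1]")
  check(cfg$cohort$signal_strength >= 0,
        "cohort.signal_strength: must be >= 0")
  check(cfg$cohort$n_core <= cfg$cohort$n_herbs,
        "cohort.n_core: must not exceed cohort.n_herbs")
  check(cfg$semantic$w_is_a > 0 && cfg$semantic$w_is_a < 1,
        "semantic.w_is_a: must lie in (0, 1)")
  check(cfg$semantic$w_part_of > 0 && cfg$semantic$w_part_of < 1,
        "semantic.w_part_of: must lie in (0, 1)")
  if (length(errors) > 0L)
    hp_stop("invalid configuration:\n  - %s", paste(errors, collapse = "\n  - "))
  structure(cfg, class = "pipeline_config")
}

stage_error <- function(stage, e) {
  hp_stop("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
}

#' Run the full screening pipeline
#'
#' Executes all stages in dependency order inside `config$workspace`:
#' simulate the cohort and knowledge base, build the co-occurrence network,
#' extract core herbs, featurize core pairs, mine Apriori-lift labels, select
#' and cross-validate the KNN screening model (comparison models are
#' available via [fit_predict()]), screen pairs at the Youden cutoff, and run
#' the enrichment/clustering complementarity analysis. Every stage writes
#' its outputs atomically; a failing stage halts the run with a stage-named
#' error and leaves earlier outputs intact. A machine-readable manifest
#' (config hash, per-output checksums, stage counts, timings) is written
#' last.
#'
#' @param config A [validate_config()] result, a partial list, or a YAML
#'   path.
#' @return The run manifest, invisibly (also written to
#'   `workspace/manifest.json`).
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  ws <- cfg$workspace
  dir.create(ws, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(cfg),
                   config_hash = config_hash(cfg),
                   r_version = as.character(getRversion()),
                   stages = list())
  t_all <- proc.time()[["elapsed"]]
  out_file <- function(name) file.path(ws, name)
  note_stage <- function(name, outputs, counts, t0) {
    manifest$stages[[name]] <<- list(
      status = "ok",
      outputs = as.list(tools::md5sum(outputs)),
      counts = counts,
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
  }

  ## simulate -----------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  sim <- tryCatch({
    cp <- do.call(cohort_params, c(cfg$cohort, list(rng_seed = cfg$seed)))
    cohort <- generate_cohort(cp)
    kp <- do.call(knowledge_params,
                  c(cfg$knowledge, list(rng_seed = cfg$seed + 1L)))
    herbs <- sprintf("H%03d", seq_len(cp$n_herbs))
    kb <- generate_knowledge_base(kp, herbs, cohort$truth)
    write_prescriptions(cohort$records, out_file("prescriptions.jsonl"))
    write_ppin(kb$net, out_file("ppin.tsv"))
    write_herb_profiles(kb$profiles, out_file("herb_profiles.jsonl"))
    write_obo_subset(kb$dag, out_file("ontology.obo"))
    write_gene_annotations(kb$dag$annotations, out_file("annotations.tsv"))
    write_gmt(kb$gene_sets, out_file("gene_sets.gmt"))
    write_disease_context(kb$disease, out_file("disease.json"))
    write_feature_table(cohort$truth$planted_pairs,
                        out_file("planted_pairs.csv"))
    list(cohort = cohort, kb = kb)
  }, error = function(e) stage_error("simulate", e))
  note_stage("simulate",
             out_file(c("prescriptions.jsonl", "ppin.tsv",
                        "herb_profiles.jsonl", "ontology.obo",
                        "annotations.tsv", "gene_sets.gmt", "disease.json",
                        "planted_pairs.csv")),
             list(records = length(sim$cohort$records),
                  planted_pairs = nrow(sim$cohort$truth$planted_pairs)), t0)

  ## co-occurrence network and core extraction --------------------------
  t0 <- proc.time()[["elapsed"]]
  core <- tryCatch({
    net <- build_cooccurrence_network(sim$cohort$records)
    ext <- extract_core(net, cfg$extraction$lambda_degree,
                        cfg$extraction$min_core_size,
                        cfg$extraction$max_iterations)
    utils::write.table(data.frame(herb = ext$core), out_file("core_herbs.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_feature_table(ext$log, out_file("extraction_log.csv"))
    ext
  }, error = function(e) stage_error("extract-core", e))
  note_stage("extract-core", out_file(c("core_herbs.tsv", "extraction_log.csv")),
             list(core_herbs = length(core$core)), t0)

  ## features ------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  features <- tryCatch({
    rw <- do.call(rwr_params, cfg$rwr)
    sm <- do.call(semantic_model, cfg$semantic)
    ft <- suppressWarnings(
      featurize_pairs(core$core, sim$cohort$records, sim$kb$profiles,
                      sim$kb$net, sim$kb$dag, sim$kb$disease, rw, sm))
    write_feature_table(ft, out_file("pair_features.csv"))
    ft
  }, error = function(e) stage_error("featurize", e))
  note_stage("featurize", out_file("pair_features.csv"),
             list(pairs = nrow(features)), t0)

  ## labels ---------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  labeled <- tryCatch({
    lp <- do.call(labeling_params, cfg$labeling)
    assoc <- mine_pair_associations(sim$cohort$records, core$core, lp)
    lab <- suppressMessages(assign_labels(assoc, lp))
    write_feature_table(lab, out_file("pair_labels.csv"))
    lab
  }, error = function(e) stage_error("label", e))
  note_stage("label", out_file("pair_labels.csv"),
             list(pairs = nrow(labeled), positive = sum(labeled$label)), t0)

  ## train + screen -------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  screened <- tryCatch({
    merged <- merge(features, labeled[, c("herb_a", "herb_b", "label")],
                    by = c("herb_a", "herb_b"))
    merged <- merged[order(merged$herb_a, merged$herb_b), , drop = FALSE]
    x <- as.matrix(merged[, c("manhattan", "jaccard", "ob_sum", "rwr",
                              "gosim")])
    y <- merged$label
    sel <- suppressWarnings(
      select_k(x, y, cfg$classification$k_grid, cfg$classification$n_folds,
               seed = cfg$seed, weighting = cfg$classification$weighting))
    rep <- sel$best_report
    scr <- screen_pairs(merged[, c("herb_a", "herb_b")], rep$scores,
                        rep$cutoff)
    write_feature_table(rep$roc, out_file("roc_points.csv"))
    write_feature_table(scr$retained, out_file("screened_pairs.tsv"))
    write_feature_table(scr$proportions, out_file("herb_proportions.csv"))
    write_report(list(selected_k = sel$best_k, auroc = rep$auroc,
                      cutoff = rep$cutoff, youden_j = rep$youden_j,
                      auroc_by_k = lapply(sel$reports, `[[`, "auroc")),
                 out_file("cv_report.json"))
    list(merged = merged, select = sel, report = rep, screen = scr)
  }, error = function(e) stage_error("train-screen", e))
  note_stage("train-screen",
             out_file(c("roc_points.csv", "screened_pairs.tsv",
                        "herb_proportions.csv", "cv_report.json")),
             list(selected_k = screened$select$best_k,
                  auroc = screened$report$auroc,
                  retained = nrow(screened$screen$retained)), t0)

  ## enrichment -----------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  enr <- tryCatch({
    herb_targets <- lapply(sim$kb$profiles[core$core], `[[`, "targets")
    universe <- sim$kb$net$nodes
    profile <- build_herb_profile(herb_targets, sim$kb$gene_sets, universe)
    retained_sets <- quartile_filter(profile, cfg$enrichment$quartile)
    prof_kept <- profile[, retained_sets, drop = FALSE]
    n_hc <- min(cfg$enrichment$n_herb_clusters, nrow(prof_kept))
    n_sc <- min(cfg$enrichment$n_set_clusters, ncol(prof_kept))
    herb_cl <- cluster_profile(prof_kept, "herbs", n_hc)
    set_cl <- cluster_profile(prof_kept, "sets", n_sc)
    all_scored <- screened$merged[, c("herb_a", "herb_b")]
    keep <- screened$report$scores >= screened$report$cutoff
    cct <- cross_cluster_test(all_scored[keep, , drop = FALSE],
                              all_scored[!keep, , drop = FALSE],
                              herb_cl$assignment)
    write_feature_table(as.data.frame(profile), out_file("herb_profile.csv"))
    utils::write.table(
      data.frame(item = c(names(herb_cl$assignment), names(set_cl$assignment)),
                 axis = c(rep("herb", length(herb_cl$assignment)),
                          rep("set", length(set_cl$assignment))),
                 cluster = c(herb_cl$assignment, set_cl$assignment)),
      out_file("clusters.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
    write_report(list(retained_sets = retained_sets,
                      table = as.data.frame(cct$table),
                      p_value = cct$p_value),
                 out_file("complementarity.json"))
    cct
  }, error = function(e) stage_error("enrich", e))
  note_stage("enrich",
             out_file(c("herb_profile.csv", "clusters.tsv",
                        "complementarity.json")),
             list(cross_cluster_p = enr$p_value), t0)

  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_all, 3)
  write_report(manifest, out_file("manifest.json"))
  invisible(manifest)
}

# Stable hash of the normalized configuration.
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}
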