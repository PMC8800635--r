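# Seeded synthetic cohorts and knowledge bases with planted ground truth.
#
# The cohort emulates the shape of a hospital EMR prescription database
# (hundreds of herbs, ~23 herbs per prescription on average, a high-frequency
# core community); the knowledge base emulates herb->compound->target
# structure, a scale-free confidence-weighted protein network containing the
# disease genes, a single-rooted biological-process ontology, and symptom
# vocabularies. A set of planted "effective" pairs carries signal through
# every one of the five features, with strength controlled by a single
# signal_strength dial (0 = indistinguishable from background).

#' Cohort generation parameters
#'
#' Defaults emulate the shape of the motivating clinical cohort: 442 herbs
#' over 3697 prescriptions averaging 23.17 herbs each, with 18 core herbs and
#' a 234-term disease symptom set inside a larger symptom vocabulary.
#'
#' @param n_herbs Total number of herbs.
#' @param n_core Number of herbs in the co-prescribed core community.
#' @param n_prescriptions Number of prescription records.
#' @param mean_herbs_per_rx Mean herbs per prescription.
#' @param n_symptom_vocab Symptom vocabulary size.
#' @param n_disease_symptoms Number of disease-related symptoms (a subset of
#'   the vocabulary).
#' @param effective_pair_fraction Fraction of core pairs planted as
#'   "effective" (each herb joins at most two planted pairs, to avoid
#'   saturating its prescription margin).
#' @param signal_strength Non-negative real controlling how strongly planted
#'   pairs are co-prescribed (treatment-module block probability
#'   `min(0.95, 0.45 * signal_strength)`) and, in the knowledge base, how
#'   strongly their biology points at the disease. 0 means no signal.
#' @param core_weight Sampling-weight multiplier of core herbs relative to
#'   background herbs (core herbs are the high-frequency community).
#' @param freq_sd Log-normal standard deviation of per-herb frequency jitter
#'   (gives the heavy-tailed herb frequency distribution typical of EMR
#'   prescription data).
#' @param block_focus Factor in `[0, 1]` by which the inclusion probability
#'   of *other* core herbs is multiplied in prescriptions that carry a
#'   treatment-module block: a prescription written around a module largely
#'   displaces the rest of the core community, which is what gives
#'   non-planted core pairs their negative association (lift below 1) when
#'   planting is strong.
#' @param rng_seed Integer seed.
#' @return List of class `cohort_params`.
#' @export
cohort_params <- function(n_herbs = 442L, n_core = 18L,
                          n_prescriptions = 3697L, mean_herbs_per_rx = 23.17,
                          n_symptom_vocab = 800L, n_disease_symptoms = 234L,
                          effective_pair_fraction = 0.15,
                          signal_strength = 2, core_weight = 4,
                          freq_sd = 0.35, block_focus = 0.15, rng_seed = 1L) {
  p <- list(n_herbs = assert_count(n_herbs, "n_herbs"),
            n_core = assert_count(n_core, "n_core"),
            n_prescriptions = assert_count(n_prescriptions, "n_prescriptions"),
            mean_herbs_per_rx = assert_real(mean_herbs_per_rx,
                                            "mean_herbs_per_rx", lo = 1),
            n_symptom_vocab = assert_count(n_symptom_vocab, "n_symptom_vocab"),
            n_disease_symptoms = assert_count(n_disease_symptoms,
                                              "n_disease_symptoms"),
            effective_pair_fraction = assert_real(effective_pair_fraction,
                                                  "effective_pair_fraction",
                                                  0, 1),
            signal_strength = assert_real(signal_strength, "signal_strength",
                                          lo = 0),
            core_weight = assert_real(core_weight, "core_weight", lo = 0),
            freq_sd = assert_real(freq_sd, "freq_sd", lo = 0),
            block_focus = assert_real(block_focus, "block_focus", 0, 1),
            rng_seed = assert_count(rng_seed, "rng_seed", min = 0L))
  if (p$n_core > p$n_herbs)
    hp_stop("n_core (%d) exceeds n_herbs (%d)", p$n_core, p$n_herbs)
  if (p$mean_herbs_per_rx > p$n_herbs)
    hp_stop("mean_herbs_per_rx exceeds n_herbs")
  if (p$n_disease_symptoms > p$n_symptom_vocab)
    hp_stop("n_disease_symptoms exceeds n_symptom_vocab")
  structure(p, class = "cohort_params")
}

# Sample planted pairs among core herbs, each herb in at most `max_per_herb`
# pairs (marginal saturation would otherwise erode the pairs' lift).
sample_planted_pairs <- function(core, n_pairs, max_per_herb = 2L) {
  usage <- stats::setNames(integer(length(core)), core)
  chosen <- character(0)
  candidates <- all_pairs(core)
  candidates <- candidates[sample.int(nrow(candidates)), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    if (length(out) >= n_pairs) break
    a <- candidates$herb_a[i]; b <- candidates$herb_b[i]
    if (usage[a] < max_per_herb && usage[b] < max_per_herb) {
      out[[length(out) + 1L]] <- c(a, b)
      usage[a] <- usage[a] + 1L; usage[b] <- usage[b] + 1L
    }
  }
  if (length(out) == 0L)
    return(data.frame(herb_a = character(), herb_b = character(),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  df <- data.frame(herb_a = m[, 1L], herb_b = m[, 2L], stringsAsFactors = FALSE)
  df <- df[order(df$herb_a, df$herb_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Generate a synthetic prescription cohort with planted effective pairs
#'
#' Each prescription is drawn as: (i) with probability
#' `min(0.95, 0.45 * signal_strength)`, one "treatment module" block — a
#' planted pair sampled uniformly, both herbs included — and (ii) every herb
#' independently with its own inclusion probability, proportional to a
#' log-normally jittered weight (`core_weight` times larger for core herbs)
#' and scaled so prescriptions average `mean_herbs_per_rx` herbs. As module
#' prevalence grows, core herbs outside a module are displaced: their
#' inclusion probability is multiplied by the mean-field focus factor
#' `1 - pi * (1 - block_focus)` (with `pi` the block probability), applied
#' uniformly so that no prescription-mode mixture is introduced.
#' Independent inclusion makes every pair's lift exactly 1 in expectation at
#' zero signal (labels become pure sampling noise, uninformative about any
#' feature), while at high signal the blocks push planted pairs' lift above
#' 1 and the module focus pushes non-planted core pairs' lift and support
#' down — the structure that Apriori lift labeling detects. Record symptoms
#' over-represent the disease symptom set (drawn from it with probability
#' 0.7). At most one block is drawn per prescription.
#'
#' @param params A [cohort_params()].
#' @return List with `records` (prescription records as in
#'   [read_prescriptions()]) and `truth` (class `synthetic_truth`: planted
#'   pairs, core herbs, symptom vocabulary, disease symptoms, and provenance
#'   notes).
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$rng_seed)
  herbs <- sprintf("H%03d", seq_len(params$n_herbs))
  core <- herbs[seq_len(params$n_core)]
  vocab <- sprintf("S%03d", seq_len(params$n_symptom_vocab))
  disease_sym <- vocab[seq_len(params$n_disease_symptoms)]
  w <- exp(stats::rnorm(params$n_herbs, 0, params$freq_sd))
  w[seq_len(params$n_core)] <- w[seq_len(params$n_core)] * params$core_weight
  names(w) <- herbs

  n_pairs <- round(params$effective_pair_fraction * choose(params$n_core, 2))
  planted <- if (n_pairs > 0 && params$n_core >= 2) {
    sample_planted_pairs(core, n_pairs)
  } else {
    data.frame(herb_a = character(), herb_b = character(),
               stringsAsFactors = FALSE)
  }
  block_prob <- min(0.95, 0.45 * params$signal_strength)
  if (nrow(planted) == 0L) block_prob <- 0
  # independent per-herb inclusion probabilities, scaled to the target mean
  # prescription size and capped away from certainty
  p_incl <- pmin(0.9, w * params$mean_herbs_per_rx / sum(w))
  is_core <- herbs %in% core
  focus <- 1 - block_prob * (1 - params$block_focus)
  p_incl[is_core] <- p_incl[is_core] * focus

  records <- vector("list", params$n_prescriptions)
  for (i in seq_len(params$n_prescriptions)) {
    block <- character(0)
    if (block_prob > 0 && stats::runif(1) < block_prob) {
      j <- sample.int(nrow(planted), 1L)
      block <- c(planted$herb_a[j], planted$herb_b[j])
    }
    drawn <- herbs[stats::runif(params$n_herbs) < p_incl]
    drawn <- setdiff(drawn, block)
    if (length(block) + length(drawn) == 0L)
      drawn <- sample(herbs, 1L, prob = w)
    n_sym <- 1L + stats::rpois(1, 4)
    from_disease <- stats::runif(n_sym) < 0.7
    sym <- ifelse(from_disease,
                  sample(disease_sym, n_sym, replace = TRUE),
                  sample(vocab, n_sym, replace = TRUE))
    records[[i]] <- list(record_id = sprintf("RX%05d", i),
                         herbs = c(block, sort(drawn)),
                         symptoms = unique(sym))
  }
  truth <- structure(list(
    planted_pairs = planted,
    core_herbs = core,
    symptom_vocab = vocab,
    disease_symptoms = disease_sym,
    notes = sprintf(
      "planted %d pair(s) with treatment-module probability %.3f (signal %.2f)",
      nrow(planted), block_prob, params$signal_strength),
    params = params), class = "synthetic_truth")
  list(records = records, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: %d core herbs, %d planted pair(s)\n",
              length(x$core_herbs), nrow(x$planted_pairs)))
  cat(" ", x$notes, "\n")
  invisible(x)
}

#' Knowledge-base generation parameters
#'
#' @param compounds_per_herb Integer range (length 2) of compounds per herb.
#' @param targets_per_compound Integer range of targets contributed per
#'   compound.
#' @param ob_range Oral-bioavailability interval within `[0, 100]` from which
#'   compound OB values are drawn.
#' @param ppin_nodes Number of proteins in the interaction network.
#' @param pa_edges Edges added per node by the preferential-attachment model
#'   (scale-free topology, guaranteed connected).
#' @param n_disease_genes Number of disease genes (chosen among high-degree
#'   nodes so restart-walk mass is non-degenerate).
#' @param effective_pair_fraction,signal_strength As in [cohort_params()];
#'   the signal here controls how strongly planted herbs' targets attach near
#'   the disease genes, their symptom sets overlap the disease symptoms, and
#'   their compounds favour high OB.
#' @param n_compound_pool Size of the shared compound pool (herbs may share
#'   compounds, which the pair OB sum deduplicates).
#' @param n_terms Number of ontology terms.
#' @param n_gene_sets Number of gene sets in the generated collection.
#' @param rng_seed Integer seed.
#' @return List of class `knowledge_params`.
#' @export
knowledge_params <- function(compounds_per_herb = c(5L, 30L),
                             targets_per_compound = c(1L, 3L),
                             ob_range = c(5, 95), ppin_nodes = 1000L,
                             pa_edges = 2L, n_disease_genes = 100L,
                             effective_pair_fraction = 0.15,
                             signal_strength = 2,
                             n_compound_pool = 600L, n_terms = 140L,
                             n_gene_sets = 25L, rng_seed = 1L) {
  p <- list(
    compounds_per_herb = assert_range(compounds_per_herb,
                                      "compounds_per_herb", 1, Inf),
    targets_per_compound = assert_range(targets_per_compound,
                                        "targets_per_compound", 1, Inf),
    ob_range = assert_range(ob_range, "ob_range", 0, 100),
    ppin_nodes = assert_count(ppin_nodes, "ppin_nodes", min = 2L),
    pa_edges = assert_count(pa_edges, "pa_edges"),
    n_disease_genes = assert_count(n_disease_genes, "n_disease_genes"),
    effective_pair_fraction = assert_real(effective_pair_fraction,
                                          "effective_pair_fraction", 0, 1),
    signal_strength = assert_real(signal_strength, "signal_strength", lo = 0),
    n_compound_pool = assert_count(n_compound_pool, "n_compound_pool"),
    n_terms = assert_count(n_terms, "n_terms", min = 5L),
    n_gene_sets = assert_count(n_gene_sets, "n_gene_sets"),
    rng_seed = assert_count(rng_seed, "rng_seed", min = 0L))
  if (p$n_disease_genes > p$ppin_nodes)
    hp_stop("n_disease_genes exceeds ppin_nodes")
  structure(p, class = "knowledge_params")
}

# Random single-rooted biological_process DAG with is_a and sparse part_of
# edges, by levels.
generate_ontology <- function(n_terms) {
  ids <- sprintf("T%04d", seq_len(n_terms))
  # level sizes: root, then widening strata
  prop <- c(0.05, 0.15, 0.3, 0.5)
  sizes <- pmax(1L, round(prop * (n_terms - 1L)))
  sizes[length(sizes)] <- n_terms - 1L - sum(sizes[-length(sizes)])
  level <- rep(seq_along(sizes), sizes)
  terms <- data.frame(id = ids,
                      name = paste("synthetic process", seq_len(n_terms)),
                      namespace = "biological_process",
                      stringsAsFactors = FALSE)
  edges <- list()
  offset <- cumsum(c(1L, sizes))
  for (lv in seq_along(sizes)) {
    ids_lv <- ids[seq(offset[lv] + 1L, offset[lv] + sizes[lv])]
    parents_pool <- if (lv == 1L) ids[1L] else
      ids[seq(offset[lv - 1L] + 1L, offset[lv - 1L] + sizes[lv - 1L])]
    for (t in ids_lv) {
      p1 <- sample(parents_pool, 1L)
      edges[[length(edges) + 1L]] <- data.frame(child = t, parent = p1,
                                                relation = "is_a",
                                                stringsAsFactors = FALSE)
      if (length(parents_pool) > 1L && stats::runif(1) < 0.15) {
        p2 <- sample(setdiff(parents_pool, p1), 1L)
        edges[[length(edges) + 1L]] <- data.frame(child = t, parent = p2,
                                                  relation = "part_of",
                                                  stringsAsFactors = FALSE)
      }
    }
  }
  list(terms = terms, edges = do.call(rbind, edges),
       levels = stats::setNames(c(0L, level), ids))
}

# Descendant closure of `roots` under child -> parent edges.
descendants_of <- function(edges, roots) {
  out <- roots
  repeat {
    nxt <- setdiff(edges$child[edges$parent %in% out], out)
    if (length(nxt) == 0L) break
    out <- c(out, nxt)
  }
  out
}

#' Generate a synthetic knowledge base around a cohort's ground truth
#'
#' Builds: herb profiles (compounds with OB, protein targets, regulated
#' symptoms), a connected scale-free confidence-weighted protein network
#' whose high-degree nodes host the disease genes, a single-rooted
#' biological-process ontology with gene annotations, a disease context, and
#' a gene-set collection. Planted-pair herbs draw their targets from within
#' two hops of the disease genes with probability
#' `min(0.85, 0.3 * signal_strength)` (closer nodes preferred), their
#' symptoms from the disease symptom set with the same probability, and
#' their compounds with weight increasing in OB — so all five pair features
#' carry signal that vanishes at `signal_strength = 0`.
#'
#' @param params A [knowledge_params()].
#' @param herbs Character vector of herb names to profile.
#' @param truth The `synthetic_truth` from [generate_cohort()] (planted pairs
#'   must be drawn from `herbs`).
#' @return List with `profiles` (named list of [herb_profile()]), `net`
#'   ([ppin()]), `disease` ([disease_context()]), `dag` ([ontology_dag()]
#'   with annotations), and `gene_sets` (GMT-style named list).
#' @export
generate_knowledge_base <- function(params, herbs, truth) {
  stopifnot(inherits(params, "knowledge_params"))
  herbs <- as.character(herbs)
  if (length(herbs) == 0L) hp_stop("empty herb list")
  planted_herbs <- unique(c(truth$planted_pairs$herb_a,
                            truth$planted_pairs$herb_b))
  if (!all(planted_herbs %in% herbs))
    hp_stop("truth's planted pairs mention herbs outside the herb list")
  set.seed(params$rng_seed)
  s <- params$signal_strength
  q_bio <- min(0.85, 0.3 * s)

  ## protein network: preferential attachment, confidences in [0.9, 1]
  genes <- sprintf("G%04d", seq_len(params$ppin_nodes))
  g <- igraph::sample_pa(params$ppin_nodes, power = 1, m = params$pa_edges,
                         directed = FALSE)
  igraph::V(g)$name <- genes
  el <- igraph::as_edgelist(g)
  net <- ppin(data.frame(protein_a = el[, 1L], protein_b = el[, 2L],
                         confidence = stats::runif(nrow(el), 0.9, 1),
                         stringsAsFactors = FALSE))
  deg <- igraph::degree(g)
  hub_pool <- genes[order(-deg)][seq_len(max(params$n_disease_genes,
                                             ceiling(params$ppin_nodes / 5)))]
  disease_genes <- sort(sample(hub_pool, params$n_disease_genes))
  # proximity pool: disease genes and their 1- and 2-hop neighbours, with
  # sampling weight decaying in hop distance
  ego_names <- function(order) {
    unique(unlist(lapply(igraph::ego(g, order, disease_genes), names),
                  use.names = FALSE))
  }
  d1 <- setdiff(ego_names(1), disease_genes)
  d2 <- setdiff(ego_names(2), c(disease_genes, d1))
  prox_pool <- c(disease_genes, d1, d2)
  # steep decay in hop distance: in a scale-free network the 2-hop shell of
  # hub disease genes covers most of the graph, so only a sharply weighted
  # draw concentrates planted targets on the disease genes themselves
  prox_w <- c(rep(16, length(disease_genes)), rep(4, length(d1)),
              rep(1, length(d2)))

  ## ontology with a disease subtree
  onto <- generate_ontology(params$n_terms)
  root <- onto$terms$id[1L]
  level1 <- onto$edges$child[onto$edges$parent == root &
                               onto$edges$relation == "is_a"]
  anchor <- sample(level1, 1L)
  disease_terms <- descendants_of(onto$edges, anchor)
  non_root_terms <- setdiff(onto$terms$id, root)
  other_terms <- setdiff(non_root_terms, disease_terms)
  annotations <- lapply(stats::setNames(genes, genes), function(gene) {
    n_a <- sample(2:4, 1L)
    pool_bias <- gene %in% prox_pool && stats::runif(1) < 0.75
    pool <- if (pool_bias) disease_terms else non_root_terms
    unique(sample(pool, min(n_a, length(pool))))
  })
  dag <- ontology_dag(onto$terms, onto$edges, annotations)

  ## compound pool with fixed OB per compound
  compounds <- sprintf("C%05d", seq_len(params$n_compound_pool))
  ob <- stats::runif(params$n_compound_pool, params$ob_range[1L],
                     params$ob_range[2L])
  names(ob) <- compounds

  ## herb profiles
  profiles <- lapply(stats::setNames(herbs, herbs), function(h) {
    is_planted <- h %in% planted_herbs
    n_comp <- sample_range(params$compounds_per_herb, 1L)
    n_comp <- min(n_comp, params$n_compound_pool)
    comp_w <- if (is_planted) exp(s * ob / 100) else rep(1, length(ob))
    comp <- sample(compounds, n_comp, prob = comp_w)
    n_t <- sum(sample_range(params$targets_per_compound, n_comp))
    from_prox <- is_planted & stats::runif(n_t) < q_bio
    targets <- character(n_t)
    if (any(from_prox))
      targets[from_prox] <- sample(prox_pool, sum(from_prox),
                                   replace = TRUE, prob = prox_w)
    if (any(!from_prox))
      targets[!from_prox] <- sample(genes, sum(!from_prox), replace = TRUE)
    n_s <- sample(5:15, 1L)
    from_dis <- is_planted & stats::runif(n_s) < q_bio
    sym <- character(n_s)
    if (any(from_dis))
      sym[from_dis] <- sample(truth$disease_symptoms, sum(from_dis),
                              replace = TRUE)
    if (any(!from_dis))
      sym[!from_dis] <- sample(truth$symptom_vocab, sum(!from_dis),
                               replace = TRUE)
    herb_profile(h, data.frame(compound_id = comp, ob_percent = ob[comp],
                               stringsAsFactors = FALSE),
                 targets = unique(targets), symptoms = unique(sym))
  })

  ## gene-set collection; one fifth of the sets lean on the disease region
  n_linked <- max(1L, round(params$n_gene_sets / 5))
  gene_sets <- lapply(seq_len(params$n_gene_sets), function(i) {
    size <- sample(10:40, 1L)
    if (i <= n_linked) {
      n_p <- round(0.6 * size)
      unique(c(sample(prox_pool, min(n_p, length(prox_pool))),
               sample(genes, size - n_p)))
    } else {
      sample(genes, size)
    }
  })
  names(gene_sets) <- sprintf("PW%03d", seq_len(params$n_gene_sets))
  attr(gene_sets, "descriptions") <-
    stats::setNames(c(rep("disease-linked synthetic set", n_linked),
                      rep("background synthetic set",
                          params$n_gene_sets - n_linked)),
                    names(gene_sets))

  list(profiles = profiles, net = net,
       disease = disease_context(disease_genes, truth$disease_symptoms,
                                 label = "synthetic disease"),
       dag = dag, gene_sets = gene_sets)
}
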