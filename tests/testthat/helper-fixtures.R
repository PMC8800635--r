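# Shared fixtures and independent oracles, built in code at test time.

rec <- function(id, herbs, symptoms = character()) {
  list(record_id = as.character(id), herbs = herbs, symptoms = symptoms)
}

make_records <- function(herb_sets) {
  lapply(seq_along(herb_sets), function(i) rec(i, herb_sets[[i]]))
}

# Two-term ontology: root A, B is_a A.
two_term_dag <- function(annotations = list()) {
  ontology_dag(
    data.frame(id = c("A", "B"), name = c("root", "child"),
               namespace = "biological_process"),
    data.frame(child = "B", parent = "A", relation = "is_a"),
    annotations)
}

# Random single-rooted DAG in the biological_process namespace.
random_dag <- function(n_terms, seed, p_part_of = 0.3) {
  set.seed(seed)
  ids <- sprintf("R%03d", seq_len(n_terms))
  edges <- lapply(seq(2L, length.out = n_terms - 1L), function(i) {
    parent <- ids[sample.int(i - 1L, 1L)]
    rel <- if (stats::runif(1) < p_part_of) "part_of" else "is_a"
    df <- data.frame(child = ids[i], parent = parent, relation = rel,
                     stringsAsFactors = FALSE)
    if (i > 2L && stats::runif(1) < 0.3) {
      extra <- ids[sample.int(i - 1L, 1L)]
      if (extra != parent)
        df <- rbind(df, data.frame(child = ids[i], parent = extra,
                                   relation = "is_a"))
    }
    df
  })
  ontology_dag(data.frame(id = ids, name = ids,
                          namespace = "biological_process"),
               do.call(rbind, edges))
}

## Independent Wang-method oracle: S-values by exhaustive path enumeration.
oracle_svalues <- function(dag, model, t) {
  w_of <- function(rel) if (rel == "is_a") model$w_is_a else model$w_part_of
  s <- stats::setNames(1, t)
  # enumerate all upward paths depth-first, keeping the max product per node
  walk <- function(node, value) {
    e <- dag$edges[dag$edges$child == node, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      v <- value * w_of(e$relation[i])
      p <- e$parent[i]
      if (is.na(s[p]) || v > s[p]) s[p] <<- v
      walk(p, v)
    }
  }
  s <- c(s, stats::setNames(rep(NA_real_, nrow(dag$terms)), dag$terms$id))
  s <- s[!duplicated(names(s))]
  walk(t, 1)
  s[!is.na(s)]
}

oracle_wang_sim <- function(dag, model, t1, t2) {
  s1 <- oracle_svalues(dag, model, t1)
  s2 <- oracle_svalues(dag, model, t2)
  common <- intersect(names(s1), names(s2))
  if (length(common) == 0) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

## Independent RWR oracle: dense linear solve built from the edge list.
oracle_rwr <- function(edges, nodes, seeds, r) {
  n <- length(nodes)
  a <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    a[edges$protein_a[i], edges$protein_b[i]] <- edges$confidence[i]
    a[edges$protein_b[i], edges$protein_a[i]] <- edges$confidence[i]
  }
  keep <- reachable_from(a, seeds)
  a <- a[keep, keep, drop = FALSE]
  iso <- which(colSums(a) == 0)
  if (length(iso) > 0) a[cbind(iso, iso)] <- 1
  w <- sweep(a, 2L, colSums(a), "/")
  q <- stats::setNames(numeric(length(keep)), keep)
  q[intersect(seeds, keep)] <- 1 / length(intersect(seeds, keep))
  p <- solve(diag(length(keep)) - (1 - r) * w, r * q)
  out <- stats::setNames(numeric(n), nodes)
  out[keep] <- p
  out
}

reachable_from <- function(a, seeds) {
  nodes <- rownames(a)
  seen <- intersect(seeds, nodes)
  frontier <- seen
  while (length(frontier) > 0) {
    nxt <- setdiff(nodes[colSums(a[frontier, , drop = FALSE] != 0) > 0], seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

## Independent AUROC oracle: exhaustive concordant/tied pair counting.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

## Independent upper-tail hypergeometric oracle by enumeration.
oracle_hyper <- function(k, K, n, N) {
  j <- seq(k, min(K, n))
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

## Brute-force pair association recount.
oracle_pair_stats <- function(records, a, b) {
  n <- length(records)
  ina <- vapply(records, function(r) a %in% r$herbs, logical(1))
  inb <- vapply(records, function(r) b %in% r$herbs, logical(1))
  list(support_a = sum(ina) / n, support_b = sum(inb) / n,
       support_pair = sum(ina & inb) / n)
}

canonical_pair_df <- function(a, b) {
  swap <- a > b
  list(a = unname(ifelse(swap, b, a)), b = unname(ifelse(swap, a, b)))
}

## Compact synthetic study world (the acceptance-scale configuration),
## memoised across test files.
compact_cohort_params <- function(seed, signal) {
  cohort_params(n_herbs = 30L, n_core = 15L, n_prescriptions = 1000L,
                mean_herbs_per_rx = 8, n_symptom_vocab = 100L,
                n_disease_symptoms = 30L, effective_pair_fraction = 0.12,
                signal_strength = signal, rng_seed = seed)
}

compact_world <- local({
  cache <- new.env(parent = emptyenv())
  function(seed, signal, n_prescriptions = 1000L, n_herbs = 30L,
           n_core = 15L, ppin_nodes = 400L) {
    key <- paste(seed, signal, n_prescriptions, n_herbs, n_core, ppin_nodes,
                 sep = "_")
    got <- get0(key, envir = cache)
    if (!is.null(got)) return(got)
    cp <- cohort_params(n_herbs = n_herbs, n_core = n_core,
                        n_prescriptions = n_prescriptions,
                        mean_herbs_per_rx = 8, n_symptom_vocab = 100L,
                        n_disease_symptoms = 30L,
                        effective_pair_fraction = 0.12,
                        signal_strength = signal, rng_seed = seed)
    cohort <- generate_cohort(cp)
    kp <- knowledge_params(compounds_per_herb = c(5L, 12L),
                           ppin_nodes = ppin_nodes, n_disease_genes = 30L,
                           n_compound_pool = 200L,
                           effective_pair_fraction = 0.12,
                           signal_strength = signal,
                           rng_seed = seed + 1000L)
    kb <- generate_knowledge_base(kp, sprintf("H%03d", seq_len(n_herbs)),
                                  cohort$truth)
    out <- list(cohort = cohort, kb = kb)
    assign(key, out, envir = cache)
    out
  }
})

# Feature table + merged labels for a compact world.
compact_features <- local({
  cache <- new.env(parent = emptyenv())
  function(seed, signal) {
    key <- paste(seed, signal, sep = "_")
    got <- get0(key, envir = cache)
    if (!is.null(got)) return(got)
    w <- compact_world(seed, signal)
    ft <- suppressWarnings(featurize_pairs(
      w$cohort$truth$core_herbs, w$cohort$records, w$kb$profiles,
      w$kb$net, w$kb$dag, w$kb$disease))
    assoc <- mine_pair_associations(w$cohort$records,
                                    w$cohort$truth$core_herbs)
    lab <- suppressMessages(assign_labels(assoc))
    merged <- merge(ft, lab[, c("herb_a", "herb_b", "label")],
                    by = c("herb_a", "herb_b"))
    merged <- merged[order(merged$herb_a, merged$herb_b), ]
    rownames(merged) <- NULL
    pk <- paste(w$cohort$truth$planted_pairs$herb_a,
                w$cohort$truth$planted_pairs$herb_b)
    merged$planted <- paste(merged$herb_a, merged$herb_b) %in% pk
    out <- list(table = merged, truth = w$cohort$truth)
    assign(key, out, envir = cache)
    out
  }
})
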