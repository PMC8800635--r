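# Wang-method ontology term semantic similarity and gene-set GoSim scores.

#' Semantic contribution model for Wang-method term similarity
#'
#' Edge contribution weights per relation type, and the annotation namespace
#' used. The defaults (0.8 for `is_a`, 0.6 for `part_of`) are the standard
#' Wang-method constants.
#'
#' @param w_is_a Contribution weight of `is_a` edges, in (0, 1).
#' @param w_part_of Contribution weight of `part_of` edges, in (0, 1).
#' @param namespace Ontology namespace used (default `"biological_process"`).
#' @return List of class `semantic_model`.
#' @export
semantic_model <- function(w_is_a = 0.8, w_part_of = 0.6,
                           namespace = "biological_process") {
  for (w in c(w_is_a, w_part_of))
    if (!is.numeric(w) || w <= 0 || w >= 1)
      hp_stop("semantic edge weights must lie in (0, 1)")
  structure(list(w_is_a = w_is_a, w_part_of = w_part_of,
                 namespace = namespace),
            class = "semantic_model")
}

# Mutable cache of per-term S-value vectors for one (dag, model) pair.
wang_cache <- function(dag, model) {
  ns_terms <- dag$terms$id[dag$terms$namespace == model$namespace]
  e <- dag$edges[dag$edges$child %in% ns_terms &
                   dag$edges$parent %in% ns_terms, , drop = FALSE]
  w <- ifelse(e$relation == "is_a", model$w_is_a, model$w_part_of)
  parents <- split(data.frame(parent = e$parent, w = w,
                              stringsAsFactors = FALSE), e$child)
  env <- new.env(parent = emptyenv())
  env$terms <- ns_terms
  env$parents <- parents
  env$sv <- new.env(parent = emptyenv())
  env
}

# S-values of term `t`: named vector over t and its ancestors.
# S_t(t) = 1; S_t(a) = max over edges (c -> a) with c in the ancestor closure
# of w(c -> a) * S_t(c), computed in topological order (children first).
wang_svalues <- function(cache, t) {
  memo <- get0(t, envir = cache$sv)
  if (!is.null(memo)) return(memo)
  # ancestor closure by upward BFS
  closure <- t
  frontier <- t
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(lapply(cache$parents[frontier],
                                function(df) df$parent), use.names = FALSE))
    nxt <- setdiff(nxt, closure)
    closure <- c(closure, nxt)
    frontier <- nxt
  }
  # induced child -> parent edges within the closure
  s <- stats::setNames(rep(-Inf, length(closure)), closure)
  s[t] <- 1
  # Kahn topological order: process a node once all its in-closure children
  # are done
  kids <- lapply(closure, function(a) {
    ch <- names(cache$parents)[vapply(cache$parents, function(df)
      a %in% df$parent, logical(1))]
    intersect(ch, closure)
  })
  names(kids) <- closure
  remaining <- setdiff(closure, t)
  done <- t
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(a)
      all(kids[[a]] %in% done), logical(1))]
    if (length(ready) == 0L) hp_stop("ontology is not acyclic")  # defensive
    for (a in ready) {
      best <- -Inf
      for (c in kids[[a]]) {
        df <- cache$parents[[c]]
        wv <- df$w[df$parent == a]
        best <- max(best, max(wv) * s[c])
      }
      s[a] <- best
    }
    done <- c(done, ready)
    remaining <- setdiff(remaining, ready)
  }
  assign(t, s, envir = cache$sv)
  s
}

#' Wang-method semantic similarity between two ontology terms
#'
#' Computes S-value vectors for both terms over their ancestor closures and
#' returns `sum over common ancestors of (S1 + S2) / (SV(t1) + SV(t2))`, which
#' is 1 for identical terms and 0 for terms with no common ancestor.
#'
#' @param dag An [ontology_dag()].
#' @param model A [semantic_model()].
#' @param t1,t2 Term ids (must exist and share the model namespace).
#' @return Similarity in `[0, 1]`.
#' @export
wang_term_similarity <- function(dag, model = semantic_model(), t1, t2) {
  terms <- dag$terms
  for (t in c(t1, t2))
    if (!t %in% terms$id) hp_stop("unknown ontology term '%s'", t)
  ns <- terms$namespace[match(c(t1, t2), terms$id)]
  if (ns[1] != ns[2])
    hp_stop("terms '%s' and '%s' are in different namespaces", t1, t2)
  if (ns[1] != model$namespace)
    hp_stop("terms are in namespace '%s' but the model uses '%s'",
            ns[1], model$namespace)
  cache <- wang_cache(dag, model)
  wang_sim_cached(cache, t1, t2)
}

wang_sim_cached <- function(cache, t1, t2) {
  s1 <- wang_svalues(cache, t1)
  s2 <- wang_svalues(cache, t2)
  common <- intersect(names(s1), names(s2))
  if (length(common) == 0L) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

#' Pairwise Wang similarity matrix for a set of terms
#'
#' @param dag An [ontology_dag()].
#' @param model A [semantic_model()].
#' @param terms Character vector of term ids in the model namespace.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
term_similarity_matrix <- function(dag, model = semantic_model(), terms) {
  terms <- unique(terms)
  cache <- wang_cache(dag, model)
  n <- length(terms)
  m <- matrix(1, n, n, dimnames = list(terms, terms))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        m[i, j] <- m[j, i] <- wang_sim_cached(cache, terms[i], terms[j])
      }
    }
  }
  m
}

# Annotation term sets restricted to the model namespace.
namespace_annotations <- function(dag, model, genes) {
  ns_terms <- dag$terms$id[dag$terms$namespace == model$namespace]
  ann <- lapply(dag$annotations[intersect(genes, names(dag$annotations))],
                function(x) intersect(x, ns_terms))
  ann[lengths(ann) > 0L]
}

# Best-match average of a similarity matrix (rows vs columns).
bma <- function(m) {
  (mean(apply(m, 1L, max)) + mean(apply(m, 2L, max))) / 2
}

#' Gene-by-gene semantic similarity matrix
#'
#' Gene-gene similarity is the best-match average (BMA) over the two genes'
#' annotation term sets under Wang-method term similarity.
#'
#' @param dag An [ontology_dag()] with annotations.
#' @param model A [semantic_model()].
#' @param genes_a,genes_b Character vectors of gene symbols. Genes without
#'   annotation in the model namespace are dropped with a warning.
#' @return Numeric matrix (annotated `genes_a` by annotated `genes_b`).
#' @export
gene_similarity_matrix <- function(dag, model = semantic_model(),
                                   genes_a, genes_b) {
  ann_a <- namespace_annotations(dag, model, unique(genes_a))
  ann_b <- namespace_annotations(dag, model, unique(genes_b))
  dropped <- length(unique(genes_a)) - length(ann_a) +
    length(unique(genes_b)) - length(ann_b)
  if (dropped > 0L)
    warning(sprintf("skipping %d gene(s) without %s annotation", dropped,
                    model$namespace), call. = FALSE)
  if (length(ann_a) == 0L || length(ann_b) == 0L)
    hp_stop("gene-set semantic similarity undefined: a set has no annotated genes")
  terms <- unique(c(unlist(ann_a, use.names = FALSE),
                    unlist(ann_b, use.names = FALSE)))
  tm <- term_similarity_matrix(dag, model, terms)
  out <- matrix(0, length(ann_a), length(ann_b),
                dimnames = list(names(ann_a), names(ann_b)))
  for (i in seq_along(ann_a)) {
    for (j in seq_along(ann_b)) {
      out[i, j] <- bma(tm[ann_a[[i]], ann_b[[j]], drop = FALSE])
    }
  }
  out
}

#' Set-level GoSim score between herb-pair targets and disease genes
#'
#' Best-match-average aggregation at both levels: gene-gene similarity is the
#' BMA over the genes' term sets, and the set-set score is the BMA over
#' annotated gene pairs (mean of per-gene best matches, averaged over both
#' directions).
#'
#' @param dag An [ontology_dag()] with annotations.
#' @param model A [semantic_model()].
#' @param pair_targets Character vector: union of the pair's targets.
#' @param disease_genes Character vector of disease genes.
#' @param gene_sim Optional precomputed [gene_similarity_matrix()] covering
#'   the two sets; rows/columns are subset as needed.
#' @return GoSim score in `[0, 1]`.
#' @export
gosim_pair_score <- function(dag, model = semantic_model(), pair_targets,
                             disease_genes, gene_sim = NULL) {
  if (is.null(gene_sim)) {
    gene_sim <- gene_similarity_matrix(dag, model, pair_targets, disease_genes)
  } else {
    ga <- intersect(unique(pair_targets), rownames(gene_sim))
    gb <- intersect(unique(disease_genes), colnames(gene_sim))
    if (length(ga) == 0L || length(gb) == 0L)
      hp_stop("gene-set semantic similarity undefined: a set has no annotated genes")
    gene_sim <- gene_sim[ga, gb, drop = FALSE]
  }
  bma(gene_sim)
}
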