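# Hypergeometric over-representation analysis, quartile filtering,
# hierarchical clustering of the herb-by-pathway profile, and the
# cross-cluster complementarity test.

#' Upper-tail hypergeometric over-representation p-value
#'
#' Probability of observing at least `k` annotated genes in a query of size
#' `n` drawn from a universe of `N` genes of which `K` belong to the set.
#'
#' @param k Overlap count.
#' @param K Set size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return `P(X >= k)` under the hypergeometric null.
#' @export
hypergeom_test <- function(k, K, n, N) {
  for (v in list(k = k, K = K, n = n, N = N))
    if (!is.numeric(v) || v < 0 || v != round(v))
      hp_stop("hypergeometric arguments must be non-negative integers")
  if (k > min(K, n) || K > N || n > N)
    hp_stop("invalid hypergeometric configuration (k <= min(K, n) <= N required)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, order-preserving, in `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    hp_stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis of a target set against a gene-set collection
#'
#' Query and sets are intersected with the universe first (items outside it
#' are dropped with a warning); one hypergeometric record per set, with BH
#' q-values across the collection.
#'
#' @param targets Character vector: the query gene set.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector: the gene universe.
#' @param q_cutoff Significance cut on the q-value (default 0.05).
#' @return Data frame with columns `set_id`, `k`, `K`, `n`, `N`, `p_value`,
#'   `q_value`, `significant`, ordered by p-value then set id.
#' @export
enrich_targets <- function(targets, collection, universe, q_cutoff = 0.05) {
  universe <- unique(as.character(universe))
  n_outside <- sum(!unique(targets) %in% universe)
  if (n_outside > 0L)
    warning(sprintf("dropping %d query gene(s) outside the universe", n_outside),
            call. = FALSE)
  query <- intersect(unique(targets), universe)
  if (length(query) == 0L)
    hp_stop("enrichment undefined: query is empty after universe intersection")
  sets <- lapply(collection, function(s) intersect(unique(s), universe))
  nn <- length(universe)
  rows <- lapply(names(sets), function(id) {
    kk <- length(intersect(query, sets[[id]]))
    data.frame(set_id = id, k = kk, K = length(sets[[id]]),
               n = length(query), N = nn,
               p_value = hypergeom_test(kk, length(sets[[id]]),
                                        length(query), nn),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < q_cutoff
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Herb-by-gene-set profile of enriched-gene counts
#'
#' Entry (herb, set) is that herb's overlap count `k` with the set, within
#' the universe — the feature profile that the quartile filter and the
#' hierarchical clustering operate on.
#'
#' @param herb_targets Named list: herb -> character vector of targets.
#' @param collection Named list of gene sets.
#' @param universe Gene universe.
#' @return Integer matrix, herbs by sets.
#' @export
build_herb_profile <- function(herb_targets, collection, universe) {
  universe <- unique(as.character(universe))
  herbs <- sort(names(herb_targets))
  sets <- names(collection)
  m <- matrix(0L, length(herbs), length(sets), dimnames = list(herbs, sets))
  for (h in herbs) {
    q <- intersect(unique(herb_targets[[h]]), universe)
    for (s in sets)
      m[h, s] <- length(intersect(q, intersect(collection[[s]], universe)))
  }
  m
}

#' Quartile filter on the herb-by-set profile
#'
#' A set is retained if, for at least one herb, its enriched-gene count
#' strictly exceeds the chosen quartile (default the upper quartile Q3,
#' linear-interpolation convention) of that herb's nonzero counts.
#'
#' @param profile Matrix from [build_herb_profile()].
#' @param probs Quartile used (default 0.75; set 0.25 for Q1).
#' @return Character vector of retained set ids (column order preserved).
#' @export
quartile_filter <- function(profile, probs = 0.75) {
  if (length(profile) == 0L) hp_stop("empty profile")
  probs <- assert_real(probs, "probs", 0, 1)
  keep <- rep(FALSE, ncol(profile))
  for (i in seq_len(nrow(profile))) {
    kv <- profile[i, ]
    nz <- kv[kv > 0]
    if (length(nz) == 0L) next
    q <- stats::quantile(nz, probs, type = 7, names = FALSE)
    keep <- keep | (kv > q)
  }
  colnames(profile)[keep]
}

#' Hierarchical clustering of the herb-by-set profile
#'
#' Agglomerative clustering (default Ward linkage on Euclidean distances of
#' log1p-transformed counts), cut at `n_clusters`. Equal merge heights are
#' resolved by `stats::hclust`'s deterministic lowest-index merge order.
#'
#' @param profile Matrix from [build_herb_profile()].
#' @param axis `"herbs"` (cluster rows) or `"sets"` (cluster columns).
#' @param n_clusters Number of clusters requested.
#' @param linkage `stats::hclust` method (default `"ward.D2"`).
#' @param transform Count transform applied before distances (default
#'   `log1p`).
#' @return List with `assignment` (named integer vector) and `tree`
#'   (`hclust` object).
#' @export
cluster_profile <- function(profile, axis = c("herbs", "sets"),
                            n_clusters, linkage = "ward.D2",
                            transform = log1p) {
  axis <- match.arg(axis)
  x <- if (axis == "herbs") profile else t(profile)
  n_clusters <- assert_count(n_clusters, "n_clusters")
  if (n_clusters > nrow(x))
    hp_stop("n_clusters = %d exceeds the %d items on the '%s' axis",
            n_clusters, nrow(x), axis)
  tree <- stats::hclust(stats::dist(transform(x)), method = linkage)
  assignment <- stats::cutree(tree, k = n_clusters)
  list(assignment = assignment, tree = tree)
}

#' Cross-cluster complementarity test for screened pairs
#'
#' Builds the 2x2 table (rows: retained vs excluded pairs; columns:
#' cross-cluster vs same-cluster) and tests enrichment of cross-cluster pairs
#' among the retained pairs with a one-sided Fisher exact (hypergeometric)
#' test. Degenerate margins give p = 1 with a warning.
#'
#' @param retained_pairs,excluded_pairs Data frames with `herb_a`, `herb_b`.
#' @param herb_clusters Named integer vector (herb -> cluster id); every herb
#'   in the pairs must be clustered.
#' @return List with `table` (2x2 matrix) and `p_value`.
#' @export
cross_cluster_test <- function(retained_pairs, excluded_pairs, herb_clusters) {
  herbs <- unique(c(retained_pairs$herb_a, retained_pairs$herb_b,
                    excluded_pairs$herb_a, excluded_pairs$herb_b))
  missing <- setdiff(herbs, names(herb_clusters))
  if (length(missing) > 0L)
    hp_stop("unclustered herb(s): %s", paste(utils::head(missing, 5),
                                             collapse = ", "))
  count_cross <- function(pairs) {
    if (nrow(pairs) == 0L) return(c(cross = 0L, same = 0L))
    cross <- herb_clusters[pairs$herb_a] != herb_clusters[pairs$herb_b]
    c(cross = sum(cross), same = sum(!cross))
  }
  tab <- rbind(retained = count_cross(retained_pairs),
               excluded = count_cross(excluded_pairs))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    warning("degenerate margins in cross-cluster table; p = 1", call. = FALSE)
    return(list(table = tab, p_value = 1))
  }
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(table = tab, p_value = p)
}
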