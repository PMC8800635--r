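# Herb co-occurrence network and degree-coefficient core extraction.

#' Binary herb-by-prescription incidence matrix
#'
#' Rows are herbs, columns are prescription records; entry 1 iff the herb
#' appears in the record. Row sums therefore equal per-herb prescription
#' frequencies. Herbs requested but absent from the records yield zero rows
#' with a warning.
#'
#' @param records List of prescription records (see [read_prescriptions()]).
#' @param herbs Optional character vector of herbs to use as rows; defaults to
#'   all herbs seen, sorted.
#' @return A sparse `dgCMatrix` with herb row names and record id column names.
#' @export
incidence_matrix <- function(records, herbs = NULL) {
  if (length(records) == 0L) hp_stop("no prescription records supplied")
  seen <- sort(unique(unlist(lapply(records, `[[`, "herbs"), use.names = FALSE)))
  if (is.null(herbs)) {
    herbs <- seen
  } else {
    herbs <- as.character(herbs)
    missing <- setdiff(herbs, seen)
    if (length(missing) > 0L)
      warning(sprintf("%d herb(s) absent from records (zero rows): %s",
                      length(missing),
                      paste(utils::head(missing, 5), collapse = ", ")),
              call. = FALSE)
  }
  rx_ids <- vapply(records, `[[`, character(1), "record_id")
  hsets <- lapply(records, function(r) intersect(r$herbs, herbs))
  j <- rep(seq_along(records), lengths(hsets))
  i <- match(unlist(hsets, use.names = FALSE), herbs)
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(herbs), length(records)),
                            dimnames = list(herbs, rx_ids))
  methods::as(m, "CsparseMatrix")
}

#' Build the weighted herb co-occurrence network
#'
#' Nodes are herbs; the weight of edge (u, v) is the exact number of
#' prescriptions containing both u and v. Equals the inner product of the two
#' herbs' incidence rows.
#'
#' @param records List of prescription records.
#' @return Object of class `herb_network`: list with `nodes` (character) and
#'   `edges` (data frame `herb_a`, `herb_b`, `weight`, lexicographic pairs).
#' @export
build_cooccurrence_network <- function(records) {
  if (length(records) == 0L) hp_stop("no prescription records supplied")
  m <- incidence_matrix(records)
  w <- Matrix::tcrossprod(m)
  w <- methods::as(w, "TsparseMatrix")
  keep <- w@i < w@j  # strict upper triangle: unordered pairs, no self-edges
  herbs <- rownames(m)
  edges <- data.frame(herb_a = herbs[w@i[keep] + 1L],
                      herb_b = herbs[w@j[keep] + 1L],
                      weight = as.integer(w@x[keep]),
                      stringsAsFactors = FALSE)
  edges <- edges[edges$weight > 0L, , drop = FALSE]
  edges <- edges[order(edges$herb_a, edges$herb_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = herbs, edges = edges), class = "herb_network")
}

#' @export
print.herb_network <- function(x, ...) {
  cat(sprintf("Herb co-occurrence network: %d herbs, %d weighted edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Weighted degree of each of `nodes` on the subnetwork induced by `nodes`.
weighted_degree <- function(edges, nodes) {
  s <- stats::setNames(numeric(length(nodes)), nodes)
  keep <- edges$herb_a %in% nodes & edges$herb_b %in% nodes
  e <- edges[keep, , drop = FALSE]
  if (nrow(e) > 0L) {
    ta <- tapply(e$weight, e$herb_a, sum)
    tb <- tapply(e$weight, e$herb_b, sum)
    s[names(ta)] <- s[names(ta)] + ta
    s[names(tb)] <- s[names(tb)] + tb
  }
  s
}

#' Extract core herbs by iterated degree-coefficient thresholding
#'
#' Computes each herb's weighted degree `s(v)` (sum of incident
#' co-occurrence weights) and retains herbs with
#' `s(v) >= lambda_degree * mean(s)`; the induced subnetwork is rebuilt on
#' the survivors and the rule is repeated up to `max_iterations` times,
#' stopping at a fixed point or — if a pass would retain fewer than
#' `min_core_size` herbs — returning the previous herb set. The default
#' degree coefficient is 1.9.
#'
#' The default is a single thresholding pass (`max_iterations = 1`): the
#' retained set `{v : s(v) >= lambda_degree * mean(s)}` is then nested in
#' the coefficient, so the core size is non-increasing in `lambda_degree`
#' whenever the pass retains anything. Deeper refinement is available by
#' raising `max_iterations`; with `threshold = "fixed"` later passes keep
#' the original network's threshold (converging to a weighted degree-core),
#' while `threshold = "adaptive"` recomputes the mean on the current
#' subnetwork at every pass (the most aggressive variant). Multi-pass
#' refinement prunes cascades of herbs whose co-occurrence was carried by
#' removed neighbours, at the cost of the monotonicity guarantee.
#'
#' @param net A `herb_network` from [build_cooccurrence_network()].
#' @param lambda_degree Positive degree coefficient (default 1.9).
#' @param min_core_size Smallest admissible core (default 1, so the fallback
#'   to the previous set only fires when the rule would empty the network —
#'   e.g. a star network at the default coefficient correctly reduces to its
#'   hub, while a uniform complete graph returns all of its nodes).
#' @param max_iterations Number of refinement passes (default 1).
#' @param threshold `"fixed"` (default) or `"adaptive"`, see Details; only
#'   relevant when `max_iterations > 1`.
#' @return List with `core` (herbs ordered by final weighted degree,
#'   descending, ties broken by name) and `log` (one row per pass:
#'   node count, mean degree, threshold, retained count).
#' @export
extract_core <- function(net, lambda_degree = 1.9, min_core_size = 1L,
                         max_iterations = 1L,
                         threshold = c("fixed", "adaptive")) {
  lambda_degree <- assert_real(lambda_degree, "lambda_degree", lo = 0)
  if (lambda_degree <= 0) hp_stop("'lambda_degree' must be > 0")
  min_core_size <- assert_count(min_core_size, "min_core_size")
  max_iterations <- assert_count(max_iterations, "max_iterations")
  threshold <- match.arg(threshold)
  if (length(net$nodes) == 0L) hp_stop("empty network")
  nodes <- sort(net$nodes)
  log <- list()
  thr <- lambda_degree * mean(weighted_degree(net$edges, nodes))
  final_s <- weighted_degree(net$edges, nodes)
  for (it in seq_len(max_iterations)) {
    s <- weighted_degree(net$edges, nodes)
    if (threshold == "adaptive") thr <- lambda_degree * mean(s)
    retained <- names(s)[s >= thr]
    log[[it]] <- data.frame(iteration = it, n_nodes = length(nodes),
                            mean_degree = mean(s), threshold = thr,
                            n_retained = length(retained))
    if (length(retained) < min_core_size) {
      final_s <- s           # rule would undershoot: keep previous node set
      break
    }
    final_s <- weighted_degree(net$edges, retained)
    if (setequal(retained, nodes)) { nodes <- retained; break }
    nodes <- sort(retained)
  }
  ord <- order(-final_s[nodes], nodes)
  list(core = nodes[ord], log = do.call(rbind, log))
}
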