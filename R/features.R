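# The five pair-level effectiveness features and the pair featurizer.

#' Manhattan distance between two herbs' prescription incidence rows
#'
#' Equals the number of prescriptions containing exactly one of the two herbs:
#' low values indicate herbs that are prescribed together (or both absent)
#' rather than interchangeably.
#'
#' @param m Incidence matrix from [incidence_matrix()].
#' @param u,v Herb names (must be rows of `m`).
#' @return Non-negative integer.
#' @export
manhattan_distance <- function(m, u, v) {
  for (h in c(u, v))
    if (!h %in% rownames(m)) hp_stop("herb '%s' is not a row of the incidence matrix", h)
  as.integer(sum(abs(m[u, ] - m[v, ])))
}

#' Jaccard similarity between a pair's symptom set and the disease symptoms
#'
#' The pair symptom set is the union of the two herbs' regulated symptom
#' sets; the score is `|S_pair intersect S_disease| / |S_pair union
#' S_disease|`, or 0 when the pair set is empty.
#'
#' @param profile_a,profile_b [herb_profile()] objects.
#' @param disease A [disease_context()] with non-empty symptoms.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard_symptom_similarity <- function(profile_a, profile_b, disease) {
  if (length(disease$disease_symptoms) == 0L)
    hp_stop("disease symptom set is empty")
  s_pair <- union(profile_a$symptoms, profile_b$symptoms)
  if (length(s_pair) == 0L) return(0)
  length(intersect(s_pair, disease$disease_symptoms)) /
    length(union(s_pair, disease$disease_symptoms))
}

#' Summed oral bioavailability over a pair's compounds
#'
#' Sums OB percentages over the deduplicated union of the two herbs'
#' compounds; a compound shared by both herbs counts once.
#'
#' @param profile_a,profile_b [herb_profile()] objects.
#' @return Non-negative real (percent units summed).
#' @export
ob_sum <- function(profile_a, profile_b) {
  comp <- rbind(profile_a$compounds, profile_b$compounds)
  if (nrow(comp) == 0L) return(0)
  comp <- comp[!duplicated(comp$compound_id), , drop = FALSE]
  sum(comp$ob_percent)
}

#' Compute the five effectiveness features for all core herb pairs
#'
#' For each of the C(n, 2) unordered pairs of `core_herbs` (lexicographic
#' order) computes: Manhattan incidence distance, Jaccard symptom similarity
#' to the disease, summed compound OB, RWR proximity of the pair's targets to
#' the disease genes, and Wang-method GO biological-process semantic
#' similarity (GoSim) between targets and disease genes. RWR propagation and
#' the gene similarity matrix are computed once and shared across pairs.
#'
#' @param core_herbs Character vector of herbs (must appear in `profiles`).
#' @param records Prescription records.
#' @param profiles Named list of [herb_profile()] objects.
#' @param net A [ppin()].
#' @param dag An [ontology_dag()] with annotations.
#' @param disease A [disease_context()].
#' @param rwr An [rwr_params()].
#' @param model A [semantic_model()].
#' @return Data frame with columns `herb_a`, `herb_b`, `manhattan`, `jaccard`,
#'   `ob_sum`, `rwr`, `gosim`.
#' @export
featurize_pairs <- function(core_herbs, records, profiles, net, dag, disease,
                            rwr = rwr_params(), model = semantic_model()) {
  core_herbs <- sort(unique(core_herbs))
  missing <- setdiff(core_herbs, names(profiles))
  if (length(missing) > 0L)
    hp_stop("no profile for herb(s): %s", paste(utils::head(missing, 5),
                                                collapse = ", "))
  if (length(core_herbs) < 2L) hp_stop("need at least two core herbs")
  pairs <- all_pairs(core_herbs)
  m <- incidence_matrix(records, core_herbs)
  propagated <- rwr_propagate(net, disease$disease_genes, rwr)
  all_targets <- unique(unlist(lapply(profiles[core_herbs], `[[`, "targets"),
                               use.names = FALSE))
  gene_sim <- gene_similarity_matrix(dag, model, all_targets,
                                     disease$disease_genes)
  feat <- function(i) {
    a <- pairs$herb_a[i]; b <- pairs$herb_b[i]
    tryCatch({
      pa <- profiles[[a]]; pb <- profiles[[b]]
      data.frame(
        herb_a = a, herb_b = b,
        manhattan = manhattan_distance(m, a, b),
        jaccard = jaccard_symptom_similarity(pa, pb, disease),
        ob_sum = ob_sum(pa, pb),
        rwr = rwr_pair_score(net, disease, pa, pb, rwr, propagated = propagated),
        gosim = gosim_pair_score(dag, model, union(pa$targets, pb$targets),
                                 disease$disease_genes, gene_sim = gene_sim),
        stringsAsFactors = FALSE)
    }, error = function(e)
      hp_stop("featurize failed for pair (%s, %s): %s", a, b,
              conditionMessage(e)))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), feat))
  rownames(out) <- NULL
  out
}
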