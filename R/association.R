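# Pair-level association rule mining (2-itemset Apriori) and lift labeling.

#' Labeling parameters for Apriori-lift supervision
#'
#' @param min_support Minimum pair support, in `[0, 1]` (default 0.05).
#' @param lift_threshold Lift cut for the positive label (default 1.0).
#' @return List of class `labeling_params`.
#' @export
labeling_params <- function(min_support = 0.05, lift_threshold = 1.0) {
  structure(list(min_support = assert_real(min_support, "min_support", 0, 1),
                 lift_threshold = assert_real(lift_threshold, "lift_threshold",
                                              lo = 0)),
            class = "labeling_params")
}

#' Mine pair-level association statistics from prescriptions
#'
#' Computes exact supports, directional confidences, and lift for every
#' unordered pair of `core_herbs` over the prescription transactions. Because
#' the unit of study is the pair, supports are obtained by direct 2-itemset
#' counting (equivalent to the corresponding Apriori level). Pairs below
#' `min_support` are reported but flagged; a pair involving a herb that never
#' appears has undefined (NA) lift and is flagged for exclusion from
#' labeling.
#'
#' @param records Prescription records.
#' @param core_herbs Character vector of herbs forming the candidate pairs.
#' @param params A [labeling_params()].
#' @return Data frame (lexicographic pair order) with columns `herb_a`,
#'   `herb_b`, `support_a`, `support_b`, `support_pair`,
#'   `confidence_a_to_b`, `confidence_b_to_a`, `lift`, `below_support`,
#'   `lift_defined`.
#' @export
mine_pair_associations <- function(records, core_herbs,
                                   params = labeling_params()) {
  if (length(records) == 0L) hp_stop("no prescription records supplied")
  core_herbs <- sort(unique(core_herbs))
  n <- length(records)
  m <- suppressWarnings(incidence_matrix(records, core_herbs))
  counts <- as.matrix(Matrix::tcrossprod(m))
  freq <- Matrix::rowSums(m)
  pairs <- all_pairs(core_herbs)
  sa <- freq[pairs$herb_a] / n
  sb <- freq[pairs$herb_b] / n
  sp <- counts[cbind(pairs$herb_a, pairs$herb_b)] / n
  lift <- ifelse(sa > 0 & sb > 0, sp / (sa * sb), NA_real_)
  out <- data.frame(
    pairs,
    support_a = as.numeric(sa), support_b = as.numeric(sb),
    support_pair = as.numeric(sp),
    confidence_a_to_b = ifelse(sa > 0, sp / sa, NA_real_),
    confidence_b_to_a = ifelse(sb > 0, sp / sb, NA_real_),
    lift = as.numeric(lift),
    below_support = sp < params$min_support,
    lift_defined = !is.na(lift),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Convert mined lift into the supervised pair label
#'
#' A pair is labeled 1 iff its lift is at least `lift_threshold` *and* its
#' pair support is at least `min_support`; otherwise 0. Pairs with undefined
#' lift (a herb never prescribed) are excluded.
#'
#' @param assoc Output of [mine_pair_associations()].
#' @param params A [labeling_params()].
#' @return `assoc` restricted to lift-defined pairs, with an integer `label`
#'   column appended; class counts are reported via `message()`.
#' @export
assign_labels <- function(assoc, params = labeling_params()) {
  excluded <- !assoc$lift_defined
  if (any(excluded))
    message(sprintf("assign_labels: excluding %d pair(s) with undefined lift",
                    sum(excluded)))
  out <- assoc[!excluded, , drop = FALSE]
  out$label <- as.integer(out$lift >= params$lift_threshold &
                            out$support_pair >= params$min_support)
  message(sprintf("assign_labels: %d positive / %d negative pair(s)",
                  sum(out$label == 1L), sum(out$label == 0L)))
  rownames(out) <- NULL
  out
}
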