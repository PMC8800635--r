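# Readers and writers for every external format the pipeline touches.
# All writers emit deterministically ordered (lexicographic) output so that
# identical objects produce byte-identical files.

## ---- prescriptions ---------------------------------------------------------

#' Read prescription records
#'
#' Reads a prescription file in either JSONL dialect (one object per line with
#' fields `id`, `herbs`, `symptoms`) or CSV dialect (columns `record_id`,
#' `herbs`, `symptoms`, the latter two `";"`-joined). The dialect is chosen by
#' file extension (`.jsonl`/`.ndjson` vs `.csv`). Duplicate herbs within a
#' record are collapsed with a warning; a record with an empty herb set is an
#' error.
#'
#' @param path Path to an existing prescription file.
#' @return A list of prescription records; each record is a list with
#'   character fields `record_id`, `herbs` and `symptoms`.
#' @seealso [write_prescriptions()]
#' @export
read_prescriptions <- function(path) {
  if (!file.exists(path)) hp_stop("prescription file '%s' does not exist", path)
  ext <- tolower(tools::file_ext(path))
  records <- if (ext %in% c("jsonl", "ndjson")) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) hp_stop("prescription file '%s' is empty", path)
    lapply(seq_along(lines), function(i) {
      obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                      error = function(e)
                        hp_stop("parse error in '%s' line %d: %s",
                                path, i, conditionMessage(e)))
      if (is.null(obj$id))
        hp_stop("parse error in '%s' line %d: missing 'id'", path, i)
      list(record_id = as.character(obj$id),
           herbs = as.character(obj$herbs %||% character()),
           symptoms = as.character(obj$symptoms %||% character()))
    })
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    need <- c("record_id", "herbs", "symptoms")
    if (!all(need %in% names(df)))
      hp_stop("parse error in '%s': expected columns %s", path,
              paste(need, collapse = ", "))
    if (nrow(df) == 0L) hp_stop("prescription file '%s' is empty", path)
    lapply(seq_len(nrow(df)), function(i) {
      split_field <- function(x) {
        out <- strsplit(x, ";", fixed = TRUE)[[1L]]
        out[nzchar(out)]
      }
      list(record_id = df$record_id[i],
           herbs = split_field(df$herbs[i]),
           symptoms = split_field(df$symptoms[i]))
    })
  } else {
    hp_stop("unrecognised prescription file extension '.%s' (use .jsonl or .csv)", ext)
  }
  validate_records(records)
}

# Enforce record invariants: non-empty deduplicated herb sets.
validate_records <- function(records) {
  n_dup <- 0L
  records <- lapply(records, function(r) {
    if (length(r$herbs) == 0L)
      hp_stop("record '%s' has an empty herb set", r$record_id)
    if (anyDuplicated(r$herbs)) {
      n_dup <<- n_dup + 1L
      r$herbs <- unique(r$herbs)
    }
    r$symptoms <- unique(r$symptoms)
    r
  })
  if (n_dup > 0L)
    warning(sprintf("collapsed duplicate herbs in %d record(s)", n_dup),
            call. = FALSE)
  records
}

#' Write prescription records
#'
#' @param records List of prescription records (see [read_prescriptions()]).
#' @param path Output path; extension selects the JSONL or CSV dialect.
#' @return `path`, invisibly.
#' @export
write_prescriptions <- function(records, path) {
  ext <- tolower(tools::file_ext(path))
  write_atomic(path, function(tmp) {
    if (ext %in% c("jsonl", "ndjson")) {
      lines <- vapply(records, function(r) {
        jsonlite::toJSON(list(id = r$record_id, herbs = r$herbs,
                              symptoms = r$symptoms),
                         auto_unbox = TRUE)
      }, character(1))
      writeLines(lines, tmp)
    } else if (ext == "csv") {
      df <- data.frame(
        record_id = vapply(records, `[[`, character(1), "record_id"),
        herbs = vapply(records, function(r) paste(r$herbs, collapse = ";"),
                       character(1)),
        symptoms = vapply(records, function(r) paste(r$symptoms, collapse = ";"),
                          character(1)),
        stringsAsFactors = FALSE)
      utils::write.csv(df, tmp, row.names = FALSE, quote = TRUE)
    } else {
      hp_stop("unrecognised prescription file extension '.%s'", ext)
    }
  })
  invisible(path)
}

## ---- protein-protein interaction network -----------------------------------

#' Construct a protein interaction network object
#'
#' An undirected confidence-weighted protein graph. Edges are stored with
#' lexicographically ordered endpoints and unit-interval confidences; the node
#' set is the union of edge endpoints plus any explicitly supplied isolated
#' nodes.
#'
#' @param edges Data frame with columns `protein_a`, `protein_b`, `confidence`.
#' @param nodes Optional character vector of nodes (may include isolated ones).
#' @return An object of class `ppin`.
#' @export
ppin <- function(edges, nodes = NULL) {
  stopifnot(all(c("protein_a", "protein_b", "confidence") %in% names(edges)))
  edges$protein_a <- as.character(edges$protein_a)
  edges$protein_b <- as.character(edges$protein_b)
  keep <- edges$protein_a != edges$protein_b
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) > 0L) {
    if (any(!is.finite(edges$confidence) | edges$confidence < 0 |
            edges$confidence > 1))
      hp_stop("edge confidences must lie in [0, 1]")
    cp <- canonical_pair(edges$protein_a, edges$protein_b)
    edges$protein_a <- cp[, 1L]
    edges$protein_b <- cp[, 2L]
    # duplicate edges keep the maximum confidence
    key <- paste(edges$protein_a, edges$protein_b, sep = "\x1f")
    conf <- tapply(edges$confidence, key, max)
    parts <- strsplit(names(conf), "\x1f", fixed = TRUE)
    edges <- data.frame(protein_a = vapply(parts, `[`, character(1), 1L),
                        protein_b = vapply(parts, `[`, character(1), 2L),
                        confidence = as.numeric(conf),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$protein_a, edges$protein_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b, nodes)))
  structure(list(edges = edges, nodes = nodes), class = "ppin")
}

#' @export
print.ppin <- function(x, ...) {
  cat(sprintf("Protein interaction network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a protein interaction network from a STRING-style TSV
#'
#' Expects columns `protein_a`, `protein_b`, `combined_score`. Scores may be
#' on the 0-1000 STRING scale or already in `[0, 1]`; any score greater than 1
#' switches the whole file to the STRING dialect (scores divided by 1000).
#' Self-loops are dropped, duplicate edges keep the maximum confidence, and
#' edges below `min_confidence` are removed.
#'
#' @param path TSV file path.
#' @param min_confidence Minimum confidence retained (default 0.9).
#' @return A [ppin()] object.
#' @export
read_ppin <- function(path, min_confidence = 0.9) {
  if (!file.exists(path)) hp_stop("PPIN file '%s' does not exist", path)
  min_confidence <- assert_real(min_confidence, "min_confidence", 0, 1)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_a", "protein_b", "combined_score")
  if (!all(need %in% names(df)))
    hp_stop("parse error in '%s': expected columns %s", path,
            paste(need, collapse = ", "))
  score <- as.numeric(df$combined_score)
  if (any(!is.finite(score)) || any(score < 0))
    hp_stop("parse error in '%s': negative or non-numeric combined_score", path)
  if (any(score > 1)) score <- score / 1000  # STRING 0-1000 dialect
  if (any(score > 1))
    hp_stop("parse error in '%s': combined_score above 1000", path)
  edges <- data.frame(protein_a = df$protein_a, protein_b = df$protein_b,
                      confidence = score, stringsAsFactors = FALSE)
  edges <- edges[edges$confidence >= min_confidence, , drop = FALSE]
  ppin(edges)
}

#' Write a protein interaction network as TSV
#'
#' Emits the STRING-style three-column dialect with scores in `[0, 1]`.
#'
#' @param net A [ppin()] object.
#' @param path Output TSV path.
#' @export
write_ppin <- function(net, path) {
  df <- data.frame(protein_a = net$edges$protein_a,
                   protein_b = net$edges$protein_b,
                   combined_score = net$edges$confidence)
  write_atomic(path, function(tmp)
    utils::write.table(df, tmp, sep = "\t", row.names = FALSE, quote = FALSE))
  invisible(path)
}

## ---- gene sets (GMT), gene lists -------------------------------------------

#' Read a GMT gene-set collection
#'
#' @param path GMT file (tab-separated: set name, description, genes...).
#' @return Named list of character vectors, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) hp_stop("GMT file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      hp_stop("parse error in '%s' line %d: fewer than 3 fields", path, i)
    sets[[f[1L]]] <- unique(f[-(1:2)])
    desc[f[1L]] <- f[2L]
  }
  sets <- sets[order(names(sets))]
  attr(sets, "descriptions") <- desc[names(sets)]
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors; an optional `descriptions`
#'   attribute supplies the second GMT column.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  nm <- sort(names(sets))
  write_atomic(path, function(tmp) {
    lines <- vapply(nm, function(s)
      paste(c(s, desc[[s]] %||% "na", sort(sets[[s]])), collapse = "\t"),
      character(1))
    writeLines(lines, tmp)
  })
  invisible(path)
}

#' Read a plain gene list (one symbol per line)
#' @param path TSV/plain-text file path.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) hp_stop("gene list '%s' does not exist", path)
  x <- readLines(path, warn = FALSE)
  unique(trimws(x[nzchar(trimws(x))]))
}

#' Write a plain gene list
#' @param genes Character vector.
#' @param path Output path.
#' @export
write_gene_list <- function(genes, path) {
  write_atomic(path, function(tmp) writeLines(sort(unique(genes)), tmp))
  invisible(path)
}

## ---- ontology (simplified OBO) ---------------------------------------------

#' Construct an ontology DAG
#'
#' A simplified Gene Ontology-style directed acyclic graph: terms with a
#' namespace, child-to-parent edges typed `is_a` or `part_of`, and an optional
#' gene-to-term annotation map. Validates acyclicity and that each namespace in
#' use has exactly one root.
#'
#' @param terms Data frame with columns `id`, `name`, `namespace`.
#' @param edges Data frame with columns `child`, `parent`, `relation`
#'   (`"is_a"` or `"part_of"`).
#' @param annotations Named list mapping gene symbols to character vectors of
#'   term ids.
#' @return An object of class `ontology_dag`.
#' @export
ontology_dag <- function(terms, edges, annotations = list()) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)),
            all(c("child", "parent", "relation") %in% names(edges)))
  terms$id <- as.character(terms$id)
  if (anyDuplicated(terms$id)) hp_stop("duplicate term ids in ontology")
  bad <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(bad) > 0L)
    hp_stop("ontology edges reference unknown terms: %s",
            paste(utils::head(bad, 3), collapse = ", "))
  if (!all(edges$relation %in% c("is_a", "part_of")))
    hp_stop("ontology edge relations must be 'is_a' or 'part_of'")
  # acyclicity via Kahn's algorithm on child -> parent edges
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       directed = TRUE,
                                       vertices = terms$id)
    if (!igraph::is_acyclic(g)) {
      comp <- tryCatch({
        scc <- igraph::components(g, mode = "strong")
        names(scc$membership)[scc$membership %in%
                                which(scc$csize > 1)][1:3]
      }, error = function(e) character())
      hp_stop("ontology is cyclic (e.g. involving terms: %s)",
              paste(comp, collapse = ", "))
    }
  }
  # exactly one root per namespace in use
  has_parent <- terms$id %in% edges$child
  for (ns in unique(terms$namespace)) {
    roots <- terms$id[terms$namespace == ns & !has_parent]
    if (length(roots) != 1L)
      hp_stop("namespace '%s' must have exactly one root (found %d)",
              ns, length(roots))
  }
  bad_ann <- setdiff(unlist(annotations, use.names = FALSE), terms$id)
  if (length(bad_ann) > 0L)
    hp_stop("annotations reference unknown terms: %s",
            paste(utils::head(bad_ann, 3), collapse = ", "))
  annotations <- lapply(annotations, function(x) sort(unique(as.character(x))))
  if (length(annotations) > 0L)
    annotations <- annotations[order(names(annotations))]
  terms <- terms[order(terms$id), c("id", "name", "namespace")]
  rownames(terms) <- NULL
  if (nrow(edges) > 0L) {
    edges <- edges[order(edges$child, edges$parent), c("child", "parent", "relation")]
    rownames(edges) <- NULL
  }
  structure(list(terms = terms, edges = edges, annotations = annotations),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("Ontology DAG: %d terms, %d edges, %d annotated genes\n",
              nrow(x$terms), nrow(x$edges), length(x$annotations)))
  invisible(x)
}

#' Read a simplified OBO ontology
#'
#' Parses `[Term]` blocks with `id`, `name`, `namespace`, `is_a` and
#' `relationship: part_of` lines. Anything outside this subset is ignored.
#'
#' @param path OBO file path.
#' @return An [ontology_dag()] (with empty annotations; see
#'   [read_gene_annotations()]).
#' @export
read_obo_subset <- function(path) {
  if (!file.exists(path)) hp_stop("OBO file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  terms <- list(); edges <- list()
  cur <- NULL; in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id))
      terms[[length(terms) + 1L]] <<- cur
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^namespace:", ln)) cur$namespace <- trimws(sub("^namespace:", "", ln))
    else if (grepl("^is_a:", ln)) {
      parent <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      edges[[length(edges) + 1L]] <- list(child = cur$id, parent = parent,
                                          relation = "is_a")
    } else if (grepl("^relationship:\\s*part_of", ln)) {
      parent <- trimws(sub("!.*$", "", sub("^relationship:\\s*part_of", "", ln)))
      edges[[length(edges) + 1L]] <- list(child = cur$id, parent = parent,
                                          relation = "part_of")
    }
  }
  flush()
  if (length(terms) == 0L) hp_stop("no [Term] blocks found in '%s'", path)
  tdf <- data.frame(
    id = vapply(terms, `[[`, character(1), "id"),
    name = vapply(terms, function(t) t$name %||% t$id, character(1)),
    namespace = vapply(terms, function(t) t$namespace %||% "biological_process",
                       character(1)),
    stringsAsFactors = FALSE)
  edf <- if (length(edges) > 0L) {
    data.frame(child = vapply(edges, `[[`, character(1), "child"),
               parent = vapply(edges, `[[`, character(1), "parent"),
               relation = vapply(edges, `[[`, character(1), "relation"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(child = character(), parent = character(),
               relation = character(), stringsAsFactors = FALSE)
  }
  ontology_dag(tdf, edf)
}

#' Write a simplified OBO ontology
#' @param dag An [ontology_dag()].
#' @param path Output path.
#' @export
write_obo_subset <- function(dag, path) {
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w"); on.exit(close(con))
    writeLines("format-version: 1.2", con)
    for (i in seq_len(nrow(dag$terms))) {
      id <- dag$terms$id[i]
      writeLines(c("", "[Term]",
                   paste0("id: ", id),
                   paste0("name: ", dag$terms$name[i]),
                   paste0("namespace: ", dag$terms$namespace[i])), con)
      e <- dag$edges[dag$edges$child == id, , drop = FALSE]
      for (j in seq_len(nrow(e))) {
        if (e$relation[j] == "is_a")
          writeLines(paste0("is_a: ", e$parent[j]), con)
        else
          writeLines(paste0("relationship: part_of ", e$parent[j]), con)
      }
    }
  })
  invisible(path)
}

#' Read gene-to-term annotations (two-column TSV: gene, term)
#' @param path TSV path.
#' @return Named list mapping genes to term id vectors.
#' @export
read_gene_annotations <- function(path) {
  if (!file.exists(path)) hp_stop("annotation file '%s' does not exist", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(df)))
    hp_stop("parse error in '%s': expected columns gene, term", path)
  sp <- split(df$term, df$gene)
  lapply(sp[order(names(sp))], function(x) sort(unique(x)))
}

#' Write gene-to-term annotations
#' @param annotations Named list mapping genes to term id vectors.
#' @param path Output TSV path.
#' @export
write_gene_annotations <- function(annotations, path) {
  genes <- sort(names(annotations))
  df <- data.frame(
    gene = rep(genes, lengths(annotations[genes])),
    term = unlist(lapply(annotations[genes], sort), use.names = FALSE),
    stringsAsFactors = FALSE)
  write_atomic(path, function(tmp)
    utils::write.table(df, tmp, sep = "\t", row.names = FALSE, quote = FALSE))
  invisible(path)
}

## ---- herb profiles ---------------------------------------------------------

#' Construct a herb knowledge profile
#'
#' @param herb Herb name.
#' @param compounds Data frame with columns `compound_id` and `ob_percent`
#'   (oral bioavailability, 0-100).
#' @param targets Character vector of protein/gene targets.
#' @param symptoms Character vector of TCM symptom terms the herb regulates.
#' @return Object of class `herb_profile`.
#' @export
herb_profile <- function(herb, compounds, targets = character(),
                         symptoms = character()) {
  if (is.null(compounds) || nrow(compounds) == 0L) {
    compounds <- data.frame(compound_id = character(), ob_percent = numeric(),
                            stringsAsFactors = FALSE)
  }
  stopifnot(all(c("compound_id", "ob_percent") %in% names(compounds)))
  if (anyDuplicated(compounds$compound_id))
    hp_stop("herb '%s': duplicate compound ids", herb)
  ob <- compounds$ob_percent
  if (any(!is.finite(ob) | ob < 0 | ob > 100))
    hp_stop("herb '%s': OB values must be finite and in [0, 100]", herb)
  compounds <- compounds[order(compounds$compound_id),
                         c("compound_id", "ob_percent"), drop = FALSE]
  rownames(compounds) <- NULL
  structure(list(herb = as.character(herb), compounds = compounds,
                 targets = sort(unique(as.character(targets))),
                 symptoms = sort(unique(as.character(symptoms)))),
            class = "herb_profile")
}

#' Read herb profiles (JSONL, one herb per line)
#'
#' Each line is an object `{"herb": ..., "compounds": [{"id": ..., "ob": ...}],
#' "targets": [...], "symptoms": [...]}`.
#'
#' @param path JSONL path.
#' @return Named list of [herb_profile()] objects.
#' @export
read_herb_profiles <- function(path) {
  if (!file.exists(path)) hp_stop("herb profile file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) hp_stop("herb profile file '%s' is empty", path)
  profiles <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e)
                      hp_stop("parse error in '%s' line %d: %s", path, i,
                              conditionMessage(e)))
    comp <- obj$compounds
    cdf <- if (is.null(comp) || length(comp) == 0L) NULL else
      data.frame(compound_id = as.character(comp$id),
                 ob_percent = as.numeric(comp$ob), stringsAsFactors = FALSE)
    herb_profile(obj$herb, cdf, as.character(obj$targets %||% character()),
                 as.character(obj$symptoms %||% character()))
  })
  names(profiles) <- vapply(profiles, `[[`, character(1), "herb")
  profiles[order(names(profiles))]
}

#' Write herb profiles (JSONL)
#' @param profiles Named list of [herb_profile()] objects.
#' @param path Output path.
#' @export
write_herb_profiles <- function(profiles, path) {
  profiles <- profiles[order(vapply(profiles, `[[`, character(1), "herb"))]
  write_atomic(path, function(tmp) {
    lines <- vapply(profiles, function(p) {
      jsonlite::toJSON(list(
        herb = p$herb,
        compounds = lapply(seq_len(nrow(p$compounds)), function(i)
          list(id = p$compounds$compound_id[i], ob = p$compounds$ob_percent[i])),
        targets = p$targets, symptoms = p$symptoms), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, tmp)
  })
  invisible(path)
}

## ---- disease context -------------------------------------------------------

#' Construct a disease context
#'
#' @param disease_genes Character vector of disease-related gene symbols.
#' @param disease_symptoms Character vector of disease-related symptom terms.
#' @param label Disease name.
#' @return Object of class `disease_context`.
#' @export
disease_context <- function(disease_genes, disease_symptoms, label = "disease") {
  if (length(disease_genes) == 0L || length(disease_symptoms) == 0L)
    hp_stop("disease context needs non-empty gene and symptom sets")
  structure(list(disease_genes = sort(unique(as.character(disease_genes))),
                 disease_symptoms = sort(unique(as.character(disease_symptoms))),
                 label = as.character(label)),
            class = "disease_context")
}

#' Read a disease context from JSON
#' @param path JSON path.
#' @return A [disease_context()].
#' @export
read_disease_context <- function(path) {
  if (!file.exists(path)) hp_stop("disease context '%s' does not exist", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  disease_context(obj$disease_genes, obj$disease_symptoms,
                  obj$label %||% "disease")
}

#' Write a disease context to JSON
#' @param disease A [disease_context()].
#' @param path Output path.
#' @export
write_disease_context <- function(disease, path) {
  write_atomic(path, function(tmp)
    jsonlite::write_json(list(label = disease$label,
                              disease_genes = disease$disease_genes,
                              disease_symptoms = disease$disease_symptoms),
                         tmp, auto_unbox = TRUE, pretty = TRUE))
  invisible(path)
}

## ---- tabular outputs -------------------------------------------------------

#' Write a feature/label table as CSV with a documented header
#' @param table Data frame.
#' @param path Output CSV path.
#' @export
write_feature_table <- function(table, path) {
  write_atomic(path, function(tmp)
    utils::write.csv(table, tmp, row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' Read a feature/label table written by [write_feature_table()]
#' @param path CSV path.
#' @return Data frame.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) hp_stop("table '%s' does not exist", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a machine-readable report (JSON)
#' @param report A list.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  write_atomic(path, function(tmp)
    jsonlite::write_json(report, tmp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA))
  invisible(path)
}
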