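# Synthetic fixtures: toy ontologies, gene2go-style annotation tables and
# label sets with a controlled monotone dependence on the true score, so the
# whole pipeline is testable offline. These emulate the *shape* of real GO
# inputs, not the scale-free topology of the real cellular-component graph.

#' Fixture specification
#'
#' @param n_terms ontology size (terms, including the single root).
#' @param depth maximum DAG depth (levels; root is level 1).
#' @param part_of_fraction fraction of edges labeled `part_of` (in
#'   expectation).
#' @param n_genes number of annotated genes.
#' @param term_count_range inclusive range of per-gene annotation sizes;
#'   the default upper bound of 45 mirrors the range of actual per-gene
#'   GO-CC term counts in human.
#' @param label_model numeric `c(alpha, beta)` of the label mechanism
#'   `P(positive) = plogis(alpha + beta * sdi)`.
#' @param iea_fraction fraction of annotation rows tagged with evidence code
#'   `IEA` (the rest are `IDA`).
#' @param taxon tax_id written into generated gene2go tables.
#' @param seed integer seed; all generation is a pure function of spec +
#'   seed.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_terms = 100L, depth = 5L, part_of_fraction = 0.2,
                         n_genes = 100L, term_count_range = c(1L, 45L),
                         label_model = c(alpha = -2, beta = 0.8),
                         iea_fraction = 0.3, taxon = "9606", seed = 1L) {
  stopifnot(n_terms >= 1L, depth >= 1L,
            part_of_fraction >= 0, part_of_fraction <= 1,
            n_genes >= 1L, term_count_range[1] >= 1L,
            term_count_range[2] >= term_count_range[1],
            length(label_model) == 2L,
            iea_fraction >= 0, iea_fraction <= 1)
  if (depth > n_terms) stop("infeasible spec: depth exceeds n_terms")
  structure(list(n_terms = as.integer(n_terms), depth = as.integer(depth),
                 part_of_fraction = part_of_fraction,
                 n_genes = as.integer(n_genes),
                 term_count_range = as.integer(term_count_range),
                 label_model = stats::setNames(as.numeric(label_model),
                                               c("alpha", "beta")),
                 iea_fraction = iea_fraction, taxon = as.character(taxon),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic ontology
#'
#' Builds a connected, single-rooted DAG by levels: the root sits at level 1,
#' every other term is placed on a deeper level and linked to 1–2 parents
#' drawn from strictly shallower levels, which guarantees acyclicity and
#' root-reachability by construction. Edge labels are drawn `part_of` with
#' probability `part_of_fraction`, else `is_a`.
#'
#' @param spec a [fixture_spec()].
#' @return An [ontology_dag()] (namespace `cellular_component`).
#' @export
make_ontology <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_terms
  ids <- sprintf("GO:%07d", seq_len(n))
  if (n == 1L) {
    return(ontology_dag(ids, NULL))
  }
  if (spec$depth < 2L) stop("infeasible spec: depth < 2 with n_terms > 1")
  with_seed(child_seed(spec$seed, 1L), {
    level <- c(1L, resample(seq.int(2L, spec$depth),
                            n - 1L, replace = TRUE))
    child <- character(); parent <- character(); relation <- character()
    for (i in seq.int(2L, n)) {
      cand <- ids[level < level[i]]
      np <- resample(seq_len(min(2L, length(cand))), 1L)
      par <- resample(cand, np)
      rel <- ifelse(stats::runif(np) < spec$part_of_fraction,
                    "part_of", "is_a")
      child <- c(child, rep(ids[i], np))
      parent <- c(parent, par)
      relation <- c(relation, rel)
    }
    ontology_dag(ids, data.frame(child = child, parent = parent,
                                 relation = relation,
                                 stringsAsFactors = FALSE))
  })
}

#' Serialize an ontology to OBO
#'
#' Writes a canonical, deterministic OBO 1.2 rendering (terms sorted by id,
#' edges sorted within each term) that round-trips through [parse_obo()].
#'
#' @param dag an [ontology_dag()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_obo <- function(dag, path) {
  out <- c("format-version: 1.2",
           paste0("default-namespace: ", dag$namespace), "")
  alt_by_term <- if (length(dag$alt_id_map)) {
    split(names(dag$alt_id_map), unname(dag$alt_id_map))
  } else list()
  for (t in dag$terms) {
    stanza <- c("[Term]", paste0("id: ", t), paste0("name: term ", t),
                paste0("namespace: ", dag$namespace))
    alts <- alt_by_term[[t]]
    if (!is.null(alts)) stanza <- c(stanza, paste0("alt_id: ", sort(alts)))
    e <- dag$edges[dag$edges$child == t, , drop = FALSE]
    isa <- sort(e$parent[e$relation == "is_a"])
    po <- sort(e$parent[e$relation == "part_of"])
    if (length(isa)) stanza <- c(stanza, paste0("is_a: ", isa))
    if (length(po)) stanza <- c(stanza, paste0("relationship: part_of ", po))
    out <- c(out, stanza, "")
  }
  for (t in dag$obsolete) {
    out <- c(out, "[Term]", paste0("id: ", t), paste0("name: term ", t),
             paste0("namespace: ", dag$namespace), "is_obsolete: true", "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Generate synthetic annotations
#'
#' Draws `n_genes` genes, each annotated with a term set of uniform size
#' within `term_count_range` sampled without replacement from the ontology
#' (clamped to the ontology size with a warning). A fraction of rows is
#' tagged `IEA`, the rest `IDA`.
#'
#' @param dag an [ontology_dag()].
#' @param spec a [fixture_spec()].
#' @return List: `annotations` (named list of [gene_annotation()]) and
#'   `table` (data frame in gene2go column layout, one row per gene/term).
#' @export
make_annotations <- function(dag, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!length(dag$terms)) stop("empty ontology")
  hi <- spec$term_count_range[2]
  if (hi > length(dag$terms)) {
    warning("term_count_range upper bound clamped to ontology size (",
            length(dag$terms), ")")
    hi <- length(dag$terms)
  }
  lo <- min(spec$term_count_range[1], hi)
  with_seed(child_seed(spec$seed, 2L), {
    gene_ids <- sprintf("%d", 10000L + seq_len(spec$n_genes))
    ann <- lapply(seq_len(spec$n_genes), function(i) {
      k <- resample(seq.int(lo, hi), 1L)
      gene_annotation(gene_ids[i], resample(dag$terms, k))
    })
    names(ann) <- gene_ids
    rows <- do.call(rbind, lapply(ann, function(a) {
      data.frame(tax_id = spec$taxon, GeneID = a$gene_id, GO_ID = a$terms,
                 stringsAsFactors = FALSE)
    }))
    rows$Evidence <- ifelse(stats::runif(nrow(rows)) < spec$iea_fraction,
                            "IEA", "IDA")
    rows$Qualifier <- "-"
    rows$GO_term <- paste("term", rows$GO_ID)
    rows$PubMed <- "-"
    rows$Category <- "Component"
    rownames(rows) <- NULL
    list(annotations = ann, table = rows)
  })
}

#' Serialize an annotation table to gene2go format
#'
#' @param table data frame in gene2go column layout (from
#'   [make_annotations()]).
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_gene2go <- function(table, path) {
  hdr <- paste(c("#tax_id", "GeneID", "GO_ID", "Evidence", "Qualifier",
                 "GO_term", "PubMed", "Category"), collapse = "\t")
  body <- do.call(paste, c(unname(as.list(table[, c(
    "tax_id", "GeneID", "GO_ID", "Evidence", "Qualifier", "GO_term",
    "PubMed", "Category")])), sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Draw a synthetic label set from scores
#'
#' Each gene is positive with probability `plogis(alpha + beta * sdi)`,
#' giving a label set whose dependence on the true score is monotone and
#' fully controlled — the mechanism behind the parameter-recovery tests.
#'
#' @param scores an `sdi_scores` object, score data frame, or named numeric
#'   vector.
#' @param label_model numeric `c(alpha, beta)`.
#' @param seed integer seed.
#' @param name label name (default `"synthetic"`).
#' @return A [label_set()].
#' @export
make_labels <- function(scores, label_model = c(alpha = -2, beta = 0.8),
                        seed = 1L, name = "synthetic") {
  s <- as_score_vector(scores)
  if (!length(s)) stop("no scores supplied")
  p <- stats::plogis(label_model[[1]] + label_model[[2]] * s)
  with_seed(child_seed(seed, 3L), {
    pos <- names(s)[stats::runif(length(s)) < p]
    label_set(name, pos)
  })
}

#' Write a label set as a one-gene-per-line file
#'
#' @param labels a [label_set()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_label_set <- function(labels, path) {
  writeLines(sort(labels$positives), path)
  invisible(path)
}
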