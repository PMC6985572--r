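# Ontology DAG container and OBO parsing.
#
# The ontology is held as a plain child->parent edge table plus adjacency
# maps, which is all Wang's recurrence needs; igraph is used only for the
# structural acyclicity check at construction time.

#' Construct an ontology DAG
#'
#' Low-level constructor for the DAG container used throughout the package.
#' Most users will obtain one from [parse_obo()] or [make_ontology()].
#'
#' @param terms character vector of term identifiers (e.g. `"GO:0005634"`).
#' @param edges data frame with columns `child`, `parent`, `relation`
#'   (directed child -> parent links); `relation` must be `"is_a"` or
#'   `"part_of"`. May have zero rows.
#' @param namespace ontology namespace tag, e.g. `"cellular_component"`.
#' @param alt_id_map named character vector mapping alias identifiers to
#'   canonical identifiers (names = aliases).
#' @param obsolete character vector of obsolete term identifiers; these never
#'   participate in edges.
#' @return An object of class `ontology_dag` with fields `terms`, `edges`,
#'   `namespace`, `roots`, `alt_id_map`, `obsolete` and internal adjacency
#'   maps `parent_map` / `parent_rel`.
#' @export
ontology_dag <- function(terms, edges, namespace = "cellular_component",
                         alt_id_map = character(), obsolete = character()) {
  terms <- sort(unique(as.character(terms)))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  edges <- unique(edges[, c("child", "parent", "relation")])
  bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
  if (length(bad_rel)) {
    stop("unsupported edge relation(s): ", paste(bad_rel, collapse = ", "))
  }
  missing_ep <- setdiff(unique(c(edges$child, edges$parent)), terms)
  if (length(missing_ep)) {
    stop("edge endpoint(s) not in term set: ",
         paste(utils::head(missing_ep, 3), collapse = ", "))
  }
  if (length(intersect(obsolete, unique(c(edges$child, edges$parent))))) {
    stop("obsolete terms must not participate in edges")
  }
  if (length(alt_id_map) && !all(alt_id_map %in% terms)) {
    stop("alt_id_map values must be members of terms")
  }
  edges <- edges[order(edges$child, edges$parent, edges$relation), , drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       vertices = terms)
    if (!igraph::is_dag(g)) {
      comp <- igraph::components(g, mode = "strong")
      big <- which(comp$csize > 1)[1]
      member <- if (is.na(big)) edges$child[edges$child == edges$parent][1] else
        names(comp$membership)[comp$membership == big][1]
      stop("ontology contains a cycle involving term ", member)
    }
  }
  parent_map <- split(edges$parent, factor(edges$child, levels = terms))
  parent_rel <- split(edges$relation, factor(edges$child, levels = terms))
  roots <- terms[lengths(parent_map) == 0L & !terms %in% obsolete]
  structure(list(
    terms = terms, edges = edges, namespace = namespace, roots = roots,
    alt_id_map = alt_id_map, obsolete = sort(unique(obsolete)),
    parent_map = parent_map, parent_rel = parent_rel
  ), class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %s: %d terms, %d edges (%d is_a, %d part_of), %d root(s)\n",
              x$namespace, length(x$terms), nrow(x$edges),
              sum(x$edges$relation == "is_a"),
              sum(x$edges$relation == "part_of"), length(x$roots)))
  invisible(x)
}

#' Resolve a term identifier against a DAG
#'
#' Maps alias (`alt_id`) identifiers to their canonical identifier and checks
#' membership. Returns `NA_character_` when the identifier is unknown.
#'
#' @param dag an [ontology_dag()].
#' @param term term identifier.
#' @return Canonical identifier, or `NA_character_`.
#' @export
resolve_term <- function(dag, term) {
  if (term %in% dag$terms) return(term)
  hit <- dag$alt_id_map[term]
  if (!is.na(hit)) return(unname(hit))
  NA_character_
}

# Ancestor closure (including the term itself), following child->parent edges.
term_ancestors <- function(dag, term) {
  seen <- character()
  frontier <- term
  while (length(frontier)) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(dag$parent_map[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  sort(unique(seen))
}

#' Parse an OBO ontology file
#'
#' Reads the `[Term]` stanzas of an OBO 1.2/1.4 file (the go-basic dialect:
#' fields `id`, `name`, `namespace`, `alt_id`, `is_a`, `relationship`,
#' `is_obsolete`) into an [ontology_dag()] restricted to one namespace.
#' Only `is_a` and `part_of` relationships are kept as edges; all other
#' relationship types (`regulates`, `occurs_in`, ...) are dropped with a
#' message reporting the count. Obsolete terms are excluded from the graph
#' but recorded, and `alt_id` aliases are recorded for later resolution.
#' Gzip-compressed files are read transparently.
#'
#' @param path path to an OBO file.
#' @param namespace namespace to retain (default `"cellular_component"`).
#' @return An [ontology_dag()].
#' @export
parse_obo <- function(path, namespace = "cellular_component") {
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)

  stanza_hdr <- grepl("^\\[", lines)
  stanza_id <- cumsum(stanza_hdr)
  term_stanzas <- stanza_id[stanza_hdr & lines == "[Term]"]
  body <- !stanza_hdr & nzchar(lines) & stanza_id %in% term_stanzas &
    grepl(":", lines, fixed = TRUE)
  l <- lines[body]
  sid <- stanza_id[body]
  key <- sub(":.*$", "", l)
  value <- sub("^[^:]*:\\s*", "", l)
  value <- sub("\\s*!.*$", "", value)            # strip trailing OBO comments
  value <- trimws(value)

  pick <- function(k) {
    i <- key == k
    list(sid = sid[i], value = value[i])
  }
  ids <- pick("id")
  id_of <- stats::setNames(ids$value, ids$sid)
  ns <- pick("namespace")
  ns_of <- stats::setNames(ns$value, ns$sid)
  obs <- pick("is_obsolete")
  obsolete_sids <- obs$sid[tolower(obs$value) == "true"]

  in_ns <- names(id_of)[ns_of[names(id_of)] %in% namespace]
  if (!length(in_ns)) stop("no terms found for namespace '", namespace, "'")
  keep_sids <- setdiff(in_ns, as.character(obsolete_sids))
  obsolete_terms <- unname(id_of[intersect(in_ns, as.character(obsolete_sids))])
  terms <- unname(id_of[keep_sids])

  isa <- pick("is_a")
  isa_edges <- data.frame(child = unname(id_of[as.character(isa$sid)]),
                          parent = isa$value,
                          relation = rep("is_a", length(isa$sid)),
                          stringsAsFactors = FALSE)
  rel <- pick("relationship")
  rel_type <- sub("\\s.*$", "", rel$value)
  rel_target <- sub("^\\S+\\s+", "", rel$value)
  is_po <- rel_type == "part_of"
  n_dropped_rel <- sum(!is_po)
  if (n_dropped_rel) {
    message(n_dropped_rel, " non is_a/part_of relationship(s) dropped (",
            paste(unique(rel_type[!is_po]), collapse = ", "), ")")
  }
  po_edges <- data.frame(child = unname(id_of[as.character(rel$sid[is_po])]),
                         parent = rel_target[is_po],
                         relation = rep("part_of", sum(is_po)),
                         stringsAsFactors = FALSE)
  edges <- rbind(isa_edges, po_edges)
  # keep only edges fully inside the retained (namespace, non-obsolete) set
  edges <- edges[edges$child %in% terms & edges$parent %in% terms, , drop = FALSE]

  alt <- pick("alt_id")
  alt_keep <- as.character(alt$sid) %in% keep_sids
  alt_id_map <- stats::setNames(unname(id_of[as.character(alt$sid[alt_keep])]),
                                alt$value[alt_keep])

  ontology_dag(terms, edges, namespace = namespace,
               alt_id_map = alt_id_map, obsolete = obsolete_terms)
}

#' Induced ancestor graph of a term
#'
#' Returns the sub-DAG spanned by a term and all of its ancestors reachable
#' through `is_a` / `part_of` edges, together with every edge among them —
#' the ancestor graph on which Wang's semantic contributions are defined.
#'
#' @param dag an [ontology_dag()].
#' @param term term identifier (aliases are resolved).
#' @return An [ontology_dag()] restricted to the ancestor set of `term`.
#' @export
induced_ancestor_graph <- function(dag, term) {
  t0 <- resolve_term(dag, term)
  if (is.na(t0)) stop("unknown term: ", term)
  anc <- term_ancestors(dag, t0)
  e <- dag$edges[dag$edges$child %in% anc & dag$edges$parent %in% anc, ,
                 drop = FALSE]
  ontology_dag(anc, e, namespace = dag$namespace)
}
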