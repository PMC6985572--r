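# Wang's graph-based semantic similarity over the is_a / part_of DAG.
#
# Each term A defines an ancestor graph; every ancestor t receives a semantic
# contribution S_A(t) through a max-product recurrence over edge contribution
# factors, and the similarity of two terms is the shared-contribution ratio
# over their semantic values. The S-values are computed by memoized dynamic
# programming in reverse-topological order; the test suite carries a naive
# exponential path-enumeration twin as the independent oracle.

#' Similarity configuration
#'
#' Contribution factors for the two edge types Wang's recurrence traverses.
#' Defaults are the values recommended by the method's authors and used
#' throughout this package: 0.8 for `is_a`, 0.6 for `part_of`.
#'
#' @param w_is_a contribution factor for `is_a` edges, in (0, 1).
#' @param w_part_of contribution factor for `part_of` edges, in (0, 1).
#' @return Object of class `similarity_config`.
#' @export
similarity_config <- function(w_is_a = 0.8, w_part_of = 0.6) {
  stopifnot(is.numeric(w_is_a), length(w_is_a) == 1L,
            w_is_a > 0, w_is_a < 1,
            is.numeric(w_part_of), length(w_part_of) == 1L,
            w_part_of > 0, w_part_of < 1)
  structure(list(w_is_a = w_is_a, w_part_of = w_part_of),
            class = "similarity_config")
}

config_key <- function(config) {
  sprintf("%.17g|%.17g", config$w_is_a, config$w_part_of)
}

#' Semantic profile of a term
#'
#' Computes Wang's per-ancestor semantic contributions for one term:
#' `S_A(A) = 1` and, for every proper ancestor `t`,
#' `S_A(t) = max { w_e * S_A(t') }` over the children `t'` of `t` inside the
#' induced ancestor graph of `A`, where `w_e` is the contribution factor of
#' the connecting edge. The semantic value `SV(A)` is the sum of all
#' contributions.
#'
#' @param dag an [ontology_dag()].
#' @param term term identifier (aliases resolved).
#' @param config a [similarity_config()].
#' @param cache optional environment used to memoize profiles across calls
#'   within one scoring run; caching never changes results.
#' @return Object of class `term_semantic_profile` with fields `term`,
#'   `s_values` (named numeric, includes the term itself at exactly 1) and
#'   `sv`.
#' @export
semantic_profile <- function(dag, term, config = similarity_config(),
                             cache = NULL) {
  t0 <- resolve_term(dag, term)
  if (is.na(t0)) stop("unknown term: ", term)
  key <- paste0(t0, "|", config_key(config))
  if (!is.null(cache)) {
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  anc <- term_ancestors(dag, t0)
  w <- c(is_a = config$w_is_a, part_of = config$w_part_of)
  e <- dag$edges[dag$edges$child %in% anc & dag$edges$parent %in% anc, ,
                 drop = FALSE]
  kids_of <- split(e$child, factor(e$parent, levels = anc))
  rels_of <- split(e$relation, factor(e$parent, levels = anc))
  s <- stats::setNames(rep(NA_real_, length(anc)), anc)
  s[t0] <- 1
  calc <- function(t) {
    v <- s[[t]]
    if (!is.na(v)) return(v)
    kids <- kids_of[[t]]
    rels <- rels_of[[t]]
    v <- max(vapply(seq_along(kids),
                    function(i) w[[rels[i]]] * calc(kids[i]),
                    numeric(1)))
    s[[t]] <<- v
    v
  }
  for (t in anc) calc(t)
  out <- structure(list(term = t0, s_values = s, sv = sum(s)),
                   class = "term_semantic_profile")
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' @export
print.term_semantic_profile <- function(x, ...) {
  cat(sprintf("<term_semantic_profile> %s: %d ancestor(s), SV = %.4f\n",
              x$term, length(x$s_values), x$sv))
  invisible(x)
}

#' Wang semantic similarity of two terms
#'
#' `S(A, B) = sum over shared ancestors t of (S_A(t) + S_B(t)) / (SV(A) +
#' SV(B))`. Symmetric, exactly 1 for identical terms, and 0 when the two
#' ancestor graphs are disjoint (possible only on disconnected ontologies).
#'
#' @param dag an [ontology_dag()].
#' @param a,b term identifiers.
#' @param config a [similarity_config()].
#' @param cache optional profile cache environment (see [semantic_profile()]).
#' @return Similarity in `[0, 1]`.
#' @export
term_similarity <- function(dag, a, b, config = similarity_config(),
                            cache = NULL) {
  pa <- semantic_profile(dag, a, config, cache)
  pb <- semantic_profile(dag, b, config, cache)
  if (identical(pa$term, pb$term)) return(1)
  common <- intersect(names(pa$s_values), names(pb$s_values))
  if (!length(common)) return(0)
  (sum(pa$s_values[common]) + sum(pb$s_values[common])) / (pa$sv + pb$sv)
}

#' Pairwise Wang similarity matrix
#'
#' Computes all pairwise similarities among a set of terms in one pass using
#' the profiles' shared-ancestor sums in matrix form; used by
#' [score_genome()] so each term's profile is computed once per run.
#'
#' @param dag an [ontology_dag()].
#' @param terms character vector of (canonical) term identifiers.
#' @param config a [similarity_config()].
#' @param cache optional profile cache environment.
#' @return Symmetric numeric matrix with unit diagonal, dimnames = terms.
#' @export
term_similarity_matrix <- function(dag, terms, config = similarity_config(),
                                   cache = NULL) {
  terms <- unique(terms)
  profs <- lapply(terms, function(t) semantic_profile(dag, t, config, cache))
  anc_all <- sort(unique(unlist(lapply(profs, function(p) names(p$s_values)),
                                use.names = FALSE)))
  P <- matrix(0, length(terms), length(anc_all),
              dimnames = list(terms, anc_all))
  for (i in seq_along(profs)) {
    P[i, names(profs[[i]]$s_values)] <- profs[[i]]$s_values
  }
  I <- (P > 0) + 0
  num <- P %*% t(I) + I %*% t(P)       # shared-ancestor contribution sums
  sv <- vapply(profs, `[[`, numeric(1), "sv")
  M <- num / outer(sv, sv, `+`)
  diag(M) <- 1
  M
}

#' Write a pairwise similarity table
#'
#' Debugging helper: dumps the upper triangle of a similarity matrix as a TSV
#' with columns `term_a`, `term_b`, `similarity`.
#'
#' @param m matrix from [term_similarity_matrix()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_similarity_tsv <- function(m, path) {
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(term_a = rownames(m)[idx[, 1]],
                   term_b = colnames(m)[idx[, 2]],
                   similarity = m[idx], stringsAsFactors = FALSE)
  df <- df[order(df$term_a, df$term_b), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
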