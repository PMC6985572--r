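# The Subcellular Diversity Index.
#
# For a gene annotated with the term cluster c of size n, each term i gets a
# penalty p_i: 1 when n = 1, otherwise an aggregate (RMS by default) of its
# n-1 pairwise Wang similarities to the other terms. SDI = sum(1 - p_i).

#' SDI configuration
#'
#' @param aggregator how the n-1 pairwise similarities of a term collapse
#'   into its penalty: `"rms"` (root mean square, the default and the
#'   best-performing variant for essential-gene validation),
#'   `"arithmetic_mean"`, or `"geometric_mean"`.
#' @param similarity_config a [similarity_config()].
#' @param quantile_type quantile convention for the genome summary (7 =
#'   linear interpolation, 1 = inverse ECDF).
#' @return Object of class `sdi_config`.
#' @export
sdi_config <- function(aggregator = c("rms", "arithmetic_mean",
                                      "geometric_mean"),
                       similarity_config = sdindex::similarity_config(),
                       quantile_type = 7) {
  aggregator <- match.arg(aggregator)
  stopifnot(quantile_type %in% c(1, 7))
  structure(list(aggregator = aggregator,
                 similarity_config = similarity_config,
                 quantile_type = quantile_type),
            class = "sdi_config")
}

#' Penalty score of one term
#'
#' Collapses the pairwise similarities of a term to the other members of its
#' gene's term cluster into a single penalty in `[0, 1]`. The single-term
#' case (penalty 1 by definition) is handled by the caller, not here.
#'
#' @param similarities non-empty numeric vector of similarities in `[0, 1]`
#'   (the n-1 values `s(i, j)` for `j != i`).
#' @param aggregator `"rms"`, `"arithmetic_mean"` or `"geometric_mean"`.
#' @return Penalty in `[0, 1]`.
#' @export
penalty <- function(similarities, aggregator = "rms") {
  if (!length(similarities)) {
    stop("penalty() requires a non-empty similarity vector")
  }
  if (any(is.na(similarities)) || any(similarities < 0) ||
      any(similarities > 1)) {
    stop("similarities must lie in [0, 1]")
  }
  switch(aggregator,
    rms = sqrt(mean(similarities^2)),
    arithmetic_mean = mean(similarities),
    # limit convention: a zero similarity annihilates the geometric mean
    geometric_mean = if (any(similarities == 0)) 0 else
      exp(mean(log(similarities))),
    stop("unknown aggregator: ", aggregator)
  )
}

new_sdi_result <- function(gene_id, terms, penalties) {
  structure(list(gene_id = gene_id, n = length(terms), terms = terms,
                 penalties = penalties, sdi = sum(1 - penalties)),
            class = "sdi_result")
}

#' @export
print.sdi_result <- function(x, ...) {
  cat(sprintf("<sdi_result> %s: n = %d, SDI = %.3f\n", x$gene_id, x$n, x$sdi))
  invisible(x)
}

#' SDI of one gene
#'
#' @param annotation a [gene_annotation()].
#' @param dag an [ontology_dag()].
#' @param config an [sdi_config()].
#' @param cache optional profile cache environment shared across genes.
#' @return Object of class `sdi_result` with fields `gene_id`, `n`, `terms`
#'   (lexicographic order, fixing the penalty order), `penalties`, `sdi`.
#' @export
gene_sdi <- function(annotation, dag, config = sdi_config(), cache = NULL) {
  terms <- vapply(annotation$terms, function(t) {
    r <- resolve_term(dag, t)
    if (is.na(r)) {
      stop("gene ", annotation$gene_id, ": unknown term ", t)
    }
    r
  }, character(1), USE.NAMES = FALSE)
  terms <- sort(unique(terms))
  n <- length(terms)
  if (n == 1L) {
    return(new_sdi_result(annotation$gene_id, terms, 1))
  }
  sc <- config$similarity_config
  p <- vapply(seq_len(n), function(i) {
    s <- vapply(setdiff(seq_len(n), i), function(j) {
      term_similarity(dag, terms[i], terms[j], sc, cache)
    }, numeric(1))
    penalty(s, config$aggregator)
  }, numeric(1))
  new_sdi_result(annotation$gene_id, terms, p)
}

# Vectorized penalties for one gene given the pairwise similarity submatrix
# (unit diagonal). Exploits that the diagonal contributes exactly 1 to the
# row sums of squares / sums / log-sums.
penalties_from_matrix <- function(m, aggregator) {
  n <- nrow(m)
  switch(aggregator,
    rms = sqrt((rowSums(m^2) - 1) / (n - 1)),
    arithmetic_mean = (rowSums(m) - 1) / (n - 1),
    geometric_mean = {
      lm <- suppressWarnings(log(m))   # log(0) = -Inf -> gmean 0
      exp(rowSums(lm) / (n - 1))
    },
    stop("unknown aggregator: ", aggregator)
  )
}

#' Score a genome
#'
#' Computes the SDI for every annotated gene plus a distribution summary
#' (minimum, quartiles, median, mean, maximum, gene count). Each distinct
#' term's semantic profile is computed once: all pairwise similarities among
#' annotated terms are assembled into one matrix and genes are scored from
#' submatrices, so the output is independent of gene iteration order.
#'
#' @param annotations named list of [gene_annotation()] (as returned by
#'   [parse_gene2go()] or [make_annotations()]).
#' @param dag an [ontology_dag()].
#' @param config an [sdi_config()].
#' @param strict if `TRUE` (default) an unresolvable term aborts with the
#'   gene named; if `FALSE` the gene is skipped with a warning.
#' @return Object of class `sdi_scores`: list with `scores` (data frame
#'   `gene_id`, `n_terms`, `sdi`, sorted by gene id), `results` (named list
#'   of `sdi_result`), and `summary` (named numeric: `min`, `q1`, `median`,
#'   `mean`, `q3`, `max`, `genes`).
#' @export
score_genome <- function(annotations, dag, config = sdi_config(),
                         strict = TRUE) {
  if (!length(annotations)) {
    summ <- c(min = NA_real_, q1 = NA_real_, median = NA_real_,
              mean = NA_real_, q3 = NA_real_, max = NA_real_, genes = 0)
    return(structure(list(
      scores = data.frame(gene_id = character(), n_terms = integer(),
                          sdi = numeric(), stringsAsFactors = FALSE),
      results = list(), summary = summ, config = config
    ), class = "sdi_scores"))
  }
  resolved <- vector("list", length(annotations))
  keep <- rep(TRUE, length(annotations))
  for (i in seq_along(annotations)) {
    a <- annotations[[i]]
    r <- vapply(a$terms, function(t) resolve_term(dag, t), character(1),
                USE.NAMES = FALSE)
    if (anyNA(r)) {
      msg <- paste0("gene ", a$gene_id, ": unknown term ",
                    a$terms[which(is.na(r))[1]])
      if (strict) stop(msg) else {
        warning(msg, "; gene skipped")
        keep[i] <- FALSE
        next
      }
    }
    resolved[[i]] <- sort(unique(r))
  }
  annotations <- annotations[keep]
  resolved <- resolved[keep]

  all_terms <- sort(unique(unlist(resolved, use.names = FALSE)))
  cache <- new.env(parent = emptyenv())
  M <- term_similarity_matrix(dag, all_terms, config$similarity_config, cache)

  results <- vector("list", length(annotations))
  for (i in seq_along(annotations)) {
    terms <- resolved[[i]]
    p <- if (length(terms) == 1L) 1 else
      unname(penalties_from_matrix(M[terms, terms, drop = FALSE],
                                   config$aggregator))
    results[[i]] <- new_sdi_result(annotations[[i]]$gene_id, terms, p)
  }
  ord <- order(vapply(results, `[[`, character(1), "gene_id"))
  results <- results[ord]
  names(results) <- vapply(results, `[[`, character(1), "gene_id")

  scores <- data.frame(
    gene_id = names(results),
    n_terms = vapply(results, `[[`, integer(1), "n"),
    sdi = vapply(results, `[[`, numeric(1), "sdi"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  q <- stats::quantile(scores$sdi, c(0.25, 0.5, 0.75),
                       type = config$quantile_type, names = FALSE)
  summ <- c(min = min(scores$sdi), q1 = q[1], median = q[2],
            mean = mean(scores$sdi), q3 = q[3], max = max(scores$sdi),
            genes = nrow(scores))
  structure(list(scores = scores, results = results, summary = summ,
                 config = config),
            class = "sdi_scores")
}

#' @export
print.sdi_scores <- function(x, ...) {
  cat(sprintf("<sdi_scores> %d gene(s), aggregator = %s\n",
              nrow(x$scores), x$config$aggregator))
  if (nrow(x$scores)) {
    cat(sprintf("  SDI: min %.3f | q1 %.3f | median %.3f | mean %.3f | q3 %.3f | max %.3f\n",
                x$summary["min"], x$summary["q1"], x$summary["median"],
                x$summary["mean"], x$summary["q3"], x$summary["max"]))
  }
  invisible(x)
}

#' Write per-gene SDI scores as TSV
#'
#' @param x an `sdi_scores` object.
#' @param path output path.
#' @param full_precision write all digits instead of the 3-decimal display
#'   format.
#' @return Invisibly, the path.
#' @export
write_sdi_scores <- function(x, path, full_precision = FALSE) {
  df <- x$scores
  if (!full_precision) df$sdi <- sprintf("%.3f", df$sdi)
  else df$sdi <- sprintf("%.17g", df$sdi)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the genome summary as a one-row TSV
#'
#' @param x an `sdi_scores` object.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_sdi_summary <- function(x, path) {
  s <- x$summary
  df <- data.frame(minimum = s["min"], first_quartile = s["q1"],
                   median = s["median"], mean = s["mean"],
                   third_quartile = s["q3"], maximum = s["max"],
                   genes = as.integer(s["genes"]), row.names = NULL)
  df[seq_len(6)] <- lapply(df[seq_len(6)], function(v) sprintf("%.3f", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
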