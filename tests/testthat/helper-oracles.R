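# Independent oracles, deliberately naive and kept free of the package's
# memoized code paths.

# Wang S-values by exhaustive path enumeration: S(t) is the max over *all*
# directed child->parent paths from `term` to t of the product of edge
# contribution factors. Exponential; only for small DAGs.
oracle_s_values <- function(dag, term, w_is_a = 0.8, w_part_of = 0.6) {
  w <- c(is_a = w_is_a, part_of = w_part_of)
  best <- new.env(parent = emptyenv())
  walk <- function(t, prod) {
    cur <- best[[t]]
    if (is.null(cur) || prod > cur) assign(t, prod, envir = best)
    e <- dag$edges[dag$edges$child == t, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      walk(e$parent[i], prod * w[[e$relation[i]]])
    }
  }
  walk(term, 1)
  vals <- unlist(as.list(best))
  vals[order(names(vals))]
}

oracle_similarity <- function(dag, a, b, w_is_a = 0.8, w_part_of = 0.6) {
  sa <- oracle_s_values(dag, a, w_is_a, w_part_of)
  sb <- oracle_s_values(dag, b, w_is_a, w_part_of)
  common <- intersect(names(sa), names(sb))
  if (!length(common)) return(0)
  (sum(sa[common]) + sum(sb[common])) / (sum(sa) + sum(sb))
}

# AUC by brute-force all-pairs counting, ties worth one half.
oracle_auc <- function(scores, positives) {
  y <- names(scores) %in% positives
  sp <- scores[y]
  sn <- scores[!y]
  mean(outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Pearson chi-square from first principles on a 2 x k table.
oracle_chisq_p <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  stats::pchisq(stat, df = (nrow(tab) - 1) * (ncol(tab) - 1),
                lower.tail = FALSE)
}
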