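# Validation battery: rank-statistic ROC/AUC, decile enrichment with a
# Pearson chi-square test, Spearman correlation against gene-level features,
# stratified cross-validated logistic regression, and the random-term
# replacement sensitivity analysis.

as_score_vector <- function(scores) {
  if (inherits(scores, "sdi_scores")) {
    return(stats::setNames(scores$scores$sdi, scores$scores$gene_id))
  }
  if (is.data.frame(scores)) {
    return(stats::setNames(scores$sdi, scores$gene_id))
  }
  if (is.numeric(scores) && !is.null(names(scores))) return(scores)
  stop("scores must be a named numeric vector, a score data frame, or an ",
       "sdi_scores object")
}

#' ROC curve and AUC against a label set
#'
#' AUC is the rank statistic: the probability that a randomly chosen positive
#' outscores a randomly chosen negative, ties counted one half. Evaluation is
#' restricted to the scored genes; positives are the intersection of the
#' label set with the scored genes and everything else scored is negative.
#'
#' @param scores named numeric vector of gene scores (higher = predicted
#'   positive), or an `sdi_scores` object / score data frame.
#' @param labels a [label_set()].
#' @return Object of class `roc_report`: `auc`, `roc_points` (data frame
#'   `fpr`, `tpr`, starting at (0,0) and ending at (1,1)), `n_pos`, `n_neg`,
#'   `n`, `label`.
#' @export
roc_auc <- function(scores, labels) {
  s <- as_score_vector(scores)
  y <- names(s) %in% labels$positives
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) {
    stop("undefined AUC: need at least one positive and one negative among ",
         "scored genes (", n_pos, " positives, ", n_neg, " negatives)")
  }
  r <- rank(s)
  auc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(-s)
  ys <- y[ord]
  ss <- s[ord]
  grp_end <- which(ss != c(ss[-1], NA) | seq_along(ss) == length(ss))
  tp <- cumsum(ys)[grp_end]
  fp <- cumsum(!ys)[grp_end]
  roc_points <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  structure(list(auc = auc, roc_points = roc_points, n_pos = n_pos,
                 n_neg = n_neg, n = length(s), label = labels$name),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("<roc_report> %s: AUC = %.3f (%d positives / %d genes)\n",
              x$label, x$auc, x$n_pos, x$n))
  invisible(x)
}

#' Decile enrichment of a label among ranked genes
#'
#' Genes are sorted ascending by score (ties broken by gene id for
#' determinism) and split into 10 contiguous near-equal groups — any
#' remainder is spread over the lowest groups, so group sizes differ by at
#' most one. Group 10 holds the highest scores. Association between group
#' and label is tested with Pearson's chi-square (no continuity correction)
#' on the 2 x 10 contingency table.
#'
#' @param scores named numeric score vector (or `sdi_scores` / data frame).
#' @param labels a [label_set()].
#' @return List: `decile_counts` (data frame `decile`, `n`, `positives`),
#'   `chi_square_stat`, `chi_square_p`, `n_pos`, `n`.
#' @export
decile_enrichment <- function(scores, labels) {
  s <- as_score_vector(scores)
  if (length(s) < 10L) stop("need at least 10 scored genes")
  ord <- order(s, names(s))
  y <- (names(s) %in% labels$positives)[ord]
  n <- length(s)
  base <- n %/% 10L
  rem <- n %% 10L
  sizes <- base + as.integer(seq_len(10L) <= rem)
  grp <- rep(seq_len(10L), times = sizes)
  pos <- tapply(y, grp, sum)
  counts <- data.frame(decile = seq_len(10L), n = sizes,
                       positives = as.integer(pos))
  tab <- rbind(positive = counts$positives,
               negative = counts$n - counts$positives)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    stop("degenerate contingency table: a full row or column is zero")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(decile_counts = counts,
       chi_square_stat = unname(ct$statistic),
       chi_square_p = ct$p.value,
       n_pos = sum(counts$positives), n = n)
}

#' Spearman correlation between scores and a gene feature
#'
#' Computed on the intersection of gene identifiers, with average-rank tie
#' handling and a two-sided p-value (asymptotic t approximation, as
#' appropriate in the presence of ties).
#'
#' @param scores named numeric score vector (or `sdi_scores` / data frame).
#' @param feature named numeric vector of a gene-level feature.
#' @return List: `rho`, `p`, `n` (intersection size).
#' @export
spearman_cor <- function(scores, feature) {
  s <- as_score_vector(scores)
  g <- intersect(names(s), names(feature))
  g <- g[!is.na(feature[g]) & !is.na(s[g])]
  if (length(g) < 3L) stop("need at least 3 genes in the intersection")
  x <- s[g]
  y <- feature[g]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("undefined correlation: constant vector")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(g))
}

# Stratified fold assignment: positives and negatives each dealt round-robin
# into k folds after shuffling.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

auc_from <- function(score, y) {
  r <- rank(score)
  np <- sum(y)
  nn <- sum(!y)
  (sum(r[y]) - np * (np + 1) / 2) / (np * nn)
}

#' Cross-validated logistic regression AUCs
#'
#' Fits a binary logistic regression for each single feature and for the
#' model combining all features, under stratified k-fold cross-validation:
#' the model is fit on the training folds and its held-out predicted
#' probabilities, pooled across folds, are scored by AUC. Complete-case
#' genes only. If a fold ends up single-class the folds are redrawn with a
#' new derived seed, up to 5 attempts.
#'
#' @param features data frame with a `gene_id` column and one or more
#'   numeric feature columns.
#' @param labels a [label_set()].
#' @param folds number of folds (default 10).
#' @param seed integer seed fixing the fold assignment.
#' @return data frame with columns `model` (feature name or
#'   `"all_features"`), `cv_auc`, `slope` (full-data fitted coefficient for
#'   single-feature models, `NA` for the combined model) and `n`.
#' @export
cv_logistic <- function(features, labels, folds = 10, seed = 1) {
  stopifnot(folds >= 2)
  feat_cols <- setdiff(names(features), "gene_id")
  if (!length(feat_cols)) stop("no feature columns")
  cc <- stats::complete.cases(features[feat_cols])
  features <- features[cc, , drop = FALSE]
  y <- features$gene_id %in% labels$positives
  if (sum(y) < folds || sum(!y) < folds) {
    stop("too few genes per class for ", folds, "-fold stratified CV")
  }

  fold <- NULL
  for (attempt in seq_len(5L)) {
    f <- stratified_folds(y, folds, child_seed(seed, attempt))
    ok <- all(vapply(seq_len(folds),
                     function(k) length(unique(y[f == k])) == 2L,
                     logical(1)))
    if (ok) { fold <- f; break }
  }
  if (is.null(fold)) stop("could not build folds with both classes present")

  model_sets <- c(stats::setNames(as.list(feat_cols), feat_cols),
                  list(all_features = feat_cols))
  out <- lapply(names(model_sets), function(mname) {
    cols <- model_sets[[mname]]
    dat <- data.frame(y = y, features[cols], check.names = FALSE)
    pred <- rep(NA_real_, nrow(dat))
    for (k in seq_len(folds)) {
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = dat[fold != k, , drop = FALSE],
                   family = stats::binomial()))
      pred[fold == k] <- suppressWarnings(
        stats::predict(fit, newdata = dat[fold == k, , drop = FALSE],
                       type = "response"))
    }
    slope <- NA_real_
    if (length(cols) == 1L) {
      full <- suppressWarnings(stats::glm(y ~ ., data = dat,
                                          family = stats::binomial()))
      slope <- unname(stats::coef(full)[2])
    }
    data.frame(model = mname, cv_auc = auc_from(pred, y), slope = slope,
               n = nrow(dat), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Perturbation specification
#'
#' Parameters of the annotation-robustness experiment: a random fraction of
#' genes has its whole term set replaced by a random term set whose size is
#' drawn uniformly from `term_count_range` — defaulting to 1–45, the range
#' of actual per-gene GO-CC term counts in human.
#'
#' @param fraction fraction of genes perturbed, in (0, 1].
#' @param term_count_range inclusive integer range for replacement term-set
#'   sizes (default `c(1, 45)`).
#' @param replicates number of independent replicate groups (default 3).
#' @param seed integer seed.
#' @return Object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(fraction, term_count_range = c(1L, 45L),
                              replicates = 3L, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1,
            length(term_count_range) == 2L,
            term_count_range[1] >= 1L,
            term_count_range[2] >= term_count_range[1],
            replicates >= 1L)
  structure(list(fraction = fraction,
                 term_count_range = as.integer(term_count_range),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Randomly replace annotations of a gene subset
#'
#' Per replicate, an independently drawn subset of `ceiling(fraction * G)`
#' genes has its entire term set replaced by `k` terms sampled uniformly
#' without replacement from the ontology, `k` uniform over
#' `term_count_range` (clamped to the ontology size). All other genes are
#' untouched. Fully reproducible from the spec's seed.
#'
#' @param annotations named list of [gene_annotation()].
#' @param dag an [ontology_dag()].
#' @param spec a [perturbation_spec()].
#' @return List of length `spec$replicates`; each element a named list of
#'   [gene_annotation()] parallel to the input.
#' @export
perturb_annotations <- function(annotations, dag, spec) {
  stopifnot(inherits(spec, "perturbation_spec"))
  if (!length(dag$terms)) stop("empty ontology")
  G <- length(annotations)
  n_pert <- max(1L, as.integer(ceiling(spec$fraction * G)))
  if (spec$fraction * G < 1) {
    warning("fraction selects < 1 gene; perturbing 1 gene")
  }
  hi <- min(spec$term_count_range[2], length(dag$terms))
  lo <- min(spec$term_count_range[1], hi)
  lapply(seq_len(spec$replicates), function(r) {
    with_seed(child_seed(spec$seed, r), {
      idx <- resample(seq_len(G), n_pert)
      out <- annotations
      for (i in idx) {
        k <- resample(seq.int(lo, hi), 1L)
        out[[i]] <- gene_annotation(annotations[[i]]$gene_id,
                                    resample(dag$terms, k))
      }
      out
    })
  })
}

#' Annotation-perturbation sensitivity suite
#'
#' For each perturbation fraction and replicate: perturb the annotations,
#' rescore the genome, and evaluate the AUC against the label set. Reports
#' the unperturbed baseline AUC, the per-replicate grid and per-fraction
#' averages (the layout of the robustness table).
#'
#' @param annotations named list of [gene_annotation()].
#' @param dag an [ontology_dag()].
#' @param labels a [label_set()].
#' @param fractions numeric vector of perturbation fractions (default
#'   `c(0.05, 0.10, 0.20)`).
#' @param term_count_range replacement-size range (default `c(1, 45)`).
#' @param replicates replicate groups per fraction (default 3).
#' @param seed integer seed; fractions and replicates get derived seeds.
#' @param config an [sdi_config()].
#' @return Object of class `sensitivity_report`: `baseline_auc`, `auc`
#'   (matrix, replicates x fractions), `average` (named numeric per
#'   fraction), `fractions`, `replicates`, `seed`.
#' @export
sensitivity_suite <- function(annotations, dag, labels,
                              fractions = c(0.05, 0.10, 0.20),
                              term_count_range = c(1L, 45L),
                              replicates = 3L, seed = 1L,
                              config = sdi_config()) {
  baseline <- roc_auc(score_genome(annotations, dag, config), labels)$auc
  auc <- matrix(NA_real_, nrow = replicates, ncol = length(fractions),
                dimnames = list(paste("Group", seq_len(replicates)),
                                sprintf("%g%%", 100 * fractions)))
  for (j in seq_along(fractions)) {
    f <- fractions[j]
    if (f == 0) {
      auc[, j] <- baseline
      next
    }
    spec <- perturbation_spec(f, term_count_range, replicates,
                              child_seed(seed, j))
    reps <- perturb_annotations(annotations, dag, spec)
    for (r in seq_len(replicates)) {
      auc[r, j] <- roc_auc(score_genome(reps[[r]], dag, config), labels)$auc
    }
  }
  structure(list(baseline_auc = baseline, auc = auc,
                 average = colMeans(auc), fractions = fractions,
                 replicates = replicates, seed = seed,
                 label = labels$name),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %s: baseline AUC = %.3f\n",
              x$label, x$baseline_auc))
  m <- rbind(x$auc, Average = x$average)
  print(round(m, 3))
  invisible(x)
}

#' Write a sensitivity grid as TSV
#'
#' @param x a `sensitivity_report`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_sensitivity_tsv <- function(x, path) {
  m <- rbind(x$auc, Average = x$average)
  df <- data.frame(baseline = sprintf("%.3f", x$baseline_auc),
                   group = rownames(m),
                   apply(m, 2, function(v) sprintf("%.3f", v)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
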