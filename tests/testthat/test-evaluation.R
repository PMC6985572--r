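test_that("roc_auc: separation, ties, errors, and curve shape", {
  s <- c(a = 3, b = 2, c = 1)
  r <- roc_auc(s, label_set("l", "a"))
  expect_identical(r$auc, 1)

  tied <- roc_auc(c(a = 1, b = 1, c = 1, d = 1), label_set("l", c("a", "c")))
  expect_identical(tied$auc, 0.5)

  expect_error(roc_auc(s, label_set("l", c("a", "b", "c"))), "undefined AUC")

  set.seed(101)
  sc <- stats::setNames(round(stats::rnorm(80), 1), paste0("g", 1:80))
  pos <- paste0("g", sample(80, 30))
  r2 <- roc_auc(sc, label_set("l", pos))
  pts <- r2$roc_points
  expect_equal(pts[1, ], data.frame(fpr = 0, tpr = 0), ignore_attr = TRUE)
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("roc_auc equals the brute-force pair-counting oracle", {
  for (seed in c(2, 9, 27)) {
    set.seed(seed)
    sc <- stats::setNames(round(stats::rnorm(200), 1), paste0("g", 1:200))
    pos <- paste0("g", sample(200, 60))
    expect_equal(roc_auc(sc, label_set("l", pos))$auc, oracle_auc(sc, pos),
                 tolerance = 1e-12)
    # complement property on tie-free scores
    sc2 <- stats::setNames(stats::rnorm(150), paste0("h", 1:150))
    pos2 <- paste0("h", sample(150, 40))
    expect_equal(roc_auc(sc2, label_set("l", pos2))$auc +
                   roc_auc(-sc2, label_set("l", pos2))$auc, 1,
                 tolerance = 1e-12)
  }
})

test_that("decile enrichment: grouping, counts and chi-square", {
  sc <- stats::setNames(as.numeric(1:100), sprintf("g%03d", 1:100))
  top10 <- sprintf("g%03d", 91:100)
  d <- decile_enrichment(sc, label_set("l", top10))
  expect_equal(d$decile_counts$n, rep(10L, 10))
  expect_equal(d$decile_counts$positives, c(rep(0L, 9), 10L))

  # remainder spread over the lowest groups, sizes differ by at most one
  sc2 <- stats::setNames(as.numeric(1:104), sprintf("g%03d", 1:104))
  d2 <- decile_enrichment(sc2, label_set("l", sprintf("g%03d", 100:104)))
  expect_equal(d2$decile_counts$n, c(rep(11L, 4), rep(10L, 6)))
  expect_equal(sum(d2$decile_counts$n), 104L)

  # chi-square p equals a first-principles evaluation of the same table
  tab <- rbind(d2$decile_counts$positives,
               d2$decile_counts$n - d2$decile_counts$positives)
  expect_equal(d2$chi_square_p, oracle_chisq_p(tab), tolerance = 1e-12)

  expect_error(decile_enrichment(sc[1:5], label_set("l", "g001")),
               "at least 10")
  expect_error(decile_enrichment(sc, label_set("l", "absent")),
               "degenerate")
})

test_that("uniform labels give non-extreme chi-square p (null sanity)", {
  hits <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    sc <- stats::setNames(stats::rnorm(1000), paste0("g", 1:1000))
    pos <- paste0("g", sample(1000, 300))
    p <- decile_enrichment(sc, label_set("l", pos))$chi_square_p
    hits <- hits + (p > 0.01)
  }
  expect_gte(hits, 4L)
})

test_that("spearman matches rank-then-pearson and validates input", {
  sc <- stats::setNames(stats::runif(50), paste0("g", 1:50))
  expect_equal(spearman_cor(sc, sc)$rho, 1, tolerance = 1e-12)
  expect_equal(spearman_cor(sc, -sc)$rho, -1, tolerance = 1e-12)

  set.seed(8)
  feat <- stats::setNames(round(stats::rnorm(50), 1), names(sc))  # ties
  got <- spearman_cor(sc, feat)
  expect_equal(got$rho, stats::cor(rank(sc), rank(feat)), tolerance = 1e-12)
  expect_equal(got$n, 50L)

  expect_error(spearman_cor(sc[1:2], feat[1:2]), "at least 3")
  expect_error(spearman_cor(sc, stats::setNames(rep(1, 50), names(sc))),
               "constant")
})

test_that("cv_logistic: self-predicting, noise, and determinism", {
  set.seed(55)
  n <- 500
  x <- stats::rnorm(n)
  y <- stats::runif(n) < stats::plogis(3 * x)
  genes <- paste0("g", seq_len(n))
  feats <- data.frame(gene_id = genes, signal = x, noise = stats::rnorm(n))
  labs <- label_set("l", genes[y])

  res <- cv_logistic(feats, labs, folds = 10, seed = 3)
  expect_setequal(res$model, c("signal", "noise", "all_features"))
  expect_gt(res$cv_auc[res$model == "signal"], 0.9)
  expect_gt(res$slope[res$model == "signal"], 0)
  expect_true(res$cv_auc[res$model == "noise"] > 0.4 &&
                res$cv_auc[res$model == "noise"] < 0.6)
  expect_identical(res, cv_logistic(feats, labs, folds = 10, seed = 3))
  expect_error(cv_logistic(feats[1:8, ], labs, folds = 10), "too few")
})

test_that("perturbation: forced n=1 rule, determinism, exact counts", {
  w <- random_world(61, n_genes = 40, term_count_range = c(2L, 5L))
  spec1 <- perturbation_spec(1, c(1L, 1L), replicates = 1L, seed = 5L)
  pert <- perturb_annotations(w$annotations, w$dag, spec1)[[1]]
  scored <- score_genome(pert, w$dag)
  expect_true(all(scored$scores$n_terms == 1L))
  expect_true(all(scored$scores$sdi == 0))

  spec2 <- perturbation_spec(0.1, c(1L, 5L), replicates = 3L, seed = 9L)
  p1 <- perturb_annotations(w$annotations, w$dag, spec2)
  p2 <- perturb_annotations(w$annotations, w$dag, spec2)
  expect_identical(p1, p2)

  for (rep in p1) {
    changed <- vapply(names(rep), function(g)
      !identical(rep[[g]], w$annotations[[g]]), logical(1))
    expect_equal(sum(changed), 4L)   # ceiling(0.1 * 40)
  }
  expect_error(perturbation_spec(0), "fraction")
})

test_that("sensitivity suite: zero fraction equals baseline; grid shape", {
  w <- random_world(71, n_terms = 25, n_genes = 60,
                    term_count_range = c(1L, 5L))
  scored <- score_genome(w$annotations, w$dag)
  labs <- make_labels(scored, c(-1, 1.2), seed = 4)
  rep <- sensitivity_suite(w$annotations, w$dag, labs,
                           fractions = c(0, 0.2),
                           term_count_range = c(1L, 5L),
                           replicates = 3L, seed = 6L)
  expect_equal(dim(rep$auc), c(3L, 2L))
  expect_true(all(rep$auc[, 1] == rep$baseline_auc))
  expect_equal(unname(rep$average), unname(colMeans(rep$auc)))
  # same seed reproduces the grid
  rep2 <- sensitivity_suite(w$annotations, w$dag, labs,
                            fractions = c(0, 0.2),
                            term_count_range = c(1L, 5L),
                            replicates = 3L, seed = 6L)
  expect_identical(rep$auc, rep2$auc)
})
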