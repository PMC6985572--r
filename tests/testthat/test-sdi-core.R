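test_that("penalty aggregators match hand arithmetic and validate input", {
  expect_equal(penalty(4 / 9, "rms"), 4 / 9, tolerance = 1e-12)
  expect_equal(penalty(c(0.6, 0.8), "rms"), sqrt(0.5), tolerance = 1e-12)
  expect_equal(penalty(c(0.6, 0.8), "arithmetic_mean"), 0.7,
               tolerance = 1e-12)
  expect_identical(penalty(c(0, 0.5), "geometric_mean"), 0)
  expect_equal(penalty(c(0.4, 0.9), "geometric_mean"), sqrt(0.36),
               tolerance = 1e-12)
  expect_error(penalty(numeric(0)), "non-empty")
  expect_error(penalty(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(penalty(0.5, "median"), "unknown aggregator")
})

test_that("single-term gene: penalty exactly 1, SDI exactly 0", {
  dag <- tiny_dag()
  res <- gene_sdi(gene_annotation("g", "GO:0000002"), dag)
  expect_identical(res$penalties, 1)
  expect_identical(res$sdi, 0)
  expect_equal(res$n, 1L)
})

test_that("two-term worked example and duplicate-term collapse", {
  dag <- tiny_dag()
  res <- gene_sdi(gene_annotation("g", c("GO:0000002", "GO:0000003")), dag)
  expect_equal(res$penalties, rep(4 / 9, 2), tolerance = 1e-9)
  expect_equal(res$sdi, 2 * (1 - 4 / 9), tolerance = 1e-9)

  dup <- gene_sdi(gene_annotation("g", c("GO:0000002", "GO:0000002")), dag)
  expect_identical(dup$sdi, 0)
  expect_equal(dup$n, 1L)

  expect_error(gene_sdi(gene_annotation("g", "GO:9999999"), dag),
               "gene g: unknown term")
})

test_that("n = 2 closed form: SDI = 2 (1 - s), strictly decreasing in s", {
  w <- random_world(13, n_terms = 30, n_genes = 30,
                    term_count_range = c(2L, 2L))
  scored <- score_genome(w$annotations, w$dag)
  for (r in scored$results) {
    s <- term_similarity(w$dag, r$terms[1], r$terms[2])
    expect_equal(r$sdi, 2 * (1 - s), tolerance = 1e-9)
  }
  sims <- vapply(scored$results, function(r)
    term_similarity(w$dag, r$terms[1], r$terms[2]), numeric(1))
  ord <- order(sims)
  expect_true(all(diff(scored$scores$sdi[ord]) <= 1e-12))
})

test_that("bounds and permutation invariance", {
  w <- random_world(29, n_genes = 25, term_count_range = c(1L, 6L))
  scored <- score_genome(w$annotations, w$dag)
  expect_true(all(scored$scores$sdi >= -1e-12))
  expect_true(all(scored$scores$sdi <= scored$scores$n_terms + 1e-12))
  for (r in scored$results) {
    expect_true(all(r$penalties >= -1e-12 & r$penalties <= 1 + 1e-12))
    expect_equal(r$sdi, sum(1 - r$penalties), tolerance = 1e-9)
  }
  # shuffled term input gives identical results
  a <- w$annotations[[which.max(scored$scores$n_terms)]]
  shuffled <- gene_annotation(a$gene_id, rev(a$terms))
  expect_equal(gene_sdi(shuffled, w$dag), gene_sdi(a, w$dag))
})

test_that("aggregator ordering follows the power-mean inequality", {
  w <- random_world(41, n_genes = 20, term_count_range = c(3L, 6L))
  sdi_of <- function(agg) {
    score_genome(w$annotations, w$dag, sdi_config(aggregator = agg))$scores$sdi
  }
  rms <- sdi_of("rms")
  am <- sdi_of("arithmetic_mean")
  gm <- sdi_of("geometric_mean")
  expect_true(all(rms <= am + 1e-9))
  expect_true(all(am <= gm + 1e-9))
  expect_true(any(rms < am - 1e-9 & am < gm - 1e-9))
})

test_that("score_genome agrees with per-gene gene_sdi (dual route)", {
  w <- random_world(37, n_genes = 15, term_count_range = c(1L, 5L))
  scored <- score_genome(w$annotations, w$dag)
  for (g in names(w$annotations)) {
    expect_equal(scored$results[[g]]$sdi,
                 gene_sdi(w$annotations[[g]], w$dag)$sdi, tolerance = 1e-9)
  }
})

test_that("genome summary matches an independent recompute", {
  w <- random_world(43, n_genes = 100, term_count_range = c(1L, 5L))
  scored <- score_genome(w$annotations, w$dag)
  x <- scored$scores$sdi
  expect_identical(unname(scored$summary["min"]), min(x))
  expect_identical(unname(scored$summary["max"]), max(x))
  expect_equal(unname(scored$summary["mean"]), mean(x), tolerance = 1e-12)
  expect_equal(unname(scored$summary[c("q1", "median", "q3")]),
               unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7)),
               tolerance = 1e-12)
  expect_identical(unname(scored$summary["genes"]), 100)
  # at least one single-term gene forces the genome minimum to 0
  expect_true(any(scored$scores$n_terms == 1L))
  expect_identical(unname(scored$summary["min"]), 0)
})

test_that("empty collection, lenient skipping and writers", {
  dag <- tiny_dag()
  empty <- score_genome(stats::setNames(list(), character()), dag)
  expect_equal(nrow(empty$scores), 0L)
  expect_identical(unname(empty$summary["genes"]), 0)

  anns <- list(g1 = gene_annotation("g1", "GO:0000002"),
               gx = gene_annotation("gx", "GO:9999999"))
  expect_error(score_genome(anns, dag), "gene gx: unknown term")
  expect_warning(len <- score_genome(anns, dag, strict = FALSE), "skipped")
  expect_equal(len$scores$gene_id, "g1")

  scored <- score_genome(anns["g1"], dag)
  f <- tempfile(fileext = ".tsv")
  write_sdi_scores(scored, f)
  out <- utils::read.delim(f, colClasses = c(gene_id = "character"))
  expect_equal(out$gene_id, "g1")
  expect_match(readLines(f)[2], "\t0\\.000$")   # 3-decimal display format
  write_sdi_summary(scored, f)
  expect_equal(utils::read.delim(f)$genes, 1L)
})
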