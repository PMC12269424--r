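test_that("query validation enforces provider and background constraints", {
  expect_error(enrichment_query(character(0)), "empty")
  expect_error(enrichment_query(c("a", "b"), background_genes = "a"),
               "missing: b")
  # ToppGene forbids a custom background, before any network call
  expect_error(enrichment_query(c("a", "b"), background_genes = c("a", "b", "c"),
                                provider = "toppgene"),
               "background")
  q <- enrichment_query(c("a", "b"), provider = "toppgene")
  expect_s3_class(q, "EnrichmentQuery")
})

test_that("the 5-of-5 overlap in a 20-gene universe gives p = 1/C(20,5)", {
  universe <- paste0("g", 1:20)
  term <- list(T1 = universe[1:5])
  res <- enrich_offline(universe[1:5], universe, term, alpha = 1)
  expect_equal(res$table$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  # single term: Bonferroni x1 leaves p unchanged
  expect_equal(res$table$p_adjusted, res$table$p_value)
  expect_equal(res$table$p_value, 6.4499e-5, tolerance = 1e-4)
})

test_that("offline p-values match exhaustive enumeration for small universes", {
  set.seed(61)
  for (rep in 1:25) {
    N <- sample(8:25, 1)
    universe <- paste0("g", seq_len(N))
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    term_genes <- sample(universe, K)
    query <- sample(universe, n)
    res <- enrich_offline(query, universe, list(T = term_genes), alpha = 1)
    kobs <- length(intersect(query, term_genes))
    if (kobs == 0) {
      expect_equal(nrow(res$table), 0) # empty result is valid, not an error
    } else {
      expect_equal(res$table$p_value, hyper_tail_oracle(kobs, K, N, n),
                   tolerance = 1e-12)
    }
  }
})

test_that("p is monotone decreasing in overlap at fixed sizes", {
  # direct property of the tail: grow overlap, keep term/query/universe sizes
  N <- 30; K <- 10; n <- 8
  ps <- vapply(0:8, function(k) hyper_tail_oracle(k, K, N, n), 0.0)
  universe <- paste0("g", 1:N)
  got <- vapply(1:8, function(k) {
    term <- c(universe[1:k], universe[(n + 1):(n + K - k)])
    enrich_offline(universe[1:n], universe, list(T = term),
                   alpha = 1)$table$p_value
  }, 0.0)
  expect_equal(got, ps[-1], tolerance = 1e-12)
  expect_true(all(diff(got) <= 1e-15))
})

test_that("Bonferroni multiplies by the number of terms tested, capped at 1", {
  universe <- paste0("g", 1:20)
  one <- enrich_offline(universe[1:5], universe, list(A = universe[1:5]),
                        alpha = 1)
  two <- enrich_offline(universe[1:5], universe,
                        list(A = universe[1:5], B = universe[1:5]), alpha = 1)
  expect_equal(two$table$p_adjusted, rep(2 * one$table$p_value, 2),
               tolerance = 1e-12)
  # weak overlap: adjusted value never exceeds 1
  weak <- enrich_offline(universe[1:5], universe,
                         list(A = universe[5:18], B = universe[4:19]),
                         alpha = 1)
  expect_true(all(weak$table$p_adjusted <= 1))
  expect_error(enrich_offline("a", character(0), list(T = "a")), "background")
})

test_that("overlap genes keep query order and unknown terms error", {
  universe <- paste0("g", 1:12)
  query <- c("g3", "g1", "g7", "g5")
  res <- enrich_offline(query, universe,
                        list(T1 = c("g1", "g3", "g9"), T2 = c("g5")),
                        alpha = 1)
  expect_identical(genes_for_term(res, "T1"), c("g3", "g1"))
  expect_identical(genes_for_term(res, "T2"), "g5")
  expect_error(genes_for_term(res, "T99"), "unknown term")
  # round-trip through CSV preserves the overlap list
  f <- withr::local_tempfile(fileext = ".csv")
  write_table(res$table, f)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_identical(strsplit(back$overlap[back$term_id == "T1"], ";")[[1]],
                   c("g3", "g1"))
})

test_that("term tables parse from two-column TSV and GMT", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("GO:1\tgA\tfirst term", "GO:1\tgB\tfirst term", "GO:2\tgC\tsecond"),
             tsv)
  tt <- read_term_table(tsv)
  expect_setequal(tt$genes[["GO:1"]], c("gA", "gB"))
  expect_equal(tt$names[["GO:2"]], "second")
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("GO:9\tninth term\tgX\tgY\tgZ", "GO:8\teighth\tgX"), gmt)
  tg <- read_term_table(gmt)
  expect_setequal(tg$genes[["GO:9"]], c("gX", "gY", "gZ"))
  expect_equal(tg$names[["GO:9"]], "ninth term")
})

test_that("provider request builders pin the documented payloads", {
  panel <- paste0("g", 1:500)
  q <- enrichment_query(panel[1:40], background_genes = panel,
                        provider = "gprofiler")
  req <- spacomod:::build_gprofiler_request(q)
  # SRT-panel query carries the full measured panel as background
  expect_length(req$body$background, 500)
  expect_identical(req$body$domain_scope, "custom")
  expect_identical(req$body$significance_threshold_method, "bonferroni")
  # transcriptome-wide query: no background field at all
  qw <- enrichment_query(panel[1:40], provider = "gprofiler")
  expect_null(spacomod:::build_gprofiler_request(qw)$body$background)
  qt <- enrichment_query(panel[1:40], provider = "toppgene")
  reqt <- spacomod:::build_toppgene_request(qt)
  expect_identical(reqt$body$Categories[[1]]$Correction, "Bonferroni")
  expect_length(reqt$body$Symbols, 40)
})
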