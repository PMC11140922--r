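test_that("hypergeometric term enrichment matches closed forms", {
  universe <- sprintf("g%02d", 1:20)
  terms <- make_terms(list(t1 = universe[1:5], t2 = universe[6:15]))
  rep <- term_enrichment(universe[1:5], terms, universe)
  # candidates exactly the term's genes: p = 1/C(20,5)
  expect_equal(rep$table$p[rep$table$term_id == "t1"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_true(rep$table$enriched[rep$table$term_id == "t1"])
  # zero overlap: upper tail includes 0 -> p = 1, not enriched
  t0 <- make_terms(list(t3 = universe[16:20]))
  rep0 <- term_enrichment(universe[1:5], t0, universe)
  expect_equal(rep0$table$p, 1)
  expect_false(rep0$table$enriched)
  expect_error(term_enrichment(character(0), terms, universe), "empty")
  expect_error(term_enrichment("nope", terms, universe), "universe")
})

test_that("random candidate draws enrich ~5% of terms", {
  set.seed(71)
  universe <- sprintf("g%03d", 1:200)
  terms <- make_terms(setNames(
    lapply(1:150, function(i) sample(universe, sample(5:40, 1))),
    sprintf("t%03d", 1:150)))
  hits <- replicate(40, {
    rep <- term_enrichment(sample(universe, 30), terms, universe)
    mean(rep$table$enriched)
  })
  expect_lt(abs(mean(hits) - 0.05), 0.025)
})

test_that("keyword categorization is deterministic, multi-label, and blind", {
  scheme <- category_scheme(list(morphology = c("muscle", "wing"),
                                 growth = c("growth"),
                                 rhythm = c("circadian")))
  terms <- make_terms(list(a = "g1", b = "g2", c = "g3"),
                      defs = list(a = "regulation of muscle growth",
                                  b = "flight muscle development",
                                  c = "dna replication"))
  cz <- categorize_terms(terms, scheme)
  expect_setequal(cz$a, c("morphology", "growth"))
  expect_equal(cz$b, "morphology")
  expect_equal(cz$c, character(0))
  # same term, different gene set (different "analysis") -> same categories
  terms2 <- make_terms(list(a = c("g8", "g9")),
                       defs = list(a = "regulation of muscle growth"))
  expect_equal(categorize_terms(terms2, scheme)$a, cz$a)
  # word-boundary mode rejects substring-only hits
  sw <- category_scheme(list(movement = "port"))
  tr <- make_terms(list(x = "g1"), defs = list(x = "ion transport activity"))
  expect_equal(categorize_terms(tr, sw)$x, "movement")
  expect_equal(categorize_terms(tr, sw, word_boundary = TRUE)$x, character(0))
})

test_that("category binomial test matches the exact binomial sum", {
  scheme <- category_scheme(list(growth = "growth", other = "zzz"))
  # 10 enriched terms, 5 in 'growth'; reference proportion 0.1
  enr <- c(rep(list("growth"), 5), rep(list(character(0)), 5))
  ref <- c(rep(list("growth"), 10), rep(list(character(0)), 90))
  rep <- category_overrepresentation(enr, ref, scheme)
  row <- rep$table[rep$table$category == "growth", ]
  exact <- sum(dbinom(5:10, 10, 0.1))
  expect_equal(row$p, exact, tolerance = 1e-12)
  expect_equal(round(exact, 5), round(1.6349e-3, 5))
  # zero observed -> p = 1
  row0 <- rep$table[rep$table$category == "other", ]
  expect_equal(row0$p, 1)
  # k/n = p0 at large n -> p near 0.5
  enr2 <- c(rep(list("growth"), 30), rep(list(character(0)), 70))
  ref2 <- c(rep(list("growth"), 300), rep(list(character(0)), 700))
  rep2 <- category_overrepresentation(enr2, ref2, scheme)
  expect_lt(abs(rep2$table$p[rep2$table$category == "growth"] - 0.5), 0.06)
})

test_that("term graph uses the overlap coefficient with a threshold", {
  terms <- make_terms(list(a = sprintf("g%d", 1:4),
                           b = sprintf("g%d", c(1, 2, 5:12)),
                           c = sprintf("g%d", 20:24),
                           d = sprintf("g%d", 1:4)))
  g <- build_term_graph(terms, threshold = 0.5)
  expect_equal(g$adjacency["a", "d"], 1)         # identical sets
  expect_equal(g$adjacency["a", "c"], 0)         # disjoint
  # |a n b| = 2, min size 4 -> 0.5, at threshold -> kept
  expect_equal(g$adjacency["a", "b"], 0.5)
  g2 <- build_term_graph(terms, threshold = 0.6)
  expect_equal(g2$adjacency["a", "b"], 0)
})

test_that("MCL separates disconnected components and singletons", {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 0
  cl <- mcl_cluster(list(nodes = letters[1:6], adjacency = A))
  expect_length(cl, 2L)
  expect_setequal(lapply(cl, sort), list(c("a", "b", "c"), c("d", "e", "f")))
  single <- mcl_cluster(list(nodes = "x", adjacency = matrix(0, 1, 1)))
  expect_equal(single, list("x"))
  expect_error(mcl_cluster(list(nodes = "x", adjacency = matrix(0, 1, 1)),
                           inflation = 1), "inflation")
})

test_that("MCL output is invariant to node order", {
  g <- planted_graph(c(4, 4, 4), between = 0.1, seed = 5)
  base <- canonical_clusters(mcl_cluster(g))
  perm <- sample(length(g$nodes))
  gp <- list(nodes = g$nodes[perm], adjacency = g$adjacency[perm, perm])
  permuted <- canonical_clusters(mcl_cluster(gp))
  expect_equal(base, permuted)
  expect_setequal(unlist(base), g$nodes)  # partition covers every node once
  expect_equal(length(unlist(base)), length(g$nodes))
})

test_that("cluster descriptors follow the four-most-common-words rule", {
  terms <- make_terms(
    list(t1 = sprintf("g%d", 1:3), t2 = sprintf("g%d", 1:2), t3 = "g9"),
    defs = list(t1 = "regulation of muscle growth",
                t2 = "muscle tissue growth and muscle repair",
                t3 = "wing disc morphogenesis"))
  cz <- list(t1 = "morphology", t2 = c("morphology", "growth"),
             t3 = character(0))
  d <- describe_clusters(list(c("t1", "t2"), "t3"), terms, cz)
  # tokens: muscle x3, growth x2, others x1 (ties alphabetical)
  expect_equal(d$descriptor[1], "muscle, growth, regulation, repair")
  expect_equal(d$category_hits[1], 3L)
  expect_equal(d$categories[2], "n/a")
  # vocabulary exhausted below four words
  t_small <- make_terms(list(s = "g1"), defs = list(s = "regulation of muscle growth"))
  ds <- describe_clusters(list("s"), t_small, list(s = character(0)))
  expect_equal(ds$descriptor, "growth, muscle, regulation")
})

test_that("well-supported flag follows the 10-hits / 5-genes rule", {
  mk_cluster <- function(n_terms, genes_per_term, cats_per_term) {
    ids <- sprintf("q%d", seq_len(n_terms))
    terms <- make_terms(setNames(lapply(seq_len(n_terms), function(i) {
      sprintf("gg%d_%d", i, seq_len(genes_per_term))
    }), ids), defs = setNames(as.list(rep("x y", n_terms)), ids))
    cz <- setNames(lapply(seq_len(n_terms), function(i) {
      sprintf("cat%d", seq_len(cats_per_term))
    }), ids)
    describe_clusters(list(ids), terms, cz)
  }
  expect_true(mk_cluster(4, 1, 3)$well_supported)    # 12 category hits
  expect_true(mk_cluster(1, 5, 1)$well_supported)    # 5 supporting genes
  expect_false(mk_cluster(2, 2, 1)$well_supported)   # 2 hits, 4 genes
})
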