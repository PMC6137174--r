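# Deterministic walk behavior is checked by exhaustive enumeration on tiny
# graphs; stochastic behavior by empirical frequencies at a fixed seed.

test_that("walks on a path graph are forced by the no-revisit rule", {
  net <- toy_network(list(c("A", "B"), c("B", "C"), c(1, 1)))
  progwalk:::with_seed(1, {
    for (i in 1:20) {
      expect_identical(random_walk(net, "A"), c("A", "B", "C"))
    }
  })
})

test_that("walks from the middle of a path graph split evenly", {
  net <- toy_network(list(c("A", "B"), c("B", "C"), c(1, 1)))
  ends <- progwalk:::with_seed(2, {
    vapply(1:1000, function(i) {
      p <- random_walk(net, "B")
      expect_length(p, 2)
      p[2]
    }, "")
  })
  expect_lt(abs(mean(ends == "A") - 0.5), 0.05)
})

test_that("star-graph walks from a leaf always traverse the hub", {
  net <- toy_network(list(c("H", "H", "H"), c("L1", "L2", "L3"), c(1, 1, 1)))
  progwalk:::with_seed(3, {
    for (i in 1:20) {
      p <- random_walk(net, "L1")
      expect_length(p, 3)
      expect_identical(p[1:2], c("L1", "H"))
      expect_true(p[3] %in% c("L2", "L3"))
    }
  })
})

test_that("max_path_length = 1 yields a single-node path", {
  net <- toy_network(list(c("A", "B"), c("B", "C"), c(1, 1)))
  expect_identical(random_walk(net, "B", walk_config(max_path_length = 1)),
                   "B")
  expect_error(random_walk(net, "Z"), "not a node")
})

test_that("first-step choice is proportional to edge weight", {
  # hub X with neighbors weighted 0.5 / 0.8 / 0.6 / 0.9
  w <- c(0.5, 0.8, 0.6, 0.9)
  net <- toy_network(list(rep("X", 4), c("a", "b", "c", "d"), w))
  firsts <- progwalk:::with_seed(17, {
    vapply(1:10000, function(i) random_walk(net, "X")[2], "")
  })
  obs <- table(factor(firsts, levels = c("a", "b", "c", "d")))
  p <- stats::chisq.test(obs, p = w / sum(w))$p.value
  expect_gt(p, 0.01)
})

test_that("corpus initiates walks_per_node walks per node and labels by source", {
  co <- small_cohort()
  g <- quiet(build_correlation_network(co$data, "good", co$network))
  p <- quiet(build_correlation_network(co$data, "poor", co$network))
  cfg <- walk_config(seed = 5)
  corp <- quiet(generate_corpus(g, p, co$data$gene_ids, cfg))
  expect_identical(corp$n_walks,
                   10L * (length(g$nodes) + length(p$nodes)))
  paths <- c(corp$train, corp$validation)
  # every path respects the Path invariants
  for (pp in paths) {
    expect_false(any(duplicated(pp$genes)))
    expect_lte(length(pp$genes), cfg$max_path_length)
    expect_gte(length(pp$genes), 1)
    if (length(pp$genes) > 1) {
      net <- if (pp$label == "good") g else p
      key <- paste(pmin(net$edges$from, net$edges$to),
                   pmax(net$edges$from, net$edges$to))
      steps <- paste(pmin(pp$genes[-length(pp$genes)], pp$genes[-1]),
                     pmax(pp$genes[-length(pp$genes)], pp$genes[-1]))
      expect_true(all(steps %in% key))
    }
  }
  # no ordered sequence appears under both labels
  key <- vapply(paths, function(x) paste(x$genes, collapse = ","), "")
  lab <- vapply(paths, `[[`, "", "label")
  expect_length(intersect(key[lab == "good"], key[lab == "poor"]), 0)
  # split proportions within one path of 80/20
  n <- length(paths)
  expect_lte(abs(length(corp$train) - 0.8 * n), 1)
  # gene index covers the full expression gene set
  expect_identical(names(corp$gene_index), co$data$gene_ids)
})

test_that("corpus generation is reproducible and empty networks are rejected", {
  co <- small_cohort()
  g <- quiet(build_correlation_network(co$data, "good", co$network))
  p <- quiet(build_correlation_network(co$data, "poor", co$network))
  a <- quiet(generate_corpus(g, p, co$data$gene_ids, walk_config(seed = 9)))
  b <- quiet(generate_corpus(g, p, co$data$gene_ids, walk_config(seed = 9)))
  expect_identical(a$train, b$train)
  expect_identical(a$validation, b$validation)
  empty <- progwalk:::correlation_network(
    "poor", data.frame(from = character(), to = character(),
                       weight = numeric()))
  expect_error(quiet(generate_corpus(g, empty, co$data$gene_ids)), "poor")
})

test_that("cross-label dedup removes shared sequences from both labels", {
  genes <- c("A", "B", "C", "D")
  # both networks are the single edge A-B, so every walk is A,B or B,A and
  # every ordered sequence occurs under both labels
  g1 <- toy_network(list("A", "B", 1), group = "good")
  g2 <- toy_network(list("A", "B", 0.9), group = "poor")
  cfg <- walk_config(walks_per_node = 2, seed = 2)
  corp <- quiet(generate_corpus(g1, g2, genes, cfg))
  expect_identical(corp$n_walks, 8L)
  expect_identical(corp$n_removed, 8L)
  expect_length(c(corp$train, corp$validation), 0)
})

test_that("paths encode to multi-hot vectors over the gene index", {
  idx <- stats::setNames(1:4, c("g1", "g2", "g3", "g4"))
  expect_identical(encode_path(c("g1", "g3"), idx), c(1, 0, 1, 0))
  expect_identical(encode_path(character(), idx), numeric(4))
  expect_identical(encode_path(c("g4", "g3", "g2", "g1"), idx), rep(1, 4))
  expect_error(encode_path("gX", idx), "not in index")
})

test_that("path frequencies count paths per gene and label", {
  genes <- c("A", "B", "C", "D")
  corp <- toy_corpus(
    list(path_of(c("A", "B"), "good"), path_of(c("A"), "good"),
         path_of(c("A", "C"), "good")),
    list(path_of(c("A", "B"), "poor")),
    genes)
  fr <- path_frequencies(corp)
  expect_identical(fr$good[fr$gene == "A"], 3L)
  expect_identical(fr$poor[fr$gene == "A"], 1L)
  expect_identical(fr$good[fr$gene == "B"], 1L)
  expect_identical(unname(unlist(fr[fr$gene == "D", c("good", "poor")])),
                   c(0L, 0L))
  # double-counting identity: total good counts = sum of good path set sizes
  expect_identical(sum(fr$good), 2L + 1L + 2L)
})

test_that("corpus serialization writes one labeled path per line", {
  corp <- toy_corpus(list(path_of(c("A", "B"), "good")),
                     list(path_of(c("C"), "poor")),
                     c("A", "B", "C"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(corp, tmp)
  expect_identical(readLines(tmp),
                   c("train\tgood\tA,B", "validation\tpoor\tC"))
})
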