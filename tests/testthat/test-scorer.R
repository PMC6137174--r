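# Embeddings with known geometry are built directly so that clustering,
# L-group labeling and scoring can be checked against enumerable answers.

fake_embedding <- function(W, trained) {
  structure(list(weights = W,
                 gene_index = stats::setNames(seq_len(nrow(W)), rownames(W)),
                 trained_mask = stats::setNames(trained, rownames(W)),
                 model = list(W = W, V = numeric(ncol(W)), b = 0)),
            class = "gene_embedding")
}

three_blob_embedding <- function(n_per = 10, m = 4, seed = 6) {
  progwalk:::with_seed(seed, {
    centers <- rbind(rep(0, m), c(20, rep(0, m - 1)), c(-20, rep(0, m - 1)))
    W <- do.call(rbind, lapply(1:3, function(k)
      sweep(matrix(rnorm(n_per * m, sd = 0.1), n_per, m), 2,
            centers[k, ], "+")))
    rownames(W) <- sprintf("g%02d", seq_len(3 * n_per))
    fake_embedding(W, trained = rep(c(FALSE, TRUE, TRUE), each = n_per))
  })
}

test_that("K-means recovers separated blobs deterministically", {
  emb <- three_blob_embedding()
  cl <- cluster_embeddings(emb, k = 3, seed = 4)
  truth <- rep(1:3, each = 10)
  expect_identical(length(unique(cl)), 3L)
  # same partition up to label permutation
  expect_identical(unname(apply(table(cl, truth) > 0, 1, sum)), rep(1L, 3))
  expect_identical(cl, cluster_embeddings(emb, k = 3, seed = 4))
  tiny <- fake_embedding(diag(3) * 10 + 0, rep(TRUE, 3))
  rownames(tiny$weights) <- c("a", "b", "c")
  tiny$trained_mask <- stats::setNames(rep(TRUE, 3), c("a", "b", "c"))
  expect_identical(length(unique(cluster_embeddings(tiny, k = 3, seed = 1))), 3L)
  expect_error(cluster_embeddings(tiny, k = 4), "fewer genes")
})

test_that("L-groups are labeled by untrained count and frequency majority", {
  emb <- three_blob_embedding()
  cl <- cluster_embeddings(emb, k = 3, seed = 4)
  genes <- rownames(emb$weights)
  # cluster of genes 11-20 occurs mostly in good paths, 21-30 in poor paths
  freqs <- data.frame(gene = genes,
                      good = c(rep(0, 10), rep(9, 10), rep(1, 10)),
                      poor = c(rep(0, 10), rep(1, 10), rep(9, 10)))
  lg <- assign_lgroups(cl, emb, freqs)
  expect_identical(sort(unname(lg)), c("good", "initial", "poor"))
  expect_identical(unname(lg[as.character(cl[genes[1]])]), "initial")
  expect_identical(unname(lg[as.character(cl[genes[11]])]), "good")
  expect_identical(unname(lg[as.character(cl[genes[21]])]), "poor")
})

test_that("abstentions and same-label votes are resolved as declared", {
  emb <- three_blob_embedding()
  cl <- cluster_embeddings(emb, k = 3, seed = 4)
  genes <- rownames(emb$weights)
  # one gene in the good cluster abstains (tied counts); majority still rules
  freqs <- data.frame(gene = genes,
                      good = c(rep(0, 10), 5, rep(9, 9), rep(1, 10)),
                      poor = c(rep(0, 10), 5, rep(1, 9), rep(9, 10)))
  lg <- assign_lgroups(cl, emb, freqs)
  expect_identical(unname(lg[as.character(cl[genes[11]])]), "good")
  # both clusters vote good, but the second with only 6/10 members
  # good-dominant: the stronger proportion keeps "good"
  freqs2 <- data.frame(gene = genes,
                       good = c(rep(0, 10), rep(9, 10), rep(6, 6), rep(2, 4)),
                       poor = c(rep(0, 10), rep(1, 10), rep(5, 6), rep(9, 4)))
  lg2 <- assign_lgroups(cl, emb, freqs2)
  expect_identical(unname(lg2[as.character(cl[genes[11]])]), "good")
  expect_identical(unname(lg2[as.character(cl[genes[21]])]), "poor")
  # an embedding with no trained gene carries no signal
  none <- emb; none$trained_mask[] <- FALSE
  expect_error(assign_lgroups(cl, none, freqs), "untrained")
})

test_that("d-score is the Euclidean norm", {
  expect_equal(d_score(numeric(5)), 0)
  expect_equal(d_score(c(3, 4)), 5)
  expect_equal(d_score(rep(1, 128)), sqrt(128))
  m <- rbind(c(3, 4), c(0, 0))
  expect_equal(unname(d_score(m)), c(5, 0))
})

test_that("t-score matches the Welch statistic and its oracle", {
  labels <- rep(c("good", "poor"), each = 3)
  expect_equal(t_score(c(1, 2, 3, 4, 5, 6), labels), 3 / sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(round(t_score(c(1, 2, 3, 4, 5, 6), labels), 4), 3.6742)
  # symmetry under label swap
  swapped <- rep(c("poor", "good"), each = 3)
  expect_equal(t_score(c(1, 2, 3, 4, 5, 6), labels),
               t_score(c(1, 2, 3, 4, 5, 6), swapped))
  # identical distributions give 0
  expect_equal(t_score(c(2, 4, 6, 2, 4, 6), labels), 0)
  expect_equal(t_score(rep(5, 6), labels), 0)
  expect_error(t_score(1:5, c("good", "poor", "poor", "poor", "poor")),
               "at least 2")
  # oracle: stats::t.test on random draws
  progwalk:::with_seed(23, {
    for (i in 1:50) {
      n1 <- sample(2:15, 1); n2 <- sample(2:15, 1)
      x <- c(rnorm(n1), rnorm(n2, 1, 2))
      lab <- rep(c("good", "poor"), c(n1, n2))
      expect_equal(t_score(x, lab),
                   abs(unname(stats::t.test(x[lab == "good"],
                                            x[lab == "poor"])$statistic)),
                   tolerance = 1e-10)
    }
  })
})

scored_table <- function() {
  # 6 genes: 2 initial, 2 good-L, 2 poor-L with controlled scores
  genes <- paste0("g", 1:6)
  W <- rbind(c(0, 0), c(0.1, 0), c(3, 4), c(6, 8), c(0, 2), c(0, 6))
  rownames(W) <- genes
  emb <- fake_embedding(W, trained = c(FALSE, FALSE, rep(TRUE, 4)))
  m <- rbind(g1 = c(1, 1, 1, 1, 1.1, 0.9, 1, 1),
             g2 = rnorm(8),
             g3 = c(0, 0, 0.2, 0.1, 5, 5, 5.1, 4.9),
             g4 = c(0, 0.3, 0, 0.1, 9, 9.2, 9.1, 8.9),
             g5 = c(5, 5.1, 5, 4.9, 0.2, 0, 0.1, 0),
             g6 = c(7, 7.2, 7.1, 6.9, 0.1, 0, 0.2, 0.1))
  colnames(m) <- paste0("s", 1:8)
  data <- expression_dataset(m, stats::setNames(rep(c("good", "poor"),
                                                    each = 4),
                                                paste0("s", 1:8)))
  clusters <- stats::setNames(c(1L, 1L, 2L, 2L, 3L, 3L), genes)
  lgroups <- stats::setNames(c("initial", "poor", "good"), 1:3)
  combine_scores(data, emb, clusters, lgroups)
}

test_that("combined scores min-max normalize over the L-group union", {
  tab <- scored_table()
  expect_identical(tab$lgroup, c("none", "none", "poor", "poor",
                                 "good", "good"))
  expect_identical(tab$cluster[1:2], c("initial", "initial"))
  scored <- tab$lgroup != "none"
  expect_true(all(is.na(tab$gene_score[!scored])))
  expect_equal(min(tab$d_norm[scored]), 0)
  expect_equal(max(tab$d_norm[scored]), 1)
  expect_equal(min(tab$t_norm[scored]), 0)
  expect_equal(max(tab$t_norm[scored]), 1)
  expect_equal(tab$gene_score[scored],
               (tab$d_norm[scored] + tab$t_norm[scored]) / 2)
  # d_norm follows the norms 5, 10, 2, 6 -> (5-2)/8 etc.
  expect_equal(tab$d_norm[3:6], c(3, 8, 0, 4) / 8)
})

test_that("min-max normalization handles degenerate inputs", {
  expect_equal(progwalk:::minmax(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(progwalk:::minmax(rep(3, 4)), rep(0, 4))
  expect_equal(progwalk:::minmax(5), 0)
})

test_that("biomarker selection takes top genes per L-group with declared tie-breaks", {
  tab <- scored_table()
  mk <- select_biomarkers(tab, per_group = 1)
  expect_s3_class(mk, "biomarker_set")
  expect_length(mk$combined, 2)
  expect_identical(mk$poor_markers, "g4")
  expect_identical(mk$good_markers, "g6")
  # shortfall returns all members with a warning per underfilled group
  w <- capture_warnings(mk2 <- select_biomarkers(tab, per_group = 50))
  expect_match(w, "only 2", all = TRUE)
  expect_length(w, 2)
  expect_length(mk2$combined, 4)
  expect_length(intersect(mk2$good_markers, mk2$poor_markers), 0)
  # ties on gene_score break by t_score then gene id
  t2 <- tab
  t2$gene_score[3:4] <- 0.5
  t2$t_score[3] <- 99; t2$t_score[4] <- 1
  expect_identical(select_biomarkers(t2, per_group = 1)$poor_markers, "g3")
  # empty L-group errors with the group named
  t3 <- tab[tab$lgroup != "good", ]
  expect_error(select_biomarkers(t3, 1), "good")
})

test_that("selection is invariant to gene input order", {
  tab <- scored_table()
  perm <- tab[c(4, 2, 6, 1, 5, 3), ]
  expect_identical(quiet(select_biomarkers(tab, 2)),
                   quiet(select_biomarkers(perm, 2)))
})

test_that("frequency-difference baseline ranks by signed count difference", {
  fr <- data.frame(gene = c("A", "B", "C"), good = c(5, 0, 2),
                   poor = c(0, 5, 2))
  mk <- diff_freq_select(fr, per_group = 1)
  expect_identical(mk$good_markers, "A")
  expect_identical(mk$poor_markers, "B")
  # degenerate all-equal counts: panels filled disjointly with a warning
  fr2 <- data.frame(gene = c("A", "B", "C", "D"), good = rep(2, 4),
                    poor = rep(2, 4))
  expect_warning(mk2 <- diff_freq_select(fr2, per_group = 2), "degenerate")
  expect_length(intersect(mk2$good_markers, mk2$poor_markers), 0)
  expect_length(mk2$combined, 4)
  # panels never exceed the available genes
  mk3 <- quiet(diff_freq_select(fr, per_group = 50))
  expect_lte(length(mk3$good_markers), 3)
  expect_length(intersect(mk3$good_markers, mk3$poor_markers), 0)
})

test_that("score tables and panels write as tab-separated text", {
  tab <- scored_table()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(tab, tmp)
  back <- utils::read.delim(tmp)
  expect_identical(names(back),
                   c("gene", "cluster", "lgroup", "d_score", "t_score",
                     "d_norm", "t_norm", "gene_score"))
  mk <- select_biomarkers(tab, 1)
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_biomarkers(mk, tmp2)
  b2 <- utils::read.delim(tmp2)
  expect_identical(b2$panel, c("good", "poor"))
})
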