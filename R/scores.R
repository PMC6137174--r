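# Gene scoring and biomarker selection: K-means clustering of gene vectors
# into the central (initial) group and two outcome-associated L-groups,
# d-scores (embedding distance from the origin), t-scores (differential
# expression), min-max combination, and top-50-per-group selection. Also the
# path-frequency difference baseline.

#' Cluster gene representations
#'
#' Standard K-means (multiple restarts, fixed seed) on the rows of the
#' embedding matrix. With the default K = 3 the clusters are the central
#' initial-vector group and the two outcome-associated L-groups.
#'
#' @param embedding a \code{gene_embedding}.
#' @param k number of clusters (default 3).
#' @param seed integer seed; same seed gives the same assignment.
#' @return named integer vector of cluster ids (1..k) over genes.
#' @export
cluster_embeddings <- function(embedding, k = 3L, seed = 1L) {
  W <- embedding$weights
  if (nrow(W) < k) stop("fewer genes than clusters")
  if (nrow(W) == k) {
    # one point per cluster is the unique partition
    return(stats::setNames(seq_len(k), rownames(W)))
  }
  km <- with_seed(substream_seed(seed, "kmeans"),
                  stats::kmeans(W, centers = k, nstart = 10L, iter.max = 100L))
  stats::setNames(km$cluster, rownames(W))
}

#' Identify the initial cluster and label the two L-groups
#'
#' The initial cluster is the one holding the most untrained genes (ties go
#' to the cluster whose centroid is nearest the zero vector). Each remaining
#' cluster is labeled good or poor by majority vote of its members' dominant
#' path-frequency label (a gene's dominant label is the outcome whose paths
#' contain it more often; equal counts abstain). If both clusters vote the
#' same label, the cluster with the higher winning proportion keeps it and
#' the other takes the remaining label.
#'
#' @param clusters named cluster assignment from
#'   \code{\link{cluster_embeddings}} with exactly 3 clusters.
#' @param embedding the \code{gene_embedding} that was clustered.
#' @param freqs path-frequency table from \code{\link{path_frequencies}}.
#' @return named character vector over cluster ids with values
#'   \code{"initial"}, \code{"good"}, \code{"poor"}.
#' @export
assign_lgroups <- function(clusters, embedding, freqs) {
  ids <- sort(unique(clusters))
  if (length(ids) != 3) stop("expected exactly 3 clusters")
  if (!any(embedding$trained_mask))
    stop("all genes are untrained; embedding carries no signal")
  untrained_by <- vapply(ids, function(cl)
    sum(!embedding$trained_mask[names(clusters)[clusters == cl]]), 0L)
  cand <- ids[untrained_by == max(untrained_by)]
  if (length(cand) > 1) {
    cn <- vapply(cand, function(cl) {
      sqrt(sum(colMeans(embedding$weights[clusters == cl, , drop = FALSE])^2))
    }, 0)
    cand <- cand[which.min(cn)]
  }
  initial <- cand[1]
  rest <- setdiff(ids, initial)

  dominant <- ifelse(freqs$good > freqs$poor, "good",
                     ifelse(freqs$poor > freqs$good, "poor", NA))
  names(dominant) <- freqs$gene
  vote <- function(cl) {
    d <- dominant[names(clusters)[clusters == cl]]
    d <- d[!is.na(d)]
    if (length(d) == 0) return(c(label = NA, prop = 0))
    tab <- table(factor(d, levels = c("good", "poor")))
    lab <- names(tab)[which.max(tab)]
    c(label = lab, prop = max(tab) / sum(tab))
  }
  v1 <- vote(rest[1]); v2 <- vote(rest[2])
  out <- stats::setNames(rep("initial", 3), as.character(ids))
  if (is.na(v1["label"]) && is.na(v2["label"]))
    stop("no cluster member has a dominant path-frequency label")
  if (is.na(v1["label"])) {
    out[as.character(rest[2])] <- v2["label"]
    out[as.character(rest[1])] <- setdiff(c("good", "poor"), v2["label"])
  } else if (is.na(v2["label"]) || v1["label"] != v2["label"]) {
    out[as.character(rest[1])] <- v1["label"]
    out[as.character(rest[2])] <-
      if (is.na(v2["label"])) setdiff(c("good", "poor"), v1["label"]) else v2["label"]
  } else {
    # both clusters voted the same label: stronger proportion wins it
    winner <- if (as.numeric(v1["prop"]) >= as.numeric(v2["prop"])) 1 else 2
    out[as.character(rest[winner])] <- v1["label"]
    out[as.character(rest[3 - winner])] <- setdiff(c("good", "poor"), v1["label"])
  }
  out[as.character(initial)] <- "initial"
  out
}

#' Embedding distance score
#'
#' Euclidean distance of a gene vector from the center of the initial gene
#' vectors, taken as the zero vector. The farther a trained vector moved from
#' the origin, the more the classifier relied on that gene.
#'
#' @param v numeric gene vector (length M), or a matrix of row vectors.
#' @return non-negative norm(s).
#' @export
d_score <- function(v) {
  if (is.matrix(v)) sqrt(rowSums(v^2)) else sqrt(sum(v^2))
}

#' Differential-expression score
#'
#' Absolute value of the two-sample unequal-variance (Welch) t-statistic
#' comparing a gene's expression between good and poor outcome samples.
#' Zero variance in both groups with equal means yields 0.
#'
#' @param x numeric expression vector over samples (or gene x sample matrix
#'   for many genes at once).
#' @param labels per-sample labels in \code{c("good", "poor")}, each class
#'   with >= 2 samples.
#' @return non-negative |t| value(s).
#' @export
t_score <- function(x, labels) {
  g <- labels == "good"; p <- labels == "poor"
  if (sum(g) < 2 || sum(p) < 2)
    stop("t_score requires at least 2 samples per class")
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  m1 <- rowMeans(x[, g, drop = FALSE]); m2 <- rowMeans(x[, p, drop = FALSE])
  v1 <- apply(x[, g, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, p, drop = FALSE], 1, stats::var)
  se2 <- v1 / sum(g) + v2 / sum(p)
  t <- abs(m1 - m2) / sqrt(se2)
  t[se2 == 0 & m1 == m2] <- 0
  if (length(t) == 1) unname(t) else t
}

# Min-max normalize to [0,1]; an all-equal vector maps to all zeros.
minmax <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Combine d-scores and t-scores into gene scores
#'
#' Both scores are min-max normalized to [0,1] over the scored gene set (the
#' union of the two L-groups; genes of the initial cluster are not
#' candidates) and averaged.
#'
#' @param data an \code{\link{expression_dataset}} (for t-scores).
#' @param embedding a \code{gene_embedding} (for d-scores).
#' @param clusters cluster assignment from \code{\link{cluster_embeddings}}.
#' @param lgroups cluster labeling from \code{\link{assign_lgroups}}.
#' @return a \code{gene_score_table} data frame with columns \code{gene},
#'   \code{cluster} (\code{initial}/\code{L1}/\code{L2}), \code{lgroup}
#'   (\code{good}/\code{poor}/\code{none}), \code{d_score}, \code{t_score},
#'   \code{d_norm}, \code{t_norm}, \code{gene_score} (normalized columns are
#'   NA for unscored genes).
#' @export
combine_scores <- function(data, embedding, clusters, lgroups) {
  genes <- rownames(embedding$weights)
  cl <- as.character(clusters[genes])
  lg <- unname(lgroups[cl])
  lgroup <- ifelse(lg == "initial", "none", lg)
  lcl <- setdiff(names(lgroups)[lgroups != "initial"], character(0))
  cluster_name <- stats::setNames(c("L1", "L2"), sort(lcl))
  cluster <- ifelse(lg == "initial", "initial", cluster_name[cl])

  d <- d_score(embedding$weights)
  t <- t_score(data$matrix[genes, , drop = FALSE], data$labels)
  scored <- lgroup != "none"
  if (!any(scored)) stop("no genes outside the initial cluster to score")
  d_norm <- t_norm <- gene_score <- rep(NA_real_, length(genes))
  d_norm[scored] <- minmax(d[scored])
  t_norm[scored] <- minmax(t[scored])
  gene_score[scored] <- (d_norm[scored] + t_norm[scored]) / 2
  structure(data.frame(gene = genes, cluster = unname(cluster),
                       lgroup = lgroup,
                       d_score = unname(d), t_score = unname(t),
                       d_norm = d_norm, t_norm = t_norm,
                       gene_score = gene_score,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("gene_score_table", "data.frame"))
}

#' Select the biomarker panel from each L-group
#'
#' Takes the \code{per_group} genes with the highest gene scores within each
#' L-group (ties broken by higher t-score, then by gene id). An L-group
#' smaller than \code{per_group} contributes all its members with a warning.
#'
#' @param table a \code{gene_score_table}.
#' @param per_group panel size per L-group (default 50, i.e. 100 biomarkers).
#' @return an object of class \code{biomarker_set}: lists
#'   \code{good_markers}, \code{poor_markers}, \code{combined}.
#' @export
select_biomarkers <- function(table, per_group = 50L) {
  pick <- function(group) {
    sub <- table[table$lgroup == group, , drop = FALSE]
    if (nrow(sub) == 0)
      stop("L-group '", group, "' is empty; cannot select biomarkers")
    if (nrow(sub) < per_group)
      warning(sprintf("L-group '%s' has only %d genes (< %d requested)",
                      group, nrow(sub), per_group))
    ord <- order(-sub$gene_score, -sub$t_score, sub$gene)
    sub$gene[ord][seq_len(min(per_group, nrow(sub)))]
  }
  good <- pick("good"); poor <- pick("poor")
  structure(list(good_markers = good, poor_markers = poor,
                 combined = c(good, poor)),
            class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat(sprintf("biomarker_set: %d good + %d poor markers\n",
              length(x$good_markers), length(x$poor_markers)))
  invisible(x)
}

#' Path-frequency difference baseline
#'
#' Selects the genes with the largest positive difference between good- and
#' poor-path occurrence counts as the good panel and the most negative
#' differences as the poor panel; ties are broken by gene id. Genes with zero
#' difference are allocated disjointly (good panel first) only when a panel
#' cannot otherwise be filled, with a degenerate-signal warning.
#'
#' @param freqs path-frequency table from \code{\link{path_frequencies}}.
#' @param per_group panel size per group (default 50).
#' @return a \code{biomarker_set}.
#' @export
diff_freq_select <- function(freqs, per_group = 50L) {
  if (nrow(freqs) == 0) stop("frequency table is empty")
  diff <- freqs$good - freqs$poor
  pos <- freqs$gene[diff > 0][order(-diff[diff > 0], freqs$gene[diff > 0])]
  neg <- freqs$gene[diff < 0][order(diff[diff < 0], freqs$gene[diff < 0])]
  zero <- sort(freqs$gene[diff == 0])
  good <- utils::head(pos, per_group)
  poor <- utils::head(neg, per_group)
  need_g <- per_group - length(good); need_p <- per_group - length(poor)
  if ((need_g > 0 || need_p > 0) && length(zero) > 0) {
    warning("degenerate frequency signal: panels padded with zero-difference genes")
    add_g <- utils::head(zero, need_g)
    good <- c(good, add_g)
    poor <- c(poor, utils::head(setdiff(zero, add_g), need_p))
  }
  structure(list(good_markers = good, poor_markers = poor,
                 combined = c(good, poor)),
            class = "biomarker_set")
}

#' Write a gene score table as tab-separated text
#' @param table a \code{gene_score_table}.
#' @param path output path.
#' @export
write_score_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a biomarker set as a two-column (gene, panel) table
#' @param markers a \code{biomarker_set}.
#' @param path output path.
#' @export
write_biomarkers <- function(markers, path) {
  df <- data.frame(gene = c(markers$good_markers, markers$poor_markers),
                   panel = rep(c("good", "poor"),
                               c(length(markers$good_markers),
                                 length(markers$poor_markers))),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
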