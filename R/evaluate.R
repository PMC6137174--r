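# Panel validation: the entire selection pipeline (correlation networks ->
# walks -> classifier training -> scoring -> panel) runs inside each training
# fold; a random forest trained on the fold's panel predicts the held-out
# samples and AUC-ROC summarizes accuracy. Test-fold expression never enters
# selection.

#' Run the full biomarker-selection pipeline on a set of training samples
#'
#' Builds both outcome-group correlation networks from the training samples
#' only, generates the walk corpus, trains the path-origin classifier,
#' clusters the gene vectors, scores genes and selects the panel.
#'
#' @param data an \code{\link{expression_dataset}}.
#' @param reference_edges reference-network edge data frame.
#' @param train_ids sample ids to use; defaults to all samples.
#' @param walk_cfg a \code{\link{walk_config}}.
#' @param model_cfg a \code{\link{model_config}}.
#' @param threshold correlation-weight threshold (default 0.5).
#' @param k number of embedding clusters (default 3).
#' @param per_group panel size per L-group (default 50).
#' @param seed integer seed for walks, training, and clustering.
#' @return list with \code{markers} (a \code{biomarker_set}), \code{scores}
#'   (a \code{gene_score_table}), \code{embedding}, \code{freqs},
#'   \code{networks}.
#' @export
select_panel <- function(data, reference_edges, train_ids = data$sample_ids,
                         walk_cfg = walk_config(), model_cfg = model_config(),
                         threshold = 0.5, k = 3L, per_group = 50L,
                         seed = 1L) {
  train <- expression_dataset(data$matrix[, train_ids, drop = FALSE],
                              data$labels[train_ids])
  good_net <- build_correlation_network(train, "good", reference_edges, threshold)
  poor_net <- build_correlation_network(train, "poor", reference_edges, threshold)
  walk_cfg$seed <- substream_seed(seed, "corpus")
  corpus <- generate_corpus(good_net, poor_net, train$gene_ids, walk_cfg)
  model_cfg$seed <- substream_seed(seed, "model")
  embedding <- train_cbow(corpus, model_cfg)
  clusters <- cluster_embeddings(embedding, k = k,
                                 seed = substream_seed(seed, "cluster"))
  freqs <- path_frequencies(corpus)
  lgroups <- assign_lgroups(clusters, embedding, freqs)
  scores <- combine_scores(train, embedding, clusters, lgroups)
  markers <- select_biomarkers(scores, per_group = per_group)
  list(markers = markers, scores = scores, embedding = embedding,
       freqs = freqs, networks = list(good = good_net, poor = poor_net))
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt cyclically into folds. Returns an integer fold id per sample.
make_folds <- function(labels, n_folds, seed) {
  for (lb in c("good", "poor")) {
    if (sum(labels == lb) < n_folds)
      stop(sprintf("class '%s' has %d samples; %d folds need at least %d",
                   lb, sum(labels == lb), n_folds, n_folds))
  }
  with_seed(substream_seed(seed, "folds"), {
    fold <- integer(length(labels))
    for (lb in unique(labels)) {
      idx <- sample(which(labels == lb))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    stats::setNames(fold, names(labels))
  })
}

# Train a 500-tree random forest on the panel genes and score test samples;
# returns AUC-ROC from the predicted poor-class probability.
rf_auc <- function(data, markers, train_ids, test_ids, seed, n_trees = 500L) {
  genes <- intersect(markers$combined, data$gene_ids)
  x_tr <- t(data$matrix[genes, train_ids, drop = FALSE])
  x_te <- t(data$matrix[genes, test_ids, drop = FALSE])
  y_tr <- factor(data$labels[train_ids], levels = c("good", "poor"))
  fit <- with_seed(substream_seed(seed, "forest"),
                   randomForest::randomForest(x = x_tr, y = y_tr,
                                              ntree = n_trees))
  prob_poor <- stats::predict(fit, x_te, type = "prob")[, "poor"]
  auc_score(data$labels[test_ids], prob_poor)
}

# AUC-ROC of a poor-class score against good/poor labels. A constant score
# gives 0.5; a score that perfectly ranks poor above good gives 1.
auc_score <- function(labels, prob_poor) {
  roc <- pROC::roc(response = factor(labels, levels = c("good", "poor")),
                   predictor = prob_poor, levels = c("good", "poor"),
                   direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(roc))
}

#' Cross-validated outcome prediction with per-fold biomarker selection
#'
#' Stratified n-fold cross-validation in which the entire selection pipeline
#' runs on each fold's training samples only; a random forest restricted to
#' the fold's panel is then scored on the held-out samples.
#'
#' @inheritParams select_panel
#' @param n_folds number of folds (default 10).
#' @param seed master seed (folds, per-fold pipelines, forests).
#' @return an object of class \code{cv_result}: \code{fold_auc} (numeric
#'   vector), \code{mean_auc}, \code{fold_markers} (list of
#'   \code{biomarker_set}), \code{folds} (per-sample fold id),
#'   \code{config}.
#' @export
cross_validate <- function(data, reference_edges, n_folds = 10L,
                           walk_cfg = walk_config(),
                           model_cfg = model_config(), threshold = 0.5,
                           k = 3L, per_group = 50L, seed = 1L) {
  folds <- make_folds(data$labels, n_folds, seed)
  fold_auc <- numeric(n_folds)
  fold_markers <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    train_ids <- data$sample_ids[folds != f]
    test_ids <- data$sample_ids[folds == f]
    sel <- select_panel(data, reference_edges, train_ids,
                        walk_cfg = walk_cfg, model_cfg = model_cfg,
                        threshold = threshold, k = k, per_group = per_group,
                        seed = substream_seed(seed, paste0("fold", f)))
    fold_markers[[f]] <- sel$markers
    fold_auc[f] <- rf_auc(data, sel$markers, train_ids, test_ids,
                          seed = substream_seed(seed, paste0("rf", f)))
    pw_log("fold %d/%d: AUC = %.3f (%d markers)", f, n_folds, fold_auc[f],
           length(sel$markers$combined))
  }
  structure(list(fold_auc = fold_auc, mean_auc = mean(fold_auc),
                 fold_markers = fold_markers, folds = folds,
                 config = list(n_folds = n_folds, threshold = threshold,
                               k = k, per_group = per_group, seed = seed,
                               walk = unclass(walk_cfg),
                               model = unclass(model_cfg),
                               n_trees = 500L)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d folds, mean AUC-ROC = %.3f (per fold: %s)\n",
              length(x$fold_auc), x$mean_auc,
              paste(sprintf("%.2f", x$fold_auc), collapse = " ")))
  invisible(x)
}

#' Small-training-sample experiment
#'
#' For each requested training size, repeatedly draws that many samples per
#' class uniformly at random as the training set, runs the full selection
#' pipeline plus random forest, and scores the remaining samples.
#'
#' @inheritParams select_panel
#' @param n_per_group training samples drawn per class (vector, default
#'   \code{c(10, 20, 30)}).
#' @param n_repeats independent draws per setting (default 10).
#' @param seed master seed.
#' @return data frame with columns \code{n_per_group}, \code{repeat_id},
#'   \code{auc}; mean AUC per setting is available via \code{aggregate}.
#' @export
small_sample_experiment <- function(data, reference_edges,
                                    n_per_group = c(10L, 20L, 30L),
                                    n_repeats = 10L,
                                    walk_cfg = walk_config(),
                                    model_cfg = model_config(),
                                    threshold = 0.5, k = 3L,
                                    per_group = 50L, seed = 1L) {
  for (npg in n_per_group) {
    for (lb in c("good", "poor")) {
      if (sum(data$labels == lb) <= npg)
        stop(sprintf("n_per_group = %d leaves no test samples in class '%s'",
                     npg, lb))
    }
  }
  res <- expand.grid(n_per_group = n_per_group, repeat_id = seq_len(n_repeats))
  res$auc <- NA_real_
  for (i in seq_len(nrow(res))) {
    npg <- res$n_per_group[i]; rep_id <- res$repeat_id[i]
    sub_seed <- substream_seed(seed, sprintf("small%d_%d", npg, rep_id))
    train_ids <- with_seed(substream_seed(sub_seed, "draw"), {
      unlist(lapply(c("good", "poor"), function(lb)
        sample(data$sample_ids[data$labels == lb], npg)))
    })
    test_ids <- setdiff(data$sample_ids, train_ids)
    sel <- select_panel(data, reference_edges, train_ids,
                        walk_cfg = walk_cfg, model_cfg = model_cfg,
                        threshold = threshold, k = k, per_group = per_group,
                        seed = sub_seed)
    res$auc[i] <- rf_auc(data, sel$markers, train_ids, test_ids,
                         seed = substream_seed(sub_seed, "rf"))
    pw_log("small-sample n=%d repeat %d: AUC = %.3f", npg, rep_id, res$auc[i])
  }
  res[order(res$n_per_group, res$repeat_id), ]
}
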