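# End-to-end orchestration: read or simulate a cohort, run the cross-validated
# evaluation, write every artifact plus a manifest sufficient to reproduce the
# run.

#' Run the full pipeline and write all outputs
#'
#' Reads a cohort from files (expression + labels-or-clinical + network) or
#' simulates one, runs a full-data biomarker selection (networks, corpus,
#' embedding, score table, panels) and a cross-validated evaluation, and
#' writes all artifacts to \code{out_dir} together with a JSON run manifest.
#'
#' @param expression,clinical,labels,network optional input file paths (see
#'   \code{\link{read_expression}}, \code{\link{read_clinical}},
#'   \code{\link{read_network}}); ignored when \code{simulate} is given.
#' @param criterion_days survival criterion used to label patients when
#'   \code{clinical} is supplied instead of \code{labels}.
#' @param simulate optional \code{\link{cohort_config}} to generate a
#'   synthetic cohort instead of reading files.
#' @param out_dir output directory (created if needed).
#' @param walk_cfg,model_cfg,threshold,k,per_group pipeline settings; see
#'   \code{\link{select_panel}}.
#' @param n_folds folds for evaluation (default 10); set to 0 to skip
#'   cross-validation.
#' @param seed master seed.
#' @return invisibly, a list with \code{selection}, \code{evaluation},
#'   \code{manifest}.
#' @export
run_pipeline <- function(expression = NULL, clinical = NULL, labels = NULL,
                         network = NULL, criterion_days = 730,
                         simulate = NULL, out_dir = "progwalk_out",
                         walk_cfg = walk_config(), model_cfg = model_config(),
                         threshold = 0.5, k = 3L, per_group = 50L,
                         n_folds = 10L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(simulate)) {
    simulate$seed <- as.integer(seed)
    cohort <- simulate_cohort(simulate)
    data <- cohort$data
    edges <- cohort$network
    write_expression(data$matrix, file.path(out_dir, "expression.tsv"))
    write_network_edges(edges, file.path(out_dir, "network.tsv"))
    utils::write.table(cohort$survival, file.path(out_dir, "clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c("gene", cohort$planted_genes),
               file.path(out_dir, "planted_genes.txt"))
  } else {
    if (is.null(expression) || is.null(network) ||
        (is.null(labels) && is.null(clinical)))
      stop("need expression, network, and labels or clinical files (or simulate=)")
    mat <- read_expression(expression)
    edges <- read_network(network)
    if (!is.null(labels)) {
      lab_df <- utils::read.delim(labels, stringsAsFactors = FALSE)
      lab <- stats::setNames(lab_df$label, lab_df$sample_id)
    } else {
      clin <- read_clinical(clinical)
      lab <- label_patients(clin, criterion_days)
      lab <- lab[lab != "excluded"]
      pw_log("labeled %d/%d patients at criterion %g days",
             length(lab), nrow(clin), criterion_days)
    }
    common <- intersect(colnames(mat), names(lab))
    if (length(common) == 0) stop("no samples shared between expression and labels")
    data <- expression_dataset(mat[, common, drop = FALSE], lab[common])
  }

  sel <- select_panel(data, edges, walk_cfg = walk_cfg, model_cfg = model_cfg,
                      threshold = threshold, k = k, per_group = per_group,
                      seed = substream_seed(seed, "selection"))
  write_correlation_network(sel$networks$good, file.path(out_dir, "corrnet_good.tsv"))
  write_correlation_network(sel$networks$poor, file.path(out_dir, "corrnet_poor.tsv"))
  write_embedding(sel$embedding, file.path(out_dir, "embedding.tsv"))
  write_training_log(sel$embedding, file.path(out_dir, "training_log.jsonl"))
  write_score_table(sel$scores, file.path(out_dir, "gene_scores.tsv"))
  write_biomarkers(sel$markers, file.path(out_dir, "biomarkers.tsv"))
  utils::write.table(sel$freqs, file.path(out_dir, "path_frequencies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  evaluation <- NULL
  if (n_folds > 0) {
    evaluation <- cross_validate(data, edges, n_folds = n_folds,
                                 walk_cfg = walk_cfg, model_cfg = model_cfg,
                                 threshold = threshold, k = k,
                                 per_group = per_group,
                                 seed = substream_seed(seed, "evaluation"))
    jsonlite::write_json(
      list(fold_auc = evaluation$fold_auc, mean_auc = evaluation$mean_auc,
           config = evaluation$config),
      file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
    fold_tab <- do.call(rbind, lapply(seq_along(evaluation$fold_markers),
      function(f) {
        m <- evaluation$fold_markers[[f]]
        data.frame(fold = f,
                   gene = c(m$good_markers, m$poor_markers),
                   panel = rep(c("good", "poor"),
                               c(length(m$good_markers), length(m$poor_markers))))
      }))
    utils::write.table(fold_tab, file.path(out_dir, "fold_biomarkers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("progwalk")),
    r_version = as.character(getRversion()),
    seed = seed,
    inputs = if (is.null(simulate))
      list(expression = expression, clinical = clinical, labels = labels,
           network = network, criterion_days = criterion_days)
      else list(simulate = unclass(simulate)),
    settings = list(threshold = threshold, k = k, per_group = per_group,
                    n_folds = n_folds, walk = unclass(walk_cfg),
                    model = unclass(model_cfg)),
    n_genes = length(data$gene_ids), n_samples = length(data$sample_ids))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(selection = sel, evaluation = evaluation, manifest = manifest))
}
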