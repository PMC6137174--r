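# Expression dataset container, preprocessing, outcome labeling, and file I/O.

#' Construct an expression dataset
#'
#' Bundles a gene x sample matrix of log-scale expression values with per-sample
#' outcome labels. Rows are genes, columns are samples, matching the common
#' transcriptomics matrix layout.
#'
#' @param matrix numeric gene x sample matrix; rownames are gene ids, colnames
#'   are sample ids.
#' @param labels character vector of per-sample labels in \code{c("good",
#'   "poor")}, named by sample id or in column order.
#' @param survival optional data frame with columns \code{sample_id},
#'   \code{time_days}, \code{event}.
#' @return an object of class \code{expression_dataset} with fields
#'   \code{matrix}, \code{gene_ids}, \code{sample_ids}, \code{labels},
#'   \code{survival}.
#' @export
expression_dataset <- function(matrix, labels, survival = NULL) {
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(matrix)))
    stop("duplicate sample identifiers in expression matrix")
  if (anyNA(matrix))
    stop("expression matrix contains missing values")
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(matrix), names(labels))
    if (length(missing))
      stop("samples without a label: ", paste(utils::head(missing, 5), collapse = ", "))
    labels <- labels[colnames(matrix)]
  } else if (length(labels) != ncol(matrix)) {
    stop("labels length does not match sample count")
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("good", "poor")))
    stop("labels must be 'good' or 'poor'")
  names(labels) <- colnames(matrix)
  structure(
    list(matrix = matrix,
         gene_ids = rownames(matrix),
         sample_ids = colnames(matrix),
         labels = labels,
         survival = survival),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%d good, %d poor)\n",
              length(x$gene_ids), length(x$sample_ids),
              sum(x$labels == "good"), sum(x$labels == "poor")))
  invisible(x)
}

#' Log-transform raw expression values
#'
#' Applies \code{log2(x + 1)} to a non-negative raw expression matrix (e.g.
#' RSEM normalized counts), the standard variance-stabilizing preprocessing
#' for these data.
#'
#' @param raw_matrix non-negative numeric gene x sample matrix.
#' @return a matrix of the same shape with every value equal to
#'   \code{log2(value + 1)}.
#' @export
preprocess_expression <- function(raw_matrix) {
  raw_matrix <- as.matrix(raw_matrix)
  bad <- which(raw_matrix < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("negative expression value at gene '%s', sample '%s'",
                 rownames(raw_matrix)[bad[1, 1]] %||% bad[1, 1],
                 colnames(raw_matrix)[bad[1, 2]] %||% bad[1, 2]))
  }
  log2(raw_matrix + 1)
}

#' Derive binary prognosis labels from survival records
#'
#' A patient surviving beyond the time criterion without a recorded death is
#' labeled \code{good}; a patient with a death event within the criterion is
#' labeled \code{poor}. Patients censored before the criterion fit neither
#' definition and are \code{excluded}; the three classes are disjoint and
#' exhaustive.
#'
#' @param records data frame with columns \code{sample_id}, \code{time_days}
#'   (non-negative), \code{event} (logical or 0/1).
#' @param criterion positive survival-time criterion in days (e.g. 730 for a
#'   two-year cutoff).
#' @return named character vector over \code{sample_id} with values in
#'   \code{c("good", "poor", "excluded")}.
#' @export
label_patients <- function(records, criterion) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "time_days", "event") %in% names(records)))
  if (criterion <= 0) stop("criterion must be positive")
  if (any(records$time_days < 0)) stop("negative survival time in records")
  event <- as.logical(records$event)
  lab <- rep("excluded", nrow(records))
  lab[records$time_days > criterion & !event] <- "good"
  lab[event & records$time_days <= criterion] <- "poor"
  stats::setNames(lab, records$sample_id)
}

#' Read a tab-separated expression matrix
#'
#' First column holds gene ids, header row holds sample ids.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write an expression matrix as tab-separated text
#' @param matrix gene x sample matrix with dimnames.
#' @param path output path.
#' @export
write_expression <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read clinical survival records
#'
#' Tab-separated with columns \code{sample_id}, \code{time_days},
#' \code{event} (0/1).
#' @param path file path.
#' @return data frame of survival records.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "time_days", "event") %in% names(df)))
  df$event <- as.integer(df$event)
  df
}

#' Read an undirected gene-interaction edge list
#'
#' Two-column tab-separated edge list (SIF-like, unweighted). Self-loops are
#' dropped; duplicate edges and reversed duplicates are collapsed.
#'
#' @param path file path.
#' @return data frame with columns \code{from}, \code{to}, one row per
#'   unordered gene pair.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("from", "to"))
  canonical_edges(df)
}

# Canonicalize an edge list: order each pair, drop self-loops and duplicates.
canonical_edges <- function(edges) {
  from <- as.character(edges[[1]]); to <- as.character(edges[[2]])
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  a <- pmin(from, to); b <- pmax(from, to)
  dup <- duplicated(paste(a, b, sep = "\r"))
  data.frame(from = a[!dup], to = b[!dup], stringsAsFactors = FALSE)
}

#' Write an edge list as two-column tab-separated text
#' @param edges data frame with columns \code{from}, \code{to}.
#' @param path output path.
#' @export
write_network_edges <- function(edges, path) {
  utils::write.table(edges[, c("from", "to")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
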