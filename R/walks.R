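# Constrained random walks on correlation networks and the labeled path
# corpus used to train the classifier.
#
# Walk constraints: (1) a node is never revisited within a path, (2) the next
# node is drawn among unvisited neighbors with probability proportional to
# edge weight, (3) a walk stops at a dead end or at the maximum path length
# (counted in nodes).

#' Walk and corpus configuration
#'
#' Defaults: walks are capped at 80 nodes, 10 walks depart from every node of
#' each network, and surviving paths are split 80/20 into training and
#' validation sets.
#'
#' @param max_path_length maximum number of nodes in a path (>= 1).
#' @param walks_per_node walks initiated from each node of each network.
#' @param train_fraction fraction of paths assigned to the training set.
#' @param seed integer seed controlling walks and the split.
#' @return a list of class \code{walk_config}.
#' @export
walk_config <- function(max_path_length = 80L, walks_per_node = 10L,
                        train_fraction = 0.8, seed = 1L) {
  stopifnot(max_path_length >= 1, walks_per_node >= 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(max_path_length = as.integer(max_path_length),
                 walks_per_node = as.integer(walks_per_node),
                 train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "walk_config")
}

#' Generate one constrained random walk
#'
#' @param network a \code{correlation_network}.
#' @param start gene id of the starting node.
#' @param config a \code{\link{walk_config}}; only \code{max_path_length} is
#'   used. Randomness comes from the current RNG state.
#' @return character vector of visited gene ids, starting at \code{start}.
#' @export
random_walk <- function(network, start, config = walk_config()) {
  v0 <- match(start, network$nodes)
  if (is.na(v0)) stop("start gene '", start, "' is not a node of the network")
  maxlen <- config$max_path_length
  path <- integer(maxlen)
  visited <- logical(length(network$nodes))
  path[1L] <- v0; visited[v0] <- TRUE
  len <- 1L
  while (len < maxlen) {
    nb <- network$adj[[path[len]]]
    if (is.null(nb)) break
    open <- !visited[nb]
    if (!any(open)) break
    nb <- nb[open]
    w <- network$wadj[[path[len]]][open]
    nxt <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L, prob = w)]
    len <- len + 1L
    path[len] <- nxt; visited[nxt] <- TRUE
  }
  network$nodes[path[seq_len(len)]]
}

#' Generate the labeled path corpus from two correlation networks
#'
#' Initiates exactly \code{walks_per_node} walks from every node of each
#' network, labels each path by its source network, removes any ordered gene
#' sequence that was produced by both networks (from both label sets), and
#' splits the survivors into training and validation paths by a uniform
#' random partition stratified by label.
#'
#' @param good_net,poor_net \code{correlation_network} objects for the good
#'   and poor outcome groups.
#' @param genes character vector of all gene ids of the expression dataset;
#'   defines the corpus' gene index (columns of the encoded input).
#' @param config a \code{\link{walk_config}}.
#' @return an object of class \code{path_corpus}: lists \code{train} and
#'   \code{validation} of paths (each a list with \code{genes},
#'   \code{label}), \code{gene_index} (named integer vector over all genes),
#'   and counts (\code{n_walks}, \code{n_removed}) as fields.
#' @export
generate_corpus <- function(good_net, poor_net, genes,
                            config = walk_config()) {
  for (net in list(good_net, poor_net)) {
    if (length(net$nodes) == 0)
      stop("correlation network for group '", net$group, "' is empty")
  }
  walks <- with_seed(substream_seed(config$seed, "walks"), {
    one_net <- function(net, label) {
      out <- vector("list", length(net$nodes) * config$walks_per_node)
      k <- 0L
      for (v in net$nodes) {
        for (r in seq_len(config$walks_per_node)) {
          k <- k + 1L
          out[[k]] <- list(genes = random_walk(net, v, config), label = label)
        }
      }
      out
    }
    c(one_net(good_net, "good"), one_net(poor_net, "poor"))
  })

  key <- vapply(walks, function(p) paste(p$genes, collapse = "\r"), "")
  label <- vapply(walks, `[[`, "", "label")
  shared <- intersect(unique(key[label == "good"]), unique(key[label == "poor"]))
  keep <- !(key %in% shared)
  n_removed <- sum(!keep)
  pw_log("corpus: %d walks (%d good, %d poor); removed %d paths found under both labels",
         length(walks), sum(label == "good"), sum(label == "poor"), n_removed)
  walks <- walks[keep]; label <- label[keep]

  split <- with_seed(substream_seed(config$seed, "split"), {
    train <- logical(length(walks))
    for (lb in c("good", "poor")) {
      idx <- which(label == lb)
      n_tr <- round(config$train_fraction * length(idx))
      train[sample(idx, n_tr)] <- TRUE
    }
    train
  })

  structure(list(train = walks[split],
                 validation = walks[!split],
                 gene_index = stats::setNames(seq_along(genes), genes),
                 n_walks = length(key),
                 n_removed = n_removed),
            class = "path_corpus")
}

#' @export
print.path_corpus <- function(x, ...) {
  cat(sprintf("path_corpus: %d train + %d validation paths over %d genes (%d cross-label paths removed)\n",
              length(x$train), length(x$validation), length(x$gene_index),
              x$n_removed))
  invisible(x)
}

#' Encode a path as a multi-hot gene vector
#'
#' @param path character vector of gene ids (or a corpus path element).
#' @param gene_index named integer vector mapping gene id to column.
#' @return binary numeric vector of length \code{length(gene_index)} with 1
#'   at the positions of genes occurring in the path.
#' @export
encode_path <- function(path, gene_index) {
  if (is.list(path)) path <- path$genes
  v <- numeric(length(gene_index))
  if (length(path)) {
    idx <- gene_index[path]
    if (anyNA(idx))
      stop("gene not in index: ", paste(path[is.na(idx)], collapse = ", "))
    v[idx] <- 1
  }
  v
}

# Sparse multi-hot encoding of a list of paths (rows = paths, cols = genes).
encode_paths <- function(paths, gene_index) {
  idx <- lapply(paths, function(p) {
    i <- unique(unname(gene_index[p$genes]))
    if (anyNA(i)) stop("gene not in index")
    i
  })
  lens <- lengths(idx)
  Matrix::sparseMatrix(i = rep.int(seq_along(paths), lens),
                       j = unlist(idx), x = 1,
                       dims = c(length(paths), length(gene_index)),
                       dimnames = list(NULL, names(gene_index)))
}

#' Count per-gene path occurrences by label
#'
#' For every gene of the corpus' index, counts the number of paths (training
#' plus validation) containing the gene, separately for good- and
#' poor-labeled paths. Genes occurring in no path get (0, 0).
#'
#' @param corpus a \code{path_corpus}.
#' @return data frame with columns \code{gene}, \code{good}, \code{poor}.
#' @export
path_frequencies <- function(corpus) {
  stopifnot(inherits(corpus, "path_corpus"))
  paths <- c(corpus$train, corpus$validation)
  if (length(paths) == 0) stop("corpus contains no paths")
  good <- integer(length(corpus$gene_index))
  poor <- integer(length(corpus$gene_index))
  for (p in paths) {
    idx <- unique(unname(corpus$gene_index[p$genes]))
    if (p$label == "good") good[idx] <- good[idx] + 1L
    else poor[idx] <- poor[idx] + 1L
  }
  data.frame(gene = names(corpus$gene_index), good = good, poor = poor,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a path corpus as tab-separated text
#'
#' One path per line: split (train/validation), label, then comma-separated
#' gene ids.
#' @param corpus a \code{path_corpus}.
#' @param path output file path; \code{.gz} suffix enables compression.
#' @export
write_corpus <- function(corpus, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (split in c("train", "validation")) {
    for (p in corpus[[split]]) {
      writeLines(paste(split, p$label, paste(p$genes, collapse = ","),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}
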