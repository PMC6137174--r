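# Outcome-group correlation networks: reference edges weighted by |Pearson r|
# over one group's samples, thresholded to keep only strong co-expression.

#' Absolute Pearson correlation weight of two expression profiles
#'
#' Computes the sample Pearson correlation coefficient from its covariance
#' formula and returns its absolute value. A vector with zero variance yields
#' weight 0: a constant gene carries no correlation signal.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a value in [0, 1].
#' @export
pearson_weight <- function(x, y) {
  if (length(x) != length(y)) stop("pearson_weight: length mismatch")
  if (length(x) < 3) stop("pearson_weight: need at least 3 observations")
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(sum(xc^2)); sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) return(0)
  min(abs(sum(xc * yc) / (sx * sy)), 1)
}

#' Build a weighted correlation network for one outcome group
#'
#' Each reference-network edge whose endpoints are both measured is weighted
#' by the absolute Pearson correlation of the two genes over the given
#' group's samples only; edges with weight below \code{threshold} are removed
#' (a weight exactly equal to the threshold is retained). Edges touching
#' unmeasured genes are dropped with a logged count.
#'
#' @param data an \code{\link{expression_dataset}}.
#' @param group \code{"good"} or \code{"poor"}.
#' @param reference_edges data frame with columns \code{from}, \code{to}.
#' @param threshold minimum retained weight (default 0.5).
#' @return an object of class \code{correlation_network}: list with
#'   \code{group}, \code{edges} (from, to, weight), \code{nodes} (genes on
#'   retained edges), and an adjacency index used by the walker.
#' @export
build_correlation_network <- function(data, group, reference_edges,
                                      threshold = 0.5) {
  stopifnot(inherits(data, "expression_dataset"),
            group %in% c("good", "poor"))
  if (nrow(reference_edges) == 0) stop("reference edge list is empty")
  cols <- which(data$labels == group)
  if (length(cols) < 3)
    stop(sprintf("group '%s' has %d samples; at least 3 are required",
                 group, length(cols)))
  edges <- canonical_edges(reference_edges)
  measured <- edges$from %in% data$gene_ids & edges$to %in% data$gene_ids
  if (any(!measured))
    pw_log("group %s: dropped %d reference edges touching unmeasured genes",
           group, sum(!measured))
  edges <- edges[measured, , drop = FALSE]

  e <- data$matrix[, cols, drop = FALSE]
  used <- unique(c(edges$from, edges$to))
  z <- e[used, , drop = FALSE] - rowMeans(e[used, , drop = FALSE])
  ss <- sqrt(rowSums(z^2))
  ia <- match(edges$from, used); ib <- match(edges$to, used)
  denom <- ss[ia] * ss[ib]
  w <- abs(rowSums(z[ia, , drop = FALSE] * z[ib, , drop = FALSE])) / denom
  w[denom == 0] <- 0
  w <- pmin(w, 1)

  keep <- w >= threshold
  pw_log("group %s: retained %d/%d edges at |r| >= %g",
         group, sum(keep), length(w), threshold)
  out <- data.frame(from = edges$from[keep], to = edges$to[keep],
                    weight = w[keep], stringsAsFactors = FALSE)
  # nodes are all measured genes of the reference network; genes whose every
  # edge fell below the threshold remain as isolated nodes (walks still start
  # there and yield single-node paths)
  correlation_network(group, out, nodes = unique(c(edges$from, edges$to)))
}

# Internal constructor: builds the integer adjacency index used by the walker.
correlation_network <- function(group, edges, nodes = NULL) {
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  ia <- match(edges$from, nodes); ib <- match(edges$to, nodes)
  adj <- vector("list", length(nodes))
  wadj <- vector("list", length(nodes))
  if (length(nodes)) {
    ord <- order(c(ia, ib))
    nb_of <- c(ia, ib)[ord]        # node each entry belongs to
    nb_to <- c(ib, ia)[ord]        # its neighbor
    nb_w <- c(edges$weight, edges$weight)[ord]
    split_idx <- split(seq_along(nb_of), nb_of)
    for (k in names(split_idx)) {
      i <- as.integer(k)
      adj[[i]] <- nb_to[split_idx[[k]]]
      wadj[[i]] <- nb_w[split_idx[[k]]]
    }
  }
  structure(list(group = group, edges = edges, nodes = nodes,
                 adj = adj, wadj = wadj),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network[%s]: %d nodes, %d edges\n",
              x$group, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a correlation network as a weighted edge list
#'
#' Three tab-separated columns: gene_a, gene_b, weight (6 decimal places).
#' @param network a \code{correlation_network}.
#' @param path output path.
#' @export
write_correlation_network <- function(network, path) {
  df <- network$edges
  df$weight <- sprintf("%.6f", df$weight)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
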