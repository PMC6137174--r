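# Diagnostic 2-D scatter of the learned gene vectors. The projection is PCA:
# deterministic, fast, and sufficient to show the three-group geometry (the
# central initial-vector cloud and the two outcome-associated groups).

#' Plot gene representations in two dimensions
#'
#' Projects the embedding rows onto their first two principal components and
#' colors genes by dominant path-frequency label: blue for good-dominant, red
#' for poor-dominant, yellow for equal non-zero occurrence, green for genes
#' never walked.
#'
#' @param embedding a \code{gene_embedding}.
#' @param freqs path-frequency table from \code{\link{path_frequencies}}.
#' @param path output PNG path.
#' @param width,height device size in pixels.
#' @return invisibly, the data frame of plotted coordinates and categories.
#' @export
plot_embeddings <- function(embedding, freqs, path, width = 900, height = 700) {
  if (!any(embedding$trained_mask))
    warning("embedding is untrained; plot shows initialization only")
  pc <- stats::prcomp(embedding$weights, center = TRUE, scale. = FALSE)
  xy <- pc$x[, 1:2, drop = FALSE]
  f <- freqs[match(rownames(embedding$weights), freqs$gene), ]
  category <- ifelse(f$good + f$poor == 0, "never walked",
                     ifelse(f$good > f$poor, "good-dominant",
                            ifelse(f$poor > f$good, "poor-dominant", "equal")))
  cols <- c("good-dominant" = "#2166ac", "poor-dominant" = "#b2182b",
            "equal" = "#e6b800", "never walked" = "#1b7837")
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::plot(xy, col = cols[category], pch = 19, cex = 0.6,
                 xlab = "PC1", ylab = "PC2",
                 main = "Gene representations by path-frequency label")
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   bty = "n")
  invisible(data.frame(gene = rownames(embedding$weights), xy, category,
                       stringsAsFactors = FALSE))
}
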