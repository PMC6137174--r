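# Modified CBOW classifier: multi-hot bag-of-genes input, linear projection
# of size M (no activation, no projection bias), single sigmoid output unit
# predicting whether a path came from the poor-outcome network. The trained
# input-to-projection weight matrix W (N x M) is the gene representation.
#
# Training: binary cross-entropy, Adam, early stopping on validation loss
# with best-weight restoration. No regularization: a gene absent from every
# training path receives exactly zero gradient, so its W row stays
# bit-identical to its initialization — that invariance is what places
# never-walked genes at the center of the embedding.

#' Model configuration
#'
#' Defaults: 128 projection units, learning rate 0.005, at most 30 epochs
#' with early stopping (patience 3) on validation loss.
#'
#' @param projection_size number of projection units M.
#' @param learning_rate Adam step size.
#' @param max_epochs maximum training epochs.
#' @param early_stopping_patience epochs without validation improvement
#'   before stopping.
#' @param batch_size minibatch size.
#' @param init_scale standard deviation of the zero-mean Gaussian weight
#'   initialization.
#' @param seed integer seed for initialization and batch shuffling.
#' @return a list of class \code{model_config}.
#' @export
model_config <- function(projection_size = 128L, learning_rate = 0.005,
                         max_epochs = 30L, early_stopping_patience = 3L,
                         batch_size = 64L, init_scale = 0.01, seed = 1L) {
  stopifnot(projection_size >= 1, learning_rate > 0, max_epochs >= 1,
            early_stopping_patience >= 1, batch_size >= 1, init_scale > 0)
  structure(list(projection_size = as.integer(projection_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 batch_size = as.integer(batch_size),
                 init_scale = init_scale,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Initialize model weights
#'
#' All weights are drawn i.i.d. zero-mean Gaussian with standard deviation
#' \code{init_scale}; the output bias starts at zero. Because the rows of W
#' are zero-mean, the centroid of the initial gene vectors is (close to) the
#' zero vector, so distance from the origin measures distance from the
#' initial-vector center.
#'
#' @param n_genes number of genes N (rows of W).
#' @param config a \code{\link{model_config}}.
#' @return list with \code{W} (N x M), \code{V} (M output weights), \code{b}
#'   (scalar bias).
#' @export
init_model <- function(n_genes, config = model_config()) {
  stopifnot(n_genes >= 1)
  with_seed(substream_seed(config$seed, "init"), {
    list(W = matrix(stats::rnorm(n_genes * config$projection_size,
                                 sd = config$init_scale),
                    nrow = n_genes),
         V = stats::rnorm(config$projection_size, sd = config$init_scale),
         b = 0)
  })
}

# Mean binary cross-entropy of sigmoid(z) against y in {0,1}, numerically
# stable form: log(1+exp(-|z|)) + max(z,0) - z*y.
bce_loss <- function(z, y) {
  mean(log1p(exp(-abs(z))) + pmax(z, 0) - z * y)
}

#' Train the path-origin classifier and extract gene representations
#'
#' @param corpus a \code{path_corpus} with at least one path of each label in
#'   both the training and validation sets.
#' @param config a \code{\link{model_config}}.
#' @return an object of class \code{gene_embedding}: \code{weights} (N x M
#'   matrix, gene ids as rownames), \code{gene_index}, \code{trained_mask}
#'   (TRUE for genes occurring in >= 1 training path), \code{model} (full
#'   weight set for prediction), \code{log} (per-epoch train/validation
#'   loss), \code{config}.
#' @export
train_cbow <- function(corpus, config = model_config()) {
  stopifnot(inherits(corpus, "path_corpus"))
  for (split in c("train", "validation")) {
    lb <- vapply(corpus[[split]], `[[`, "", "label")
    if (length(unique(lb)) < 2)
      stop("corpus ", split, " set does not contain both labels")
  }
  n <- length(corpus$gene_index)
  X_tr <- encode_paths(corpus$train, corpus$gene_index)
  y_tr <- as.numeric(vapply(corpus$train, `[[`, "", "label") == "poor")
  X_va <- encode_paths(corpus$validation, corpus$gene_index)
  y_va <- as.numeric(vapply(corpus$validation, `[[`, "", "label") == "poor")

  par <- init_model(n, config)
  W0 <- par$W
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  mW <- matrix(0, n, config$projection_size); vW <- mW
  mV <- numeric(config$projection_size); vV <- mV
  mb <- 0; vb <- 0; t_step <- 0L

  eval_loss <- function(X, y) {
    z <- as.numeric(X %*% par$W %*% par$V) + par$b
    bce_loss(z, y)
  }

  best <- list(loss = Inf, W = par$W, V = par$V, b = par$b, epoch = 0L)
  wait <- 0L
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())

  with_seed(substream_seed(config$seed, "batches"), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(nrow(X_tr))
      for (batch in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        Xb <- X_tr[batch, , drop = FALSE]
        yb <- y_tr[batch]
        H <- as.matrix(Xb %*% par$W)                    # |b| x M
        z <- as.numeric(H %*% par$V) + par$b
        p <- stats::plogis(z)
        dz <- (p - yb) / length(yb)
        dV <- as.numeric(crossprod(H, dz))
        db <- sum(dz)
        dW <- as.matrix(Matrix::crossprod(Xb, tcrossprod(dz, par$V)))  # N x M
        t_step <- t_step + 1L
        corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
        mW <- beta1 * mW + (1 - beta1) * dW
        vW <- beta2 * vW + (1 - beta2) * dW^2
        par$W <- par$W - lr * (mW / corr1) / (sqrt(vW / corr2) + eps)
        mV <- beta1 * mV + (1 - beta1) * dV
        vV <- beta2 * vV + (1 - beta2) * dV^2
        par$V <- par$V - lr * (mV / corr1) / (sqrt(vV / corr2) + eps)
        mb <- beta1 * mb + (1 - beta1) * db
        vb <- beta2 * vb + (1 - beta2) * db^2
        par$b <- par$b - lr * (mb / corr1) / (sqrt(vb / corr2) + eps)
      }
      tr_loss <- eval_loss(X_tr, y_tr)
      va_loss <- eval_loss(X_va, y_va)
      log[nrow(log) + 1L, ] <- list(epoch, tr_loss, va_loss)
      if (va_loss < best$loss) {
        best <- list(loss = va_loss, W = par$W, V = par$V, b = par$b,
                      epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stopping_patience) break
      }
    }
  })
  pw_log("training stopped after %d epochs (best validation loss %.4f at epoch %d)",
         nrow(log), best$loss, best$epoch)

  trained <- Matrix::colSums(X_tr) > 0
  W <- best$W
  # rows of genes absent from every training path carry zero gradient and
  # zero Adam moments throughout, hence remain bit-identical to W0
  rownames(W) <- names(corpus$gene_index)
  structure(list(weights = W,
                 gene_index = corpus$gene_index,
                 trained_mask = stats::setNames(as.vector(trained),
                                                names(corpus$gene_index)),
                 model = list(W = W, V = best$V, b = best$b),
                 init_weights = W0,
                 log = log,
                 config = config),
            class = "gene_embedding")
}

#' @export
print.gene_embedding <- function(x, ...) {
  cat(sprintf("gene_embedding: %d genes x %d dimensions (%d trained, %d at initialization)\n",
              nrow(x$weights), ncol(x$weights), sum(x$trained_mask),
              sum(!x$trained_mask)))
  invisible(x)
}

#' Predict the origin probability of an encoded path
#'
#' @param model a trained \code{gene_embedding}, or a raw weight list with
#'   elements \code{W}, \code{V}, \code{b} as returned by
#'   \code{\link{init_model}}.
#' @param encoded binary numeric vector of length N (see
#'   \code{\link{encode_path}}).
#' @return probability in [0, 1] that the path came from the poor-outcome
#'   network.
#' @export
predict_path_origin <- function(model, encoded) {
  if (inherits(model, "gene_embedding")) model <- model$model
  if (length(encoded) != nrow(model$W))
    stop(sprintf("encoded path has length %d; expected %d",
                 length(encoded), nrow(model$W)))
  z <- sum((encoded %*% model$W) * model$V) + model$b
  stats::plogis(z)
}

#' Write a gene embedding as tab-separated text
#'
#' Columns: gene id, trained flag (0/1), then the M weight coordinates.
#' @param embedding a \code{gene_embedding}.
#' @param path output path.
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(gene = rownames(embedding$weights),
                   trained = as.integer(embedding$trained_mask),
                   embedding$weights, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a training log as JSON lines
#' @param embedding a \code{gene_embedding}.
#' @param path output path; one JSON object per epoch.
#' @export
write_training_log <- function(embedding, path) {
  lines <- vapply(seq_len(nrow(embedding$log)), function(i) {
    jsonlite::toJSON(as.list(embedding$log[i, ]), auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}
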