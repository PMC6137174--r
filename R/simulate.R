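# Synthetic cohort simulator: sparse gene network, two outcome groups with
# planted group-specific co-expression modules, and consistent survival times.

#' Configuration for a synthetic cohort
#'
#' Defaults describe a cohort with two 20-gene modules planted in a 500-gene,
#' 2000-edge network, 60 samples per outcome group, a two-standard-deviation
#' mean expression shift for planted genes and within-module co-expression of
#' 0.9 in the module's own outcome group.
#'
#' @param n_genes number of genes.
#' @param n_samples_per_group samples per outcome group.
#' @param n_network_edges number of distinct undirected edges; must be at
#'   least the number of edges needed to wire every planted module as a
#'   clique.
#' @param planted_module_sizes integer vector of planted module sizes; modules
#'   are assigned alternately to the good and poor group.
#' @param planted_effect mean expression shift (in expression units) of
#'   planted genes in their module's group relative to the other group.
#' @param within_module_corr target pairwise correlation of planted genes
#'   within their module's own group, in (0,1); induced by a shared latent
#'   factor per module.
#' @param noise_sd standard deviation of per-gene noise.
#' @param baseline mean log-scale expression of all genes.
#' @param criterion_days survival-time criterion used to generate consistent
#'   survival records.
#' @param seed master seed; all stages (network, expression, survival) draw
#'   from named substreams of it.
#' @return a list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_genes = 500L,
                          n_samples_per_group = 60L,
                          n_network_edges = 2000L,
                          planted_module_sizes = c(20L, 20L),
                          planted_effect = 2,
                          within_module_corr = 0.9,
                          noise_sd = 1,
                          baseline = 8,
                          criterion_days = 730,
                          seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_group = as.integer(n_samples_per_group),
              n_network_edges = as.integer(n_network_edges),
              planted_module_sizes = as.integer(planted_module_sizes),
              planted_effect = planted_effect,
              within_module_corr = within_module_corr,
              noise_sd = noise_sd,
              baseline = baseline,
              criterion_days = criterion_days,
              seed = as.integer(seed))
  if (sum(cfg$planted_module_sizes) > cfg$n_genes)
    stop("planted modules exceed n_genes")
  if (cfg$n_network_edges > cfg$n_genes * (cfg$n_genes - 1) / 2)
    stop("n_network_edges exceeds the number of possible gene pairs")
  clique_edges <- sum(choose(cfg$planted_module_sizes, 2))
  if (cfg$n_network_edges < clique_edges)
    stop("n_network_edges too small to wire planted modules as cliques")
  if (cfg$within_module_corr < 0 || cfg$within_module_corr >= 1)
    stop("within_module_corr must be in [0, 1)")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  structure(cfg, class = "cohort_config")
}

#' Simulate a synthetic cohort with planted prognostic structure
#'
#' Generates (i) a sparse undirected gene network in which each planted module
#' is wired as a clique and the remaining edge budget is spent on random
#' pairs, (ii) log-scale expression where each planted module's genes are
#' shifted by \code{planted_effect} and co-expressed (shared latent factor,
#' target correlation \code{within_module_corr}) in the module's own outcome
#' group only, with all other genes independent noise, and (iii) survival
#' records consistent with the labels under \code{\link{label_patients}} at
#' \code{criterion_days}.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return list with elements \code{data} (an
#'   \code{\link{expression_dataset}}), \code{survival} (data frame),
#'   \code{network} (edge data frame), \code{planted} (list: per-module gene
#'   ids and assigned group), \code{planted_genes} (all planted gene ids),
#'   \code{criterion_days}.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_genes
  genes <- sprintf("g%04d", seq_len(n))
  n_good <- config$n_samples_per_group
  n_poor <- config$n_samples_per_group
  samples <- c(sprintf("GOOD%03d", seq_len(n_good)),
               sprintf("POOR%03d", seq_len(n_poor)))
  labels <- stats::setNames(rep(c("good", "poor"), c(n_good, n_poor)), samples)

  sizes <- config$planted_module_sizes
  offsets <- cumsum(c(0L, sizes))
  modules <- lapply(seq_along(sizes), function(m) {
    list(genes = genes[(offsets[m] + 1L):offsets[m + 1L]],
         group = c("good", "poor")[(m - 1L) %% 2L + 1L])
  })
  planted_genes <- unlist(lapply(modules, `[[`, "genes"))

  network <- with_seed(substream_seed(config$seed, "network"), {
    clique <- do.call(rbind, lapply(modules, function(mod) {
      t(utils::combn(mod$genes, 2L))
    }))
    edges <- data.frame(from = clique[, 1], to = clique[, 2],
                        stringsAsFactors = FALSE)
    need <- config$n_network_edges - nrow(edges)
    seen <- new.env(hash = TRUE)
    for (k in seq_len(nrow(edges)))
      assign(paste(edges$from[k], edges$to[k], sep = "\r"), TRUE, envir = seen)
    extra_from <- character(need); extra_to <- character(need)
    got <- 0L
    while (got < need) {
      pair <- sort(genes[sample.int(n, 2L)])
      key <- paste(pair[1], pair[2], sep = "\r")
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        got <- got + 1L
        extra_from[got] <- pair[1]; extra_to[got] <- pair[2]
      }
    }
    rbind(edges, data.frame(from = extra_from, to = extra_to,
                            stringsAsFactors = FALSE))
  })

  expr <- with_seed(substream_seed(config$seed, "expression"), {
    m <- matrix(stats::rnorm(n * length(samples), mean = config$baseline,
                             sd = config$noise_sd),
                nrow = n, dimnames = list(genes, samples))
    rho <- config$within_module_corr
    for (mod in modules) {
      in_group <- which(labels == mod$group)
      f <- stats::rnorm(length(in_group))  # shared latent factor
      for (g in mod$genes) {
        eps <- stats::rnorm(length(in_group))
        m[g, in_group] <- config$baseline + config$planted_effect +
          config$noise_sd * (sqrt(rho) * f + sqrt(1 - rho) * eps)
      }
    }
    m
  })

  survival <- with_seed(substream_seed(config$seed, "survival"), {
    crit <- config$criterion_days
    time <- numeric(length(samples))
    event <- integer(length(samples))
    good <- labels == "good"
    time[good] <- crit + stats::runif(sum(good), 1, 2 * crit)
    event[good] <- 0L
    time[!good] <- stats::runif(sum(!good), 30, crit)
    event[!good] <- 1L
    data.frame(sample_id = samples, time_days = round(time, 1), event = event,
               stringsAsFactors = FALSE)
  })

  list(data = expression_dataset(expr, labels, survival = survival),
       survival = survival,
       network = network,
       planted = modules,
       planted_genes = planted_genes,
       criterion_days = config$criterion_days)
}
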