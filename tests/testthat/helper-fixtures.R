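# Shared fixtures, all built in code at test time.

# Hand-built correlation network from a weighted edge list.
toy_network <- function(edges, group = "good") {
  df <- data.frame(from = edges[[1]], to = edges[[2]],
                   weight = edges[[3]], stringsAsFactors = FALSE)
  progwalk:::correlation_network(group, df)
}

# A corpus built directly from explicit paths: list of list(genes, label).
toy_corpus <- function(train, validation, genes) {
  structure(list(train = train, validation = validation,
                 gene_index = stats::setNames(seq_along(genes), genes),
                 n_walks = length(train) + length(validation),
                 n_removed = 0L),
            class = "path_corpus")
}

path_of <- function(genes, label) list(genes = genes, label = label)

# Linearly separable toy corpus: good paths over one gene block, poor paths
# over a disjoint block.
separable_corpus <- function(n_each = 30, block = 5, n_genes = 20, seed = 11) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  good_pool <- genes[1:block]
  poor_pool <- genes[(block + 1):(2 * block)]
  withr_seed <- function(expr) progwalk:::with_seed(seed, expr)
  withr_seed({
    mk <- function(pool, label, n) {
      lapply(seq_len(n), function(i)
        path_of(sample(pool, sample(2:block, 1)), label))
    }
    train <- c(mk(good_pool, "good", n_each), mk(poor_pool, "poor", n_each))
    val <- c(mk(good_pool, "good", ceiling(n_each / 4)),
             mk(poor_pool, "poor", ceiling(n_each / 4)))
    toy_corpus(train, val, genes)
  })
}

# Small planted-structure cohort used across module tests (distinct from the
# larger acceptance fixture).
small_cohort <- function(seed = 7) {
  simulate_cohort(cohort_config(n_genes = 120L, n_samples_per_group = 30L,
                                n_network_edges = 400L,
                                planted_module_sizes = c(15L, 15L),
                                seed = seed))
}

# The acceptance-scale fixture: 500 genes, 60 samples per group, two planted
# 20-gene modules, effect 2*noise_sd, within-module correlation 0.9.
fixture_cohort <- function(seed = 42) {
  simulate_cohort(cohort_config(seed = seed))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
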