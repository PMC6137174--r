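# Internal helpers: reproducible seed substreams and scoped RNG use.

#' Derive a deterministic substream seed from a master seed and a stream name
#'
#' Every stochastic stage (network construction, expression noise, survival
#' times, walks, weight initialization, splits, folds) draws its seed from the
#' single top-level seed through this function, so each stage is reproducible
#' in isolation.
#'
#' @param seed integer master seed.
#' @param name character stream name, e.g. "network".
#' @return an integer in [0, 2^31 - 2].
#' @keywords internal
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) %% 2147483647) * 31 + h) %% 2147483647L
}

# Run `expr` under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Consistent INFO-level logging; suppressible via suppressMessages().
pw_log <- function(fmt, ...) {
  message(sprintf(paste0("[progwalk] ", fmt), ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
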