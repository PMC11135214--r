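#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` after seeding the global RNG with `seed`, then restores the
#' previous RNG state, so seeded generators do not perturb the caller's random
#' stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed
#'
#' Stage seeds are derived from one master seed by a fixed multiplicative
#' counter scheme, `(master * 48271 + 1 + stage) mod (2^31 - 1)`, so every
#' stage of a pipeline (graph, kingdoms, covariance, sampling, reads, each
#' method) is independently reproducible from `(master_seed, stage)`.
#'
#' @param master single integer master seed.
#' @param stage non-negative integer stage counter.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(42, 0)
#' child_seed(42, 1)
child_seed <- function(master, stage) {
  stopifnot(length(master) == 1L, length(stage) == 1L, stage >= 0)
  m <- 2147483647 # 2^31 - 1
  as.integer((abs(as.double(master)) %% m * 48271 + 1 + as.double(stage)) %% m)
}

# internal shorthand: positive scalar check
is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x > 0
}
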