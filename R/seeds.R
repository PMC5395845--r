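# Deterministic seed derivation and scoped RNG use.

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Folds the master seed and any number of string labels into a new seed in
#' `[0, 2^31 - 2]` with a multiplicative string hash. Each simulation stage
#' (predictor draws, outcome draws, row shuffling) and each population id gets
#' its own stream, so changing one stage's logic never silently shifts
#' another's random numbers.
#'
#' @param seed Integer master seed.
#' @param ... Character labels (stage names, population ids, grid values).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "A", "predictors")
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  h <- abs(as.double(seed)) %% m
  for (tok in as.character(unlist(list(...)))) {
    for (ch in utf8ToInt(tok)) h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}
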