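# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a per-trial random seed
#'
#' Deterministic, documented mixing of a master seed with the class id and the
#' replicate index, so that a dataset is reproducible trial by trial and
#' individual trials can be regenerated in isolation.  The recurrence is a
#' 32-bit multiplicative congruential step, `s <- (s * 69069 + key) mod 2^31`,
#' applied to the class id and then the replicate index; it is stable across
#' package versions.
#'
#' @param master_seed integer master seed for the whole dataset.
#' @param class_id gesture class, integer 1..9.
#' @param replicate replicate index within the class, integer >= 1.
#' @return an integer seed in `[0, 2^31)`.
#' @export
trial_seed <- function(master_seed, class_id, replicate) {
  m <- 2^31
  s <- as.numeric(master_seed) %% m
  s <- (s * 69069 + as.numeric(class_id)) %% m
  s <- (s * 69069 + as.numeric(replicate)) %% m
  as.integer(s)
}

# sign() with sign(0) -> +1, the tie rule used throughout the binarized
# datapath (an accumulator equal to its threshold fires).
sign0 <- function(x) {
  ifelse(x >= 0, 1, -1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
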