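# Internal helpers: seeded evaluation and per-part seed derivation.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic stream split: map (master_seed, index) to a seed in
# [1, 2^31 - 2] by an LCG-style mix in double precision (exact below 2^53).
# Parts therefore get independent, schedule-invariant seeds.
derive_seed <- function(master_seed, index) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.numeric(master_seed) %% m
  x <- (s * 48271 + 1) %% m
  x <- (x * 16807 + (as.numeric(index) + 1) * 69621) %% m
  as.integer(x %% (m - 2)) + 1L
}

# Consistent error class so callers can distinguish bad configuration
# from bad data.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("smurfens_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("smurfens_data_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
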