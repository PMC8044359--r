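# Internal helpers: seeded evaluation without touching the caller's RNG
# state, and deterministic per-stage seed fan-out.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Derive a stage/replicate seed from one global seed; stays inside the
# 32-bit integer range required by set.seed().
seedStream <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %%
               2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pearson correlation that returns NA (rather than erroring/warning) for
# degenerate inputs; used by the CV harness which must flag such folds.
safeCor <- function(x, y) {
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}
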