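`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `code` under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# counter-derived replicate seed, kept inside 32-bit integer range
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) + 7919 * as.numeric(counter)) %% 2147483629 + 1)
}

# numerically stable log(1 + exp(x))
log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 1 && x == floor(x)

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
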