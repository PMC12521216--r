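# internal helpers shared across modules

# data.table is used via :: only
.datatable.aware <- TRUE

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package route through this.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream seed from a root seed; keeps results independent across
# streams while remaining reproducible from one root. Kept below 2^31.
fan_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483629
}

# argmax with deterministic lowest-index tie-break
argmax_first <- function(x) which(x == max(x))[1L]

# modal value of an integer vector; ties broken toward the lowest value
mode_lowest <- function(x) {
  vals <- sort(unique(x))
  counts <- tabulate(match(x, vals))
  vals[argmax_first(counts)]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
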