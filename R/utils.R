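# internal helpers shared across modules

abort <- function(..., class = "glioscan_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

abort_validation <- function(...) abort(..., class = "glioscan_validation_error")
abort_io <- function(...) abort(..., class = "glioscan_io_error")

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
# Keeps package functions from clobbering the user's random stream.
with_seed <- function(seed, expr) {
  if (!is_count(seed)) abort_validation("seed must be a non-negative integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a stream of child seeds from one master seed, each < 2^31
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
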