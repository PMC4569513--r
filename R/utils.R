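# internal helpers

# stop with a classed condition so tests can target specific failures
stop_limbperf <- function(msg, class) {
  abort(msg, class = c(class, "limbperf_error"))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# run code with a private RNG stream, restoring the caller's state afterwards
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# derive a child seed that stays inside the 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483629)
}
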