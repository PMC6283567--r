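# internal helpers

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL leaves the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic substream seeds below 2^31 (R integers are 32-bit).
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 69621) %% 2147483587)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x == round(x) && x >= 0
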