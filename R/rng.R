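# Named, independently seeded random streams. Each stochastic process
# (germination, placement, management efficacy, ...) draws from its own
# stream derived from a master seed, so that switching off the weed seed
# bank leaves every crop-related draw unchanged (the paired-run contract).

# Derive a 31-bit sub-seed from a master seed and a stream name.
stream_seed <- function(master, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483629
  as.integer((as.numeric(master) %% 2147483629 * 7919 + h) %% 2147483629) + 1L
}

# Evaluate expr with the RNG temporarily seeded from (master, name),
# restoring the caller's RNG state afterwards.
with_stream <- function(master, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(stream_seed(master, name))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# A stateful stream object: an environment holding its own RNG state.
new_stream <- function(master, name) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(stream_seed(master, name))
  env$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  env
}

# Draw from a stream: run expr under the stream's RNG state and advance it.
draw <- function(stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", stream$state, envir = globalenv())
  out <- expr
  stream$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  out
}
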