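## evaluate expr with a temporary RNG state seeded by `seed`, restoring
## the caller's stream afterwards
with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## derive a child seed from a master seed and integer tags, keeping the
## result a valid 32-bit integer; used to give every cell/condition an
## independent, reproducible stream
child_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (v in tags) h <- (h * 69069 + as.numeric(v) + 1) %% 2147483647
  as.integer(h)
}
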