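# internal helpers

# evaluate expr with a local RNG state seeded by `seed`; restores the caller's
# RNG afterwards so library code never disturbs user-level reproducibility
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# deterministic child seed, kept below 2^31 - 1
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (i in seq_along(idx))
    s <- (s * 69069 + as.numeric(idx[i]) * 104729 + 1) %% 2147483647
  as.integer(s)
}
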