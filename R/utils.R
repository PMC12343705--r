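## Evaluate `expr` under a temporary RNG state when `seed` is given,
## restoring the caller's state afterwards; with seed = NULL the global
## stream is used untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Independent child seeds below 2^31, derived deterministically from a
## master seed (NULL master -> NULL children).
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}
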