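## Internal helpers.

## Evaluate expr with a locally seeded Mersenne-Twister RNG, restoring the
## caller's RNG state afterwards, so seeded package operations never perturb
## user code and are reproducible regardless of surrounding RNG use.
withSeed <- function(seed, expr) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

## stable descending order of a numeric vector (ties keep input order)
orderDescStable <- function(x) order(-x, seq_along(x))
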