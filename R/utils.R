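## Internal helpers shared across modules.

## Evaluate expr with a local RNG state seeded by `seed`, restoring the
## caller's state afterwards. All randomness in the package flows through
## explicit seed arguments; there is no reliance on ambient global state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Derive a stream of child seeds from one parent seed, staying within the
## 32-bit integer range.
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "flowPE_error")))
}

warnf <- function(fmt, ..., class = "flowPE_warning") {
  warning(warningCondition(sprintf(fmt, ...), class = c(class, "flowPE_warning")))
}

## Display rounding used for reported tables: pg to 2 decimals, percent to 1.
roundPg <- function(x) round(x, 2)
roundPct <- function(x) round(x, 1)
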