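# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without clobbering the caller's
# stream. `seed = NULL` leaves the current stream untouched.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed from a master seed and an integer key; keeps the
# result a valid 32-bit R integer so stochastic streams per grain size (or
# per scenario component) are decoupled but reproducible.
subSeed <- function(master, key) {
  as.integer((as.numeric(master) %% 2147483629 * 7919 +
              as.numeric(key) * 104729 + 17) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Significance codes as printed under community-ordination bar plots.
signifCode <- function(p) {
  ifelse(p < 0.001, "***",
  ifelse(p < 0.01,  "**",
  ifelse(p < 0.05,  "*",
  ifelse(p < 0.1,   ".", ""))))
}
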