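# Internal helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed` (if not NA),
# restoring the caller's RNG state afterwards. Keeps every generator
# reproducible without clobbering the global stream.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, staying within
# 32-bit integer range.
childSeed <- function(seed, stream) {
  if (is.null(seed) || is.na(seed)) return(NA_integer_)
  as.integer((as.numeric(seed) * 7919 + 104729 * stream) %% 2147483647)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Draw from N(mean, v) where v is read as a variance or an SD depending on
# the convention flag; the source text writes N(0, 0.1)-style parameters
# without disambiguating, so both readings are supported.
rnormConv <- function(n, mean, v, convention = c("variance", "sd")) {
  convention <- match.arg(convention)
  sdv <- if (convention == "variance") sqrt(v) else v
  stats::rnorm(n, mean = mean, sd = sdv)
}
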