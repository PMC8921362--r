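# run code with a local, restored RNG state so seeded generators never
# disturb (or depend on) the caller's random stream
withLocalSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# derived child seed for per-phantom reproducibility; stays inside 32-bit range
childSeed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + i * 104729) %% 2147483629)
}

# display rounding used by the published tables: 1 decimal, half-up
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
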