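# internal helpers shared across modules

# half-up decimal rounding for display tables (R's round() is half-to-even)
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# derive an independent substream seed from a global seed and a generator tag,
# so changing one generator's parameters never perturbs another's draws
substream_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  v <- utf8ToInt(tag)
  h <- sum(v * seq_along(v))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

# evaluate expr under a locally seeded RNG, restoring the caller's RNG state
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}
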