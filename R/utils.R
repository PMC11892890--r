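# Internal helpers: seeded evaluation that does not disturb the caller's RNG
# stream, and deterministic sub-seed derivation.

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Linear-congruential scramble keeps derived seeds inside 32-bit range.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + 12345 + 1000003 * k) %%
               2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}
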