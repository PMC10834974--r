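# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stage index, kept within the
# 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 12347) %%
               .Machine$integer.max)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
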