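# internal helpers

# evaluate code under a temporary RNG state so generators are
# deterministic without clobbering the caller's stream
withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

# derive a stream of per-unit seeds from a master seed, kept within the
# 32-bit integer range
deriveSeeds <- function(seed, n, salt = 0L) {
    as.integer((as.double(seed) + 7919 * (seq_len(n) + as.double(salt) * 1e4)) %%
               2147483587)
}

# round half away from zero (base round() is half-even)
roundHalfUp <- function(x) floor(x + 0.5)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
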