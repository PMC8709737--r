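# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's stream.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        stop("seed must be a single finite number")
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Fan a single pipeline seed out into named per-stage seeds so stages can be
# re-run in isolation deterministically.
deriveSeeds <- function(seed, stages) {
    s <- withSeed(seed, sample.int(.Machine$integer.max - 1L, length(stages)))
    names(s) <- stages
    s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
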