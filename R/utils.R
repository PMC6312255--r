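# Internal helpers shared across modules.

# Evaluate expr with a local RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user
# randomness.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# Stable per-stage child seed: a small multiplicative hash of the stage
# name folded into the global seed, kept inside the 32-bit integer range.
childSeed <- function(seed, stage) {
    h <- 0
    for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 1000003
    as.integer((as.numeric(seed) * 7919 + h) %% 2147483587 + 1)
}

# Two-sided empirical direction: sign of a difference, as integer -1/0/1.
signDir <- function(x) as.integer(sign(x))

.doseGroupLevels <- c("control", "low", "medium", "high")
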