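# Internal helpers shared across modules.

# Round half away from zero (the convention that reproduces printed
# percentages such as 91.38 from 297/325); base round() is half-to-even.
.roundAway <- function(x, digits = 2L) {
    p <- 10^digits
    sign(x) * trunc(abs(x) * p + 0.5) / p
}

# Percentage of num/den, two decimals, half away from zero.
.pctAway <- function(num, den, digits = 2L) .roundAway(100 * num / den, digits)

.assertScalarNumber <- function(x, name, lo = -Inf, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
        stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi),
             call. = FALSE)
    invisible(x)
}

.assertRate <- function(x, name) .assertScalarNumber(x, name, 0, 1)

# Seed scope: set the seed for the duration of the calling function only,
# restoring the caller's RNG state on exit.
.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        if (has) old <- get(".Random.seed", envir = globalenv())
        set.seed(seed)
        on.exit({
            if (has) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
    }
    force(expr)
}
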