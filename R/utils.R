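# Run expr under a fixed RNG seed, restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv(),
                           inherits = FALSE))
                    rm(".Random.seed", envir = globalenv())
            } else {
                assign(".Random.seed", old, envir = globalenv())
            }
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
    out <- x
    lo <- x <= 30
    out[lo] <- log1p(exp(x[lo]))
    out[!lo] <- x[!lo] + log1p(exp(-x[!lo]))
    out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# lexicographically smallest label among the (numerically) tied minima;
# the relative tolerance only merges residuals equal up to float noise
argminLabel <- function(resid, relTol = 1e-9) {
    rmin <- min(resid)
    near <- resid <= rmin + relTol * max(rmin, .Machine$double.eps)
    sort(names(resid)[near])[1L]
}
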