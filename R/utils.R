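# Nearest-integer rounding with ties half-up, the convention used when
# richness estimates are reported in inventory tables.
roundHalfUp <- function(x) floor(x + 0.5)

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (is.null(seed) || is.na(seed))
        return(eval.parent(substitute(expr)))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    eval.parent(substitute(expr))
}

.detectSep <- function(path) {
    header <- readLines(path, n = 1L)
    if (grepl("\t", header)) "\t" else ","
}

.assertCount <- function(x, name, min = 0) {
    if (length(x) != 1L || is.na(x) || x != round(x) || x < min)
        stop(sprintf("'%s' must be a single integer >= %d", name, min),
            call. = FALSE)
    as.numeric(x)
}

.newEstimate <- function(estimator, point, sObs, inputs = list(),
                         class = "RichnessEstimate", ...) {
    new(class, estimator = estimator, point = as.numeric(point),
        pointRounded = roundHalfUp(point), sObs = as.numeric(sObs),
        inputs = inputs, ...)
}
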