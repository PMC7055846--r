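# Independent oracles and fixture generators shared across the test files.
# Every oracle here is written as naive, explicit looping over the raw data,
# deliberately not reusing any package internals.

# Combined non-parametric estimator by brute-force per-site loops.
cneOracle <- function(m, corrected = TRUE) {
    m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
    n <- nrow(m)
    occ <- colSums(m > 0)
    sObs <- ncol(m)
    q1h <- 0
    q2h <- 0
    for (i in seq_len(n)) {
        x <- m[i, ]
        pres <- x > 0
        sobs_i <- sum(pres)
        f1 <- sum(x == 1)
        f2 <- sum(x == 2)
        uni <- sum(pres & occ == 1)
        dup <- sum(pres & occ == 2)
        denom <- if (corrected) 2 * (f2 + 1) else 2 * f2 + 1
        extra <- f1 * (f1 - 1) / denom
        q1h <- q1h + uni + extra * uni / sobs_i
        q2h <- q2h + dup + extra * dup / sobs_i
    }
    q2h <- q2h / 2
    den <- if (corrected) 2 * (q2h + 1) else 2 * q2h + 1
    sObs + q1h * (q1h - 1) / den
}

# Random small abundance matrix with at least minSites non-empty sites.
randomCountMatrix <- function(nsites, nspecies, lambda = 0.8) {
    repeat {
        m <- matrix(rpois(nsites * nspecies, lambda), nsites, nspecies,
            dimnames = list(paste0("t", seq_len(nsites)),
                paste0("sp", seq_len(nspecies))))
        m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
        if (nrow(m) >= 2 && ncol(m) >= 2) return(m)
    }
}

# All permutations of 1..n (n <= 6), one per row.
allPermutations <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- allPermutations(n - 1)
    out <- matrix(0L, n * nrow(sub), n)
    r <- 0L
    for (k in seq_len(n)) {
        for (j in seq_len(nrow(sub))) {
            r <- r + 1L
            rest <- seq_len(n)[-k]
            out[r, ] <- c(k, rest[sub[j, ]])
        }
    }
    out
}

# Exact mean accumulation curve by exhaustive enumeration of site orders.
accumulationOracle <- function(pres) {
    n <- nrow(pres)
    perms <- allPermutations(n)
    curves <- matrix(0, nrow(perms), n)
    for (r in seq_len(nrow(perms))) {
        seen <- rep(FALSE, ncol(pres))
        for (k in seq_len(n)) {
            seen <- seen | pres[perms[r, k], ]
            curves[r, k] <- sum(seen)
        }
    }
    colMeans(curves)
}

# Closed-form expected accumulation curve (hypergeometric site sampling).
accumulationClosedForm <- function(pres) {
    n <- nrow(pres)
    occ <- colSums(pres)
    vapply(seq_len(n), function(k)
        sum(1 - choose(n - occ, k) / choose(n, k)), numeric(1))
}

# First-order jackknife by brute-force leave-one-site-out resampling:
# jack1 = n * S_obs - (n - 1) * mean(S_{-i}).
jack1Oracle <- function(pres) {
    n <- nrow(pres)
    sObs <- sum(colSums(pres) > 0)
    sMinus <- vapply(seq_len(n), function(i)
        sum(colSums(pres[-i, , drop = FALSE]) > 0), numeric(1))
    n * sObs - (n - 1) * mean(sMinus)
}

# Toy two-site matrix used in several worked examples.
toyTwoSiteMatrix <- function() {
    AbundanceMatrix(rbind(
        site1 = c(s1 = 1, s2 = 2, s3 = 3, s4 = 0, s5 = 0),
        site2 = c(s1 = 0, s2 = 1, s3 = 0, s4 = 1, s5 = 2)))
}

# Write a small records CSV and return its path.
writeRecordsFixture <- function(lines, file = tempfile(fileext = ".csv")) {
    writeLines(lines, file)
    file
}
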