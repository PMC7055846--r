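#' Specification of a synthetic regional community
#'
#' Defines the ground truth for the estimator test-bed: a regional species
#' pool with lognormal relative abundances, restricted per-species site
#' occupancy (the heterogeneity knob), and per-site sampling effort.  The
#' defaults emulate a large heterogeneous region sampled by a modest number
#' of traps: each species occupies a random subset of sites (independent
#' Bernoulli per site with mean occupancy 0.3), relative abundances are
#' lognormal with sdlog 1.5 (a typical steep species-abundance distribution),
#' and effort controls the coverage of the pool that the sample achieves.
#'
#' @param poolSize true regional richness S.
#' @param nSites number of sampling sites (traps).
#' @param effortPerSite expected number of specimens per site; scalar or
#'   vector of length nSites.
#' @param occupancy list; either \code{list(type = "probability", p = 0.3)}
#'   with p a scalar or per-species vector of site-occupancy probabilities,
#'   or \code{list(type = "fixed", k = 3)} placing each species at exactly k
#'   random sites.
#' @param abundance list with meanlog and sdlog of the lognormal relative
#'   abundance distribution.
#' @param seed mandatory RNG seed (reproducibility is part of the contract;
#'   no global RNG state is consumed).
#' @return a list of class-free spec fields, consumed by
#'   [simulateCommunity()].
#' @export
communitySpec <- function(poolSize, nSites, effortPerSite,
    occupancy = list(type = "probability", p = 0.3),
    abundance = list(meanlog = 0, sdlog = 1.5),
    seed) {
    if (missing(seed) || is.null(seed) || is.na(seed))
        stop("a seed is mandatory in a community spec", call. = FALSE)
    poolSize <- .assertCount(poolSize, "poolSize", min = 1)
    nSites <- .assertCount(nSites, "nSites", min = 1)
    if (any(effortPerSite < 0))
        stop("effortPerSite must be non-negative", call. = FALSE)
    if (!length(effortPerSite) %in% c(1L, nSites))
        stop("effortPerSite must be scalar or one value per site",
            call. = FALSE)
    if (occupancy$type == "fixed" && occupancy$k > nSites)
        stop("fixed occupancy k exceeds the number of sites", call. = FALSE)
    if (occupancy$type == "probability" &&
        (any(occupancy$p < 0) || any(occupancy$p > 1)))
        stop("occupancy probability must lie in [0, 1]", call. = FALSE)
    list(poolSize = poolSize, nSites = nSites,
        effortPerSite = rep(effortPerSite, length.out = nSites),
        occupancy = occupancy, abundance = abundance, seed = seed)
}

#' Simulate a multi-site community sample
#'
#' Generation proceeds in three seeded steps: (1) per-species relative
#' abundances are drawn from the lognormal model; (2) the true occupancy
#' matrix is drawn per the occupancy model; (3) per-site specimen counts are
#' drawn as independent Poisson counts with rates proportional to relative
#' abundance x occupancy, normalised within each site so the expected site
#' total equals the site's effort.  Everything is deterministic given the
#' spec's seed.  Species that occupy no site remain part of the true pool
#' but can never be sampled.
#'
#' @param spec a [communitySpec()].
#' @return a [SyntheticCommunity-class]; its \code{sampled} slot drops empty
#'   rows and columns (and may be an empty matrix at effort 0).
#' @examples
#' com <- simulateCommunity(communitySpec(poolSize = 50, nSites = 6,
#'     effortPerSite = 100, seed = 1))
#' poolSize(com); com@sampled
#' @export
simulateCommunity <- function(spec) {
    withSeed(spec$seed, {
        S <- spec$poolSize
        n <- spec$nSites
        w <- stats::rlnorm(S, spec$abundance$meanlog, spec$abundance$sdlog)
        occ <- spec$occupancy
        Z <- if (occ$type == "fixed") {
            z <- matrix(FALSE, n, S)
            for (k in seq_len(S)) z[sample.int(n, occ$k), k] <- TRUE
            z
        } else {
            p <- rep(occ$p, length.out = S)
            matrix(stats::rbinom(n * S, 1L, rep(p, each = n)) > 0, n, S)
        }
        dimnames(Z) <- list(sprintf("site%02d", seq_len(n)),
            sprintf("sp%04d", seq_len(S)))
        cnts <- matrix(0, n, S, dimnames = dimnames(Z))
        for (i in seq_len(n)) {
            wi <- w * Z[i, ]
            tot <- sum(wi)
            if (tot > 0 && spec$effortPerSite[i] > 0)
                cnts[i, ] <- stats::rpois(S, spec$effortPerSite[i] * wi / tot)
        }
        new("SyntheticCommunity", spec = spec, trueOccupancy = Z,
            sampled = AbundanceMatrix(cnts), trueRichness = S)
    })
}

#' Binomial thinning of an abundance matrix
#'
#' Emulates processing only a fraction of the catch: each cell count is
#' thinned binomially with the given retention fraction.  Empty rows and
#' columns are dropped from the result.
#'
#' @param x an [AbundanceMatrix-class].
#' @param fraction retention probability in (0, 1].
#' @param seed RNG seed.
#' @return an [AbundanceMatrix-class].
#' @export
subsampleMatrix <- function(x, fraction, seed) {
    if (length(fraction) != 1L || is.na(fraction) || fraction <= 0 ||
        fraction > 1)
        stop("fraction must lie in (0, 1]", call. = FALSE)
    m <- counts(x)
    if (fraction == 1) return(x)
    withSeed(seed, {
        thinned <- matrix(stats::rbinom(length(m), as.integer(m), fraction),
            nrow = nrow(m), dimnames = dimnames(m))
        AbundanceMatrix(thinned)
    })
}

#' Species-pool coverage of a synthetic sample
#'
#' @param community a [SyntheticCommunity-class].
#' @return S_obs / true pool size, in [0, 1].
#' @export
coverageOf <- function(community) {
    nSpecies(community@sampled) / community@trueRichness
}
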