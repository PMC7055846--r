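#' Proportion of species with a focal trait, per site group
#'
#' Pools the sites of each group, takes the distinct species present there,
#' and returns the fraction carrying the focal trait label (e.g. the
#' proportion of Diptera species per biogeographic zone).  Species missing
#' the trait are excluded with a warning.
#'
#' @param x an [IncidenceMatrix-class] or [AbundanceMatrix-class].
#' @param traits data.frame with a \code{species} column and one column per
#'   trait (order-level taxon, feeding niche, microhabitat, ...); at most one
#'   label per species and trait.
#' @param siteGroups named character/factor vector mapping every site id to a
#'   group.
#' @param trait name of the trait column to use.
#' @param focal the trait level whose proportion is computed.
#' @return named numeric vector of per-group proportions, ordered by the
#'   group factor levels.
#' @export
proportionByGroup <- function(x, traits, siteGroups, trait, focal) {
    p <- presence(x)
    sites <- rownames(p)
    if (!all(sites %in% names(siteGroups)))
        stop("every site must be assigned to a group", call. = FALSE)
    g <- factor(siteGroups[sites])
    lab <- traits[[trait]][match(colnames(p), traits$species)]
    miss <- is.na(lab)
    if (any(miss)) {
        warning(sum(miss), " species missing trait '", trait,
            "'; excluded")
        p <- p[, !miss, drop = FALSE]
        lab <- lab[!miss]
    }
    out <- vapply(levels(g), function(gr) {
        present <- colSums(p[g == gr, , drop = FALSE]) > 0
        if (!any(present))
            stop("group '", gr, "' contains no species", call. = FALSE)
        mean(lab[present] == focal)
    }, numeric(1))
    out
}

.groupStatistic <- function(props, statistic) {
    if (statistic == "extreme_diff") {
        unname(props[length(props)] - props[1])
    } else {  # trend: least-squares slope of proportion on group rank
        k <- seq_along(props)
        unname(stats::cov(k, props) / stats::var(k))
    }
}

# All distinct assignments of the multiset of group labels to sites.
.enumerateAssignments <- function(g) {
    n <- length(g)
    lv <- levels(g)
    res <- list()
    recurse <- function(remaining, current) {
        if (!length(remaining)) {
            res[[length(res) + 1L]] <<- current
            return(invisible())
        }
        for (l in unique(remaining)) {
            idx <- match(l, remaining)
            recurse(remaining[-idx], c(current, l))
        }
    }
    recurse(sort(as.character(g)), character(0))
    lapply(res, function(v) factor(v, levels = lv))
}

#' Permutation test for a compositional trend across site groups
#'
#' Tests whether the proportion of species with a focal trait differs across
#' an ordered set of site groups (e.g. biogeographic zones) by permuting the
#' site-to-group assignments.  Two statistics are available: the difference
#' in proportion between the last and first group along the stated ordering
#' (\code{"extreme_diff"}, the default) and the least-squares slope of the
#' proportions on group rank (\code{"trend"}).  The default sidedness is
#' one-sided in the observed direction.  The Monte-Carlo p-value uses the
#' add-one convention, \eqn{p = (1 + \#\{null \ge obs\}) / (n + 1)}, so p is
#' never zero; with \code{exhaustive = TRUE} all distinct assignments are
#' enumerated instead and p is the exact proportion of assignments at least
#' as extreme as the observed one.
#'
#' @inheritParams proportionByGroup
#' @param statistic "extreme_diff" or "trend".
#' @param alternative "observed" (one-sided in the observed direction),
#'   "greater", or "less".
#' @param nPermutations number of random permutations (default 10000).
#' @param seed RNG seed (required unless exhaustive).
#' @param exhaustive enumerate all distinct site-to-group assignments
#'   (feasible only for small site sets).
#' @return a [PermutationTestResult-class].
#' @export
permutationTest <- function(x, traits, siteGroups, trait, focal,
    statistic = c("extreme_diff", "trend"),
    alternative = c("observed", "greater", "less"),
    nPermutations = 10000, seed = NULL, exhaustive = FALSE) {
    statistic <- match.arg(statistic)
    alternative <- match.arg(alternative)
    p <- presence(x)
    sites <- rownames(p)
    if (!all(sites %in% names(siteGroups)))
        stop("every site must be assigned to a group", call. = FALSE)
    g <- factor(siteGroups[sites])
    if (nlevels(g) < 2)
        stop("permutation test needs at least 2 site groups", call. = FALSE)
    statFun <- function(assign) {
        names(assign) <- sites
        props <- suppressWarnings(
            proportionByGroup(x, traits, assign, trait, focal))
        .groupStatistic(props, statistic)
    }
    observed <- statFun(g)
    dir <- switch(alternative,
        greater = 1,
        less = -1,
        observed = if (observed >= 0) 1 else -1)
    if (exhaustive) {
        assigns <- .enumerateAssignments(g)
        nullStats <- vapply(assigns, statFun, numeric(1))
        pval <- mean(nullStats * dir >= observed * dir - 1e-12)
        nPermutations <- length(assigns)
        seedOut <- NA_real_
    } else {
        if (is.null(seed))
            stop("a seed is required for Monte-Carlo permutations",
                call. = FALSE)
        nullStats <- withSeed(seed, vapply(seq_len(nPermutations),
            function(r) statFun(sample(g)), numeric(1)))
        pval <- (1 + sum(nullStats * dir >= observed * dir - 1e-12)) /
            (nPermutations + 1)
        seedOut <- as.numeric(seed)
    }
    new("PermutationTestResult", observed = observed, nullStats = nullStats,
        pValue = pval, nPermutations = as.numeric(nPermutations),
        seed = seedOut, statistic = statistic, alternative = alternative)
}

#' Species-area power-law exponent
#'
#' Under a power law \eqn{S = c A^z} with c = 1, the exponent implied by a
#' single (richness, area) pair is \eqn{z = \ln S / \ln A}.
#'
#' @param richness number of species (>= 1).
#' @param area region area (> 1, in any fixed unit).
#' @return the exponent ln(richness)/ln(area).
#' @export
speciesAreaExponent <- function(richness, area) {
    if (any(richness < 1)) stop("richness must be >= 1", call. = FALSE)
    if (any(area <= 1))
        stop("area must exceed 1 (in its measurement unit) for the ",
            "log-ratio to be defined", call. = FALSE)
    log(richness) / log(area)
}

#' Area-controlled latitudinal richness regression
#'
#' Ordinary least squares of ln(richness) on ln(area) across countries (the
#' species-area relationship), followed by a regression of the residuals on
#' latitude — the latitudinal gradient after the area effect is removed.
#' Outlier countries can be excluded by name.
#'
#' @param faunaTable data.frame with columns country, richness, area,
#'   latitude.
#' @param exclude character vector of country names to drop before fitting.
#' @return list with elements \code{areaFit} (lm of log richness on log
#'   area), \code{latitudeFit} (lm of the residuals on latitude),
#'   \code{residuals} (named by country), \code{latitudeSlope},
#'   \code{latitudePValue}, \code{rSquared} (of the latitude fit), and
#'   \code{excluded}.
#' @export
areaControlledRichness <- function(faunaTable, exclude = character()) {
    d <- faunaTable[!faunaTable$country %in% exclude, , drop = FALSE]
    if (nrow(d) < 3)
        stop("at least 3 countries required", call. = FALSE)
    areaFit <- stats::lm(log(richness) ~ log(area), data = d)
    res <- stats::residuals(areaFit)
    names(res) <- d$country
    latFit <- stats::lm(res ~ d$latitude)
    sm <- summary(latFit)
    list(areaFit = areaFit, latitudeFit = latFit, residuals = res,
        latitudeSlope = unname(stats::coef(latFit)[2]),
        latitudePValue = unname(sm$coefficients[2, 4]),
        rSquared = sm$r.squared, excluded = exclude)
}
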