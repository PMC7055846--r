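#' @import methods
NULL

.checkSiteSpeciesMatrix <- function(m, what) {
    msg <- character()
    if (!is.matrix(m))
        return(sprintf("'%s' must be a matrix", what))
    if (length(m) == 0)
        return(msg)   # an empty sample is a valid (vacuous) matrix
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msg <- c(msg, "matrix must carry site (row) and species (column) names")
    else {
        if (anyDuplicated(rownames(m)))
            msg <- c(msg, "duplicated site ids")
        if (anyDuplicated(colnames(m)))
            msg <- c(msg, "duplicated species ids")
    }
    msg
}

#' Site-by-species abundance matrix
#'
#' Core container for inventory count data: rows are sites (traps), columns
#' are species, cells are non-negative integer specimen counts.  Validity
#' requires unique dimnames and, for non-empty matrices, no all-zero row or
#' column (empty sites carry no information and all-zero species are
#' non-observations).
#'
#' @slot counts integer matrix, sites x species, with dimnames.
#' @seealso [AbundanceMatrix()] for construction from raw counts,
#'   [buildMatrix()] for construction from records.
#' @export
setClass("AbundanceMatrix", representation(counts = "matrix"))

setValidity("AbundanceMatrix", function(object) {
    m <- object@counts
    msg <- .checkSiteSpeciesMatrix(m, "counts")
    if (length(msg)) return(msg)
    if (length(m)) {
        if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
            msg <- c(msg, "counts must be non-negative integers")
        else {
            if (any(rowSums(m) == 0)) msg <- c(msg, "all-zero site row present")
            if (any(colSums(m) == 0)) msg <- c(msg, "all-zero species column present")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Site-by-species incidence (presence/absence) matrix
#'
#' @slot presence logical matrix, sites x species, with dimnames.
#' @export
setClass("IncidenceMatrix", representation(presence = "matrix"))

setValidity("IncidenceMatrix", function(object) {
    m <- object@presence
    msg <- .checkSiteSpeciesMatrix(m, "presence")
    if (length(msg)) return(msg)
    if (length(m)) {
        if (!is.logical(m) || any(is.na(m)))
            msg <- c(msg, "presence must be logical with no NA")
        else {
            if (any(rowSums(m) == 0)) msg <- c(msg, "all-zero site row present")
            if (any(colSums(m) == 0)) msg <- c(msg, "all-zero species column present")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Prior checklist of known species for a group
#'
#' The set of species known before the inventory started (S_known of the
#' mark-recapture estimator).
#'
#' @slot groupName single character label for the taxon group.
#' @slot species character vector of unique taxon labels.
#' @export
setClass("KnownPool",
    representation(groupName = "character", species = "character"))

setValidity("KnownPool", function(object) {
    msg <- character()
    if (length(object@groupName) != 1L)
        msg <- c(msg, "groupName must be a single string")
    if (anyDuplicated(object@species))
        msg <- c(msg, "species labels must be unique")
    if (length(msg)) msg else TRUE
})

#' Universal richness-estimate record
#'
#' Every estimator in the package returns (a subclass of) this object: the
#' estimator name, the real-valued point estimate, its nearest-integer report
#' value (ties rounded half-up, matching how inventory tables print
#' estimates), the observed richness, and a digest of the inputs used.
#'
#' @slot estimator character name tag, e.g. "chao1".
#' @slot point numeric point estimate (>= 0).
#' @slot pointRounded numeric nearest-integer report value.
#' @slot sObs observed species richness behind the estimate.
#' @slot inputs named list summarising the inputs used.
#' @export
setClass("RichnessEstimate",
    representation(estimator = "character", point = "numeric",
        pointRounded = "numeric", sObs = "numeric", inputs = "list"))

setValidity("RichnessEstimate", function(object) {
    msg <- character()
    if (length(object@point) != 1L || is.na(object@point) || object@point < 0)
        msg <- c(msg, "point must be a single non-negative number")
    if (length(msg)) msg else TRUE
})

#' Combined non-parametric estimate with per-site breakdown
#'
#' Result of [cneEstimate()]: the point estimate together with the per-site
#' extrapolations and the across-site extrapolated counts of uniques
#' (\code{q1Hat}) and duplicates (\code{q2Hat}) that feed the final
#' Chao2-type step.
#'
#' @slot perSite data.frame with one row per site: observed richness,
#'   within-site singleton/doubleton counts, observed uniques/duplicates, and
#'   the extrapolated sHat, s1Hat, s2Hat.
#' @slot q1Hat estimated number of unique species (>= observed Q1).
#' @slot q2Hat estimated number of duplicate species (>= observed Q2).
#' @export
setClass("CNEEstimate", contains = "RichnessEstimate",
    representation(perSite = "data.frame", q1Hat = "numeric",
        q2Hat = "numeric"))

#' Preston lognormal fit
#'
#' Gaussian fit to species frequencies on the log2 abundance octave scale.
#' The area under the fitted Gaussian estimates total (veiled + observed)
#' richness; the point estimate is clamped below at the observed richness.
#'
#' @slot modeHeight fitted Gaussian height at the mode.
#' @slot modeLocation octave of the mode.
#' @slot width fitted Gaussian width (standard deviation in octaves).
#' @slot veiledRichness area under the fitted Gaussian,
#'   modeHeight * width * sqrt(2*pi).
#' @slot octaves data.frame of octave midpoints and species frequencies used
#'   in the fit.
#' @export
setClass("PrestonFit", contains = "RichnessEstimate",
    representation(modeHeight = "numeric", modeLocation = "numeric",
        width = "numeric", veiledRichness = "numeric", octaves = "data.frame"))

setValidity("PrestonFit", function(object) {
    if (length(object@width) == 1L && !is.na(object@width) &&
        object@width <= 0)
        "width must be positive" else TRUE
})

#' Synthetic multi-site community with known true richness
#'
#' Ground-truth object produced by [simulateCommunity()]: the generating
#' specification, the true site-occupancy pattern of the full species pool,
#' and the sampled abundance matrix.
#'
#' @slot spec the [communitySpec()] list used for generation.
#' @slot trueOccupancy logical matrix, sites x pool species.
#' @slot sampled the sampled [AbundanceMatrix-class] (empty rows/columns
#'   dropped).
#' @slot trueRichness the pool size (true regional richness).
#' @export
setClass("SyntheticCommunity",
    representation(spec = "list", trueOccupancy = "matrix",
        sampled = "AbundanceMatrix", trueRichness = "numeric"))

setValidity("SyntheticCommunity", function(object) {
    msg <- character()
    sm <- object@sampled@counts
    if (length(sm)) {
        occ <- object@trueOccupancy
        bad <- vapply(seq_len(nrow(sm)), function(i) {
            j <- sm[i, ] > 0
            any(!occ[rownames(sm)[i], colnames(sm)[j]])
        }, logical(1))
        if (any(bad))
            msg <- c(msg, "specimens sampled at sites the species does not occupy")
    }
    if (length(msg)) msg else TRUE
})

#' Species accumulation curve
#'
#' Mean number of distinct species in the first k sites, averaged over random
#' permutations of the site accumulation order.
#'
#' @slot curve data.frame with columns nSites, mean, lower, upper.
#' @slot nPermutations number of random site orders averaged.
#' @slot seed RNG seed used.
#' @export
setClass("AccumulationCurve",
    representation(curve = "data.frame", nPermutations = "numeric",
        seed = "numeric"))

setValidity("AccumulationCurve", function(object) {
    msg <- character()
    m <- object@curve$mean
    if (length(m) > 1 && any(diff(m) < -1e-9))
        msg <- c(msg, "mean richness must be non-decreasing")
    if (length(msg)) msg else TRUE
})

#' Monte-Carlo / exhaustive permutation test result
#'
#' @slot observed observed value of the test statistic.
#' @slot nullStats statistics under permuted site-group assignments.
#' @slot pValue permutation p-value (add-one convention in Monte-Carlo mode).
#' @slot nPermutations number of permutations used.
#' @slot seed RNG seed (NA for exhaustive enumeration).
#' @slot statistic statistic name ("extreme_diff" or "trend").
#' @slot alternative sidedness used.
#' @export
setClass("PermutationTestResult",
    representation(observed = "numeric", nullStats = "numeric",
        pValue = "numeric", nPermutations = "numeric", seed = "numeric",
        statistic = "character", alternative = "character"))

setValidity("PermutationTestResult", function(object) {
    p <- object@pValue
    if (length(p) != 1L || is.na(p) || p <= 0 || p > 1)
        "pValue must lie in (0, 1]" else TRUE
})
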