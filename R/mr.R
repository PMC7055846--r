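#' Chapman mark-recapture estimator of total species richness
#'
#' Treats the species known before the inventory as "marked" individuals: the
#' proportion of previously known species in the new sample extrapolates the
#' prior checklist to the total fauna.  The Chapman small-sample form is
#'
#' \deqn{\hat S_{MR} = \frac{S_{obs} + 1}{S_{obs,known} + 1}
#'   (S_{known} + 1) - 1}
#'
#' which, unlike the plain Lincoln-Petersen index, is defined even when no
#' species were known prior to sampling.
#'
#' @param sObs number of species observed in the sample.
#' @param sObsKnown number of observed species that were previously known
#'   (must be <= sObs and <= sKnown).
#' @param sKnown number of species known prior to sampling.
#' @return a [RichnessEstimate-class] with estimator tag "chapman_mr".  The
#'   reported value is the nearest integer (ties half-up); the unrounded
#'   point is kept in \code{richness()}.
#' @examples
#' ## 314 species known beforehand, 204 observed of which 31 were new:
#' roundedRichness(chapmanMR(204, 173, 314))   # 370
#' @seealso [mrFromTableRow()] for the (known, observed, new) tally
#'   parameterisation, [chapmanMRFromSets()] for raw species lists.
#' @export
chapmanMR <- function(sObs, sObsKnown, sKnown) {
    sObs <- .assertCount(sObs, "sObs")
    sObsKnown <- .assertCount(sObsKnown, "sObsKnown")
    sKnown <- .assertCount(sKnown, "sKnown")
    if (sObsKnown > sObs)
        stop("sObsKnown must not exceed sObs", call. = FALSE)
    if (sObsKnown > sKnown)
        stop("sObsKnown must not exceed sKnown", call. = FALSE)
    point <- (sObs + 1) / (sObsKnown + 1) * (sKnown + 1) - 1
    .newEstimate("chapman_mr", point, sObs,
        inputs = list(sObs = sObs, sObsKnown = sObsKnown, sKnown = sKnown))
}

#' Chapman estimator from summary-table tallies
#'
#' Parameterisation matching inventory summary tables that report, per group,
#' the prior checklist size, the number of species found, and how many of
#' those were new: \code{sObs = spp}, \code{sObsKnown = spp - new},
#' \code{sKnown = known}.
#'
#' @param known species known prior to the inventory.
#' @param spp species observed in the inventory sample.
#' @param new observed species not previously known (must be <= spp).
#' @return a [RichnessEstimate-class].
#' @examples
#' roundedRichness(mrFromTableRow(known = 182, spp = 863, new = 743))  # 1306
#' @export
mrFromTableRow <- function(known, spp, new) {
    spp <- .assertCount(spp, "spp")
    new <- .assertCount(new, "new")
    if (new > spp)
        stop("'new' must not exceed 'spp'", call. = FALSE)
    chapmanMR(sObs = spp, sObsKnown = spp - new, sKnown = known)
}

#' Chapman estimator from raw species sets
#'
#' Computes the overlap between an observed species list and a prior
#' checklist, then applies [chapmanMR()].  A checklist species absent from
#' the sample contributes only to S_known.
#'
#' @param observed character vector of observed taxon labels (duplicates
#'   collapsed), or an object with [speciesIds()].
#' @param knownPool a [KnownPool-class] or character vector of prior labels.
#' @return a [RichnessEstimate-class].
#' @export
chapmanMRFromSets <- function(observed, knownPool) {
    if (is(observed, "AbundanceMatrix") || is(observed, "IncidenceMatrix"))
        observed <- speciesIds(observed)
    observed <- unique(as.character(observed))
    known <- if (is(knownPool, "KnownPool")) knownPool@species else
        unique(as.character(knownPool))
    chapmanMR(sObs = length(observed),
        sObsKnown = sum(observed %in% known),
        sKnown = length(known))
}
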