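#' Per-site statistics feeding the combined non-parametric estimator
#'
#' For each site i, the within-site abundance statistics and the across-site
#' occupancy statistics:
#' \describe{
#'   \item{sObs}{species observed at site i}
#'   \item{f1, f2}{species observed exactly once / twice at site i
#'     (within-site singletons / doubletons)}
#'   \item{uniques}{observed species occurring at site i and nowhere else}
#'   \item{duplicates}{observed species occurring at site i and exactly one
#'     other site}
#' }
#' Summed over sites, uniques equals Q1 and duplicates equals 2 Q2.
#'
#' @param matrix an [AbundanceMatrix-class].
#' @return data.frame with one row per site and columns site, sObs, f1, f2,
#'   uniques, duplicates.
#' @export
siteStatistics <- function(matrix) {
    if (!is(matrix, "AbundanceMatrix"))
        stop("siteStatistics requires abundance data (within-site singleton/",
            "doubleton counts are undefined for incidence data)",
            call. = FALSE)
    m <- counts(matrix)
    if (nrow(m) < 1) stop("matrix has no sites", call. = FALSE)
    pres <- m > 0
    occ <- colSums(pres)
    data.frame(
        site = rownames(m),
        sObs = rowSums(pres),
        f1 = rowSums(m == 1),
        f2 = rowSums(m == 2),
        uniques = as.numeric(pres %*% (occ == 1)),
        duplicates = as.numeric(pres %*% (occ == 2)),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Chao1-type within-site extrapolation
#'
#' Extrapolates the observed per-site statistics to what more extensive
#' sampling of the same site would have shown.  With
#' \eqn{e_i = F_1^{(i)}(F_1^{(i)} - 1) / d(F_2^{(i)})} the Chao1 correction
#' term at site i:
#' \deqn{\hat S^{(i)} = S_{obs}^{(i)} + e_i}
#' \deqn{\hat S_1^{(i)} = U_i + e_i\, U_i / S_{obs}^{(i)}, \qquad
#'       \hat S_2^{(i)} = D_i + e_i\, D_i / S_{obs}^{(i)}}
#' where U and D are the observed uniques and duplicates at the site — the
#' undiscovered species at a site are assumed to be uniques/duplicates in the
#' same proportion as the discovered ones.  The denominator d is
#' \eqn{2 (F_2 + 1)} under the default bias-corrected convention and
#' \eqn{2 F_2 + 1} under \code{denominator = "as_printed"}.
#'
#' @param stats one row of [siteStatistics()] output (or a list with fields
#'   sObs, f1, f2, uniques, duplicates).
#' @param denominator small-sample denominator convention.
#' @return list with elements sHat, s1Hat, s2Hat.
#' @export
siteExtrapolation <- function(stats,
    denominator = c("corrected", "as_printed")) {
    denominator <- match.arg(denominator)
    if (stats$sObs < 1)
        stop("site has no observed species", call. = FALSE)
    d <- if (denominator == "corrected") 2 * (stats$f2 + 1) else
        2 * stats$f2 + 1
    extra <- stats$f1 * (stats$f1 - 1) / d
    list(sHat = stats$sObs + extra,
        s1Hat = stats$uniques + extra * stats$uniques / stats$sObs,
        s2Hat = stats$duplicates + extra * stats$duplicates / stats$sObs)
}

#' Combined non-parametric estimator (CNE) of total species richness
#'
#' Chao2-type across-site extrapolation underestimates the species pool when
#' the individual sites are themselves undersampled: more trapping at the
#' same sites would reveal more of the highly localised unique and duplicate
#' species.  The CNE corrects for this by first applying a Chao1-type
#' within-site extrapolation to the counts of uniques and duplicates at each
#' site ([siteExtrapolation()]), then feeding the extrapolated totals
#' \deqn{\hat Q_1 = \sum_i \hat S_1^{(i)}, \qquad
#'       \hat Q_2 = \tfrac{1}{2} \sum_i \hat S_2^{(i)}}
#' into the Chao2-type step
#' \deqn{\hat S_{CNE} = S_{obs} + \hat Q_1 (\hat Q_1 - 1) / d(\hat Q_2).}
#' \eqn{\hat Q_1} and \eqn{\hat Q_2} are real-valued and never rounded before
#' the final step.  Sites with no specimens are excluded before the
#' computation.  Incidence-only input is refused: the within-site step needs
#' abundance counts (use [chao2()] or [jackknifeRichness()] instead).
#'
#' @param x an [AbundanceMatrix-class] with at least 2 non-empty sites.
#' @param variant alias accepted by [estimateRichness()]:
#'   "bias_corrected" maps to denominator "corrected", "classic" to
#'   "as_printed".
#' @param denominator small-sample denominator convention (overrides
#'   variant when given explicitly).
#' @param ... unused.
#' @return a [CNEEstimate-class] with the per-site breakdown.
#' @examples
#' m <- AbundanceMatrix(rbind(site1 = c(s1 = 1, s2 = 2, s3 = 3, s4 = 0, s5 = 0),
#'                            site2 = c(s1 = 0, s2 = 1, s3 = 0, s4 = 1, s5 = 2)))
#' cneEstimate(m)   # point estimate 8.467
#' @export
setMethod("cneEstimate", "AbundanceMatrix",
    function(x, variant = c("bias_corrected", "classic"),
             denominator = NULL, ...) {
    variant <- match.arg(variant)
    if (is.null(denominator))
        denominator <- if (variant == "bias_corrected") "corrected" else
            "as_printed"
    denominator <- match.arg(denominator, c("corrected", "as_printed"))
    m <- counts(x)
    keep <- rowSums(m) > 0
    if (!all(keep)) {
        warning("excluding ", sum(!keep), " site(s) with no specimens")
        m <- m[keep, , drop = FALSE]
    }
    if (nrow(m) < 2)
        stop("the combined non-parametric estimator requires at least 2 ",
            "sites with specimens", call. = FALSE)
    x <- AbundanceMatrix(m)
    st <- siteStatistics(x)
    ex <- lapply(seq_len(nrow(st)), function(i)
        siteExtrapolation(st[i, ], denominator = denominator))
    st$sHat <- vapply(ex, `[[`, numeric(1), "sHat")
    st$s1Hat <- vapply(ex, `[[`, numeric(1), "s1Hat")
    st$s2Hat <- vapply(ex, `[[`, numeric(1), "s2Hat")
    q1Hat <- sum(st$s1Hat)
    q2Hat <- sum(st$s2Hat) / 2
    sObs <- nSpecies(x)
    d <- if (denominator == "corrected") 2 * (q2Hat + 1) else 2 * q2Hat + 1
    point <- sObs + q1Hat * (q1Hat - 1) / d
    .newEstimate("cne", point, sObs,
        inputs = list(nSites = nrow(st), denominator = denominator),
        class = "CNEEstimate", perSite = st, q1Hat = q1Hat, q2Hat = q2Hat)
})

#' @rdname cneEstimate
#' @export
setMethod("cneEstimate", "IncidenceMatrix", function(x, ...)
    stop("the combined non-parametric estimator needs within-site abundance ",
        "counts; for incidence data use chao2() or jackknifeRichness()",
        call. = FALSE))
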