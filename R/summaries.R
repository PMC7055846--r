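#' Abundance frequency-count summary
#'
#' The sufficient statistics of the pooled sample for abundance-based
#' estimators: observed richness, the frequency counts F_k (number of species
#' with exactly k specimens in total; F1 = singletons, F2 = doubletons), and
#' the total specimen count.
#'
#' @param x an [AbundanceMatrix-class], or a numeric vector of per-species
#'   total abundances.
#' @return list with elements \code{sObs}, \code{fCounts} (named numeric
#'   vector, names = abundance k), \code{n} (specimens), and
#'   \code{abundances}.
#' @export
abundanceSummary <- function(x) {
    ab <- if (is(x, "AbundanceMatrix")) colSums(counts(x)) else {
        if (is(x, "IncidenceMatrix"))
            stop("abundance summary requires abundance data; ",
                "this input is incidence-only", call. = FALSE)
        as.numeric(x)
    }
    ab <- ab[ab > 0]
    tab <- table(ab)
    f <- as.numeric(tab)
    names(f) <- names(tab)
    list(sObs = length(ab), fCounts = f, n = sum(ab), abundances = ab)
}

#' Incidence (site-occupancy) summary
#'
#' The sufficient statistics for incidence-based estimators: observed
#' richness, number of sites, the occupancy frequency counts Q_m (number of
#' species occurring at exactly m sites; Q1 = uniques, Q2 = duplicates), and
#' the per-species occupancy.
#'
#' @param x an [AbundanceMatrix-class] or [IncidenceMatrix-class].
#' @return list with elements \code{sObs}, \code{nSites}, \code{qCounts}
#'   (named numeric vector, names = occupancy m), and \code{occupancy}.
#' @export
incidenceSummary <- function(x) {
    p <- presence(x)
    occ <- colSums(p)
    occ <- occ[occ > 0]
    tab <- table(occ)
    q <- as.numeric(tab)
    names(q) <- names(tab)
    list(sObs = length(occ), nSites = nrow(p), qCounts = q, occupancy = occ)
}

.fk <- function(summary, k) {
    v <- summary$fCounts[as.character(k)]
    if (is.na(v)) 0 else as.numeric(v)
}

.qm <- function(summary, m) {
    v <- summary$qCounts[as.character(m)]
    if (is.na(v)) 0 else as.numeric(v)
}

# Chao extrapolation term numerator/denominator convention.
# bias_corrected: F1(F1-1) / (2 (F2+1))  (small-sample form, always finite)
# classic:        F1^2    / (2 F2)       (undefined at F2 = 0 -> fall back to
#                                          the bias-corrected form, as the
#                                          reference implementations do)
.chaoTerm <- function(f1, f2, variant = c("bias_corrected", "classic")) {
    variant <- match.arg(variant)
    if (variant == "classic" && f2 > 0) f1^2 / (2 * f2)
    else f1 * (f1 - 1) / (2 * (f2 + 1))
}
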