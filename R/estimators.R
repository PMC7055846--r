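#' Chao1 abundance-based richness estimator
#'
#' Extrapolates observed richness from the singleton and doubleton counts of
#' the pooled sample.  The default bias-corrected form is
#' \deqn{\hat S = S_{obs} + \frac{F_1 (F_1 - 1)}{2 (F_2 + 1)}}
#' which is finite for any sample; \code{variant = "classic"} uses
#' \eqn{F_1^2 / (2 F_2)} (falling back to the corrected form when
#' \eqn{F_2 = 0}).  Site structure is ignored by design: pooling all sites
#' into one leaves the estimate unchanged.
#'
#' @param x an [AbundanceMatrix-class], a per-species abundance vector, or an
#'   [abundanceSummary()] list.
#' @param variant Chao denominator convention.
#' @param ... passed through to the summary method.
#' @return a [RichnessEstimate-class].
#' @examples
#' richness(chao1(c(1, 1, 2, 3)))   # 4 + 2*1/4 = 4.5
#' @export
setMethod("chao1", "AbundanceMatrix", function(x, ...)
    chao1(abundanceSummary(x), ...))

#' @rdname chao1
#' @export
setMethod("chao1", "IncidenceMatrix", function(x, ...)
    stop("chao1 requires abundance data; use chao2() or jackknifeRichness() ",
        "for incidence data", call. = FALSE))

#' @rdname chao1
#' @export
setMethod("chao1", "numeric", function(x, ...)
    chao1(abundanceSummary(x), ...))

#' @rdname chao1
#' @export
setMethod("chao1", "list",
    function(x, variant = c("bias_corrected", "classic"), ...) {
    variant <- match.arg(variant)
    if (x$sObs < 1) stop("empty abundance summary", call. = FALSE)
    point <- x$sObs + .chaoTerm(.fk(x, 1), .fk(x, 2), variant)
    .newEstimate("chao1", point, x$sObs,
        inputs = list(F1 = .fk(x, 1), F2 = .fk(x, 2), n = x$n,
            variant = variant))
})

#' ACE abundance-based coverage estimator
#'
#' Splits species into rare (total abundance <= \code{rareCutoff}) and
#' abundant groups, estimates sample coverage of the rare group as
#' \eqn{C = 1 - F_1 / N_{rare}}, and corrects for heterogeneity through the
#' squared coefficient of variation
#' \eqn{\gamma^2 = \max(\frac{S_{rare}}{C}
#'   \frac{\sum_k k (k-1) F_k}{N_{rare} (N_{rare} - 1)} - 1,\; 0)}:
#' \deqn{\hat S = S_{abund} + S_{rare} / C + (F_1 / C)\, \gamma^2.}
#' When every rare species is a singleton the coverage is zero and the
#' estimator falls back to [chao1()] with a warning.
#'
#' @inheritParams chao1
#' @param rareCutoff abundance threshold separating rare from abundant
#'   species (default 10, the standard convention).
#' @return a [RichnessEstimate-class].
#' @export
setMethod("ace", "AbundanceMatrix", function(x, ...)
    ace(abundanceSummary(x), ...))

#' @rdname ace
#' @export
setMethod("ace", "IncidenceMatrix", function(x, ...)
    stop("ace requires abundance data", call. = FALSE))

#' @rdname ace
#' @export
setMethod("ace", "numeric", function(x, ...) ace(abundanceSummary(x), ...))

#' @rdname ace
#' @export
setMethod("ace", "list", function(x, rareCutoff = 10, ...) {
    if (x$sObs < 1) stop("empty abundance summary", call. = FALSE)
    ab <- x$abundances
    rare <- ab[ab <= rareCutoff]
    sAbund <- sum(ab > rareCutoff)
    sRare <- length(rare)
    nRare <- sum(rare)
    f1 <- sum(rare == 1)
    if (sRare == 0) {
        point <- sAbund
        return(.newEstimate("ace", point, x$sObs,
            inputs = list(rareCutoff = rareCutoff, coverage = 1)))
    }
    C <- 1 - f1 / nRare
    if (C == 0) {
        warning("ACE coverage is zero (all rare species are singletons); ",
            "falling back to Chao1")
        est <- chao1(x)
        return(.newEstimate("ace", richness(est), x$sObs,
            inputs = list(rareCutoff = rareCutoff, fallback = "chao1")))
    }
    k <- as.numeric(names(x$fCounts))
    fk <- as.numeric(x$fCounts)
    sel <- k <= rareCutoff
    sumK <- sum(k[sel] * (k[sel] - 1) * fk[sel])
    gamma2 <- max(sRare / C * sumK / (nRare * (nRare - 1)) - 1, 0)
    point <- sAbund + sRare / C + f1 / C * gamma2
    .newEstimate("ace", point, x$sObs,
        inputs = list(rareCutoff = rareCutoff, coverage = C,
            gamma2 = gamma2))
})

#' Chao2 incidence-based richness estimator
#'
#' Extrapolates observed richness from the counts of unique (one-site) and
#' duplicate (two-site) species across sampling sites.  The default
#' bias-corrected, small-sample form is
#' \deqn{\hat S = S_{obs} + \frac{n - 1}{n}
#'   \frac{Q_1 (Q_1 - 1)}{2 (Q_2 + 1)}}
#' with n the number of sites; \code{variant = "classic"} uses
#' \eqn{Q_1^2 / (2 Q_2)} without the small-sample factor.
#'
#' @param x an [AbundanceMatrix-class], [IncidenceMatrix-class], or an
#'   [incidenceSummary()] list.
#' @param variant Chao denominator convention.
#' @param ... passed through to the summary method.
#' @return a [RichnessEstimate-class].
#' @export
setMethod("chao2", "AbundanceMatrix", function(x, ...)
    chao2(incidenceSummary(x), ...))

#' @rdname chao2
#' @export
setMethod("chao2", "IncidenceMatrix", function(x, ...)
    chao2(incidenceSummary(x), ...))

#' @rdname chao2
#' @export
setMethod("chao2", "list",
    function(x, variant = c("bias_corrected", "classic"), ...) {
    variant <- match.arg(variant)
    n <- x$nSites
    if (n < 2)
        stop("chao2 requires at least 2 sites", call. = FALSE)
    q1 <- .qm(x, 1); q2 <- .qm(x, 2)
    point <- if (variant == "classic" && q2 > 0)
        x$sObs + q1^2 / (2 * q2)
    else x$sObs + (n - 1) / n * q1 * (q1 - 1) / (2 * (q2 + 1))
    .newEstimate("chao2", point, x$sObs,
        inputs = list(Q1 = q1, Q2 = q2, nSites = n, variant = variant))
})

#' First- and second-order jackknife richness estimators
#'
#' Incidence-based jackknife extrapolations:
#' order 1: \eqn{S_{obs} + Q_1 (n-1)/n};
#' order 2: \eqn{S_{obs} + Q_1 (2n-3)/n - Q_2 (n-2)^2 / (n (n-1))}.
#'
#' @inheritParams chao2
#' @param order jackknife order, 1 or 2.
#' @return a [RichnessEstimate-class] tagged "jack1" or "jack2".
#' @export
setMethod("jackknifeRichness", "AbundanceMatrix", function(x, ...)
    jackknifeRichness(incidenceSummary(x), ...))

#' @rdname jackknifeRichness
#' @export
setMethod("jackknifeRichness", "IncidenceMatrix", function(x, ...)
    jackknifeRichness(incidenceSummary(x), ...))

#' @rdname jackknifeRichness
#' @export
setMethod("jackknifeRichness", "list", function(x, order = 1, ...) {
    if (!order %in% c(1, 2)) stop("order must be 1 or 2", call. = FALSE)
    n <- x$nSites
    if (n < order + 1)
        stop(sprintf("jackknife order %d requires at least %d sites",
            order, order + 1), call. = FALSE)
    q1 <- .qm(x, 1); q2 <- .qm(x, 2)
    point <- if (order == 1) x$sObs + q1 * (n - 1) / n
        else x$sObs + q1 * (2 * n - 3) / n - q2 * (n - 2)^2 / (n * (n - 1))
    .newEstimate(paste0("jack", order), point, x$sObs,
        inputs = list(Q1 = q1, Q2 = q2, nSites = n, order = order))
})

#' Bootstrap incidence-based richness estimator
#'
#' \deqn{\hat S = S_{obs} + \sum_k (1 - p_k)^n}
#' where \eqn{p_k} is the occupancy fraction of species k and n the number of
#' sites.
#'
#' @inheritParams chao2
#' @return a [RichnessEstimate-class] tagged "boot".
#' @export
setMethod("bootstrapRichness", "AbundanceMatrix", function(x, ...)
    bootstrapRichness(incidenceSummary(x), ...))

#' @rdname bootstrapRichness
#' @export
setMethod("bootstrapRichness", "IncidenceMatrix", function(x, ...)
    bootstrapRichness(incidenceSummary(x), ...))

#' @rdname bootstrapRichness
#' @export
setMethod("bootstrapRichness", "list", function(x, ...) {
    if (x$sObs < 1) stop("empty incidence summary", call. = FALSE)
    p <- x$occupancy / x$nSites
    point <- x$sObs + sum((1 - p)^x$nSites)
    .newEstimate("boot", point, x$sObs,
        inputs = list(nSites = x$nSites))
})

#' Bin abundances into Preston log2 octaves
#'
#' Half-open log2 octave convention: abundance a falls in octave
#' \eqn{\lceil \log_2 a \rceil}; a species whose abundance lies exactly on an
#' octave boundary (a power of 2) is split 50/50 between the two adjacent
#' octaves.
#'
#' @param ab numeric vector of per-species total abundances (>= 1).
#' @return data.frame with columns octave (0, 1, 2, ...) and freq (species
#'   per octave, halves possible from boundary splitting).
#' @export
prestonOctaves <- function(ab) {
    maxOct <- ceiling(log2(max(ab)))
    freq <- numeric(maxOct + 1)   # octaves 0..maxOct
    oct <- log2(ab)
    onBoundary <- oct == round(oct)
    for (a in oct[!onBoundary]) {
        j <- ceiling(a)           # (2^(j-1), 2^j) -> octave j
        freq[j + 1] <- freq[j + 1] + 1
    }
    for (a in oct[onBoundary]) {
        j <- round(a)
        freq[j + 1] <- freq[j + 1] + 0.5
        if (j + 2 <= length(freq)) freq[j + 2] <- freq[j + 2] + 0.5
        else freq <- c(freq, 0.5)
    }
    data.frame(octave = seq_along(freq) - 1, freq = freq)
}

#' Preston lognormal richness estimator
#'
#' Bins the pooled per-species abundances into log2 octaves (boundary counts
#' split 50/50 between adjacent octaves), fits a Gaussian
#' \eqn{h \exp(-(o - \mu)^2 / (2 w^2))} to the octave frequencies by least
#' squares, and estimates total richness as the area under the fitted curve,
#' \eqn{h\, w \sqrt{2 \pi}} — the observed species plus those still hidden
#' behind the sampling veil.  The point estimate is clamped below at the
#' observed richness.
#'
#' @inheritParams chao1
#' @return a [PrestonFit-class].
#' @export
setMethod("prestonRichness", "AbundanceMatrix", function(x, ...)
    prestonRichness(abundanceSummary(x), ...))

#' @rdname prestonRichness
#' @export
setMethod("prestonRichness", "IncidenceMatrix", function(x, ...)
    stop("the Preston estimator requires abundance data", call. = FALSE))

#' @rdname prestonRichness
#' @export
setMethod("prestonRichness", "numeric", function(x, ...)
    prestonRichness(abundanceSummary(x), ...))

#' @rdname prestonRichness
#' @export
setMethod("prestonRichness", "list", function(x, ...) {
    oct <- prestonOctaves(x$abundances)
    par <- fitOctaveGaussian(oct$octave, oct$freq)
    veiled <- par$height * par$width * sqrt(2 * pi)
    point <- max(veiled, x$sObs)
    .newEstimate("preston", point, x$sObs,
        inputs = list(nOctaves = nrow(oct)), class = "PrestonFit",
        modeHeight = par$height, modeLocation = par$mode, width = par$width,
        veiledRichness = veiled, octaves = oct)
})

#' Least-squares Gaussian fit to octave frequencies
#'
#' Fits \eqn{y = h \exp(-(o - \mu)^2 / (2 w^2))} by nonlinear least squares,
#' initialised from a log-quadratic regression on the positive frequencies
#' (falling back to moment estimates when the quadratic is not concave).
#'
#' @param octave numeric octave positions.
#' @param freq species frequencies per octave.
#' @return list with elements height, mode, width.
#' @export
fitOctaveGaussian <- function(octave, freq) {
    occupied <- sum(freq > 0)
    if (occupied < 3)
        stop("Gaussian octave fit needs at least 3 occupied octaves (got ",
            occupied, ")", call. = FALSE)
    o <- octave; y <- freq
    pos <- y > 0
    op <- o[pos]
    cf <- stats::coef(stats::lm(log(y[pos]) ~ op + I(op^2)))
    init <- if (!is.na(cf[3]) && cf[3] < 0) {
        w0 <- sqrt(-1 / (2 * cf[3]))
        m0 <- cf[2] * w0^2
        list(h = exp(cf[1] + m0^2 / (2 * w0^2)), mu = m0, w = w0)
    } else {
        mu0 <- sum(o * y) / sum(y)
        w0 <- sqrt(sum(y * (o - mu0)^2) / sum(y))
        list(h = max(y), mu = mu0, w = max(w0, 0.5))
    }
    fit <- try(suppressWarnings(
        stats::nls(y ~ h * exp(-(o - mu)^2 / (2 * w^2)), start = init,
            control = stats::nls.control(maxiter = 500, warnOnly = TRUE))),
        silent = TRUE)
    if (inherits(fit, "try-error"))
        stop("Preston Gaussian fit failed to converge", call. = FALSE)
    par <- stats::coef(fit)
    list(height = unname(par["h"]), mode = unname(par["mu"]),
        width = abs(unname(par["w"])))
}

#' Run a suite of richness estimators on a matrix
#'
#' Convenience wrapper routing each requested estimator to the input it
#' applies to.  Abundance-only estimators (chao1, ace, preston, cne)
#' requested on incidence data are reported as NA with a message rather than
#' an error, so benchmark sweeps over mixed data types degrade gracefully.
#'
#' @param x an [AbundanceMatrix-class] or [IncidenceMatrix-class].
#' @param methods character vector among "chao1", "ace", "chao2", "jack1",
#'   "jack2", "boot", "preston", "cne".
#' @param variant Chao denominator convention passed to chao1/chao2/cne.
#' @param extra named list of additional estimator functions (each taking the
#'   matrix and returning a [RichnessEstimate-class]); a plug-in hook for,
#'   e.g., externally defined sampling-intensity-corrected estimators.
#' @return data.frame with columns estimator, point, pointRounded, sObs.
#' @export
estimateRichness <- function(x,
    methods = c("chao1", "ace", "chao2", "jack1", "jack2", "boot",
        "preston", "cne"),
    variant = c("bias_corrected", "classic"), extra = list()) {
    variant <- match.arg(variant)
    isAb <- is(x, "AbundanceMatrix")
    one <- function(m) {
        est <- switch(m,
            chao1 = if (isAb) chao1(x, variant = variant),
            ace = if (isAb) ace(x),
            preston = if (isAb) prestonRichness(x),
            cne = if (isAb) cneEstimate(x, variant = variant),
            chao2 = chao2(x, variant = variant),
            jack1 = jackknifeRichness(x, order = 1),
            jack2 = jackknifeRichness(x, order = 2),
            boot = bootstrapRichness(x),
            stop("unknown estimator: ", m, call. = FALSE))
        if (is.null(est)) {
            message("estimator '", m, "' requires abundance data; reported as NA")
            return(data.frame(estimator = m, point = NA_real_,
                pointRounded = NA_real_, sObs = NA_real_))
        }
        data.frame(estimator = m, point = richness(est),
            pointRounded = roundedRichness(est), sObs = est@sObs)
    }
    rows <- lapply(methods, function(m) {
        tryCatch(one(m), error = function(e) {
            message("estimator '", m, "' failed: ", conditionMessage(e))
            data.frame(estimator = m, point = NA_real_,
                pointRounded = NA_real_, sObs = NA_real_)
        })
    })
    if (length(extra)) {
        rows <- c(rows, lapply(names(extra), function(nm) {
            est <- extra[[nm]](x)
            data.frame(estimator = nm, point = richness(est),
                pointRounded = roundedRichness(est), sObs = est@sObs)
        }))
    }
    do.call(rbind, rows)
}
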