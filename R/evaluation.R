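#' Log-scale accuracy of a richness estimate
#'
#' The two accuracy metrics used throughout the benchmarking framework:
#' squared error of the log estimate, \eqn{(\ln \hat S - \ln S)^2}, and log
#' bias, \eqn{\ln \hat S - \ln S}.  Natural logarithms are used, so a squared
#' error of e corresponds to a multiplicative error factor
#' \eqn{\exp(\sqrt{e})} (e.g. 0.4 corresponds to a factor of about 1.9 — the
#' estimate may be off by close to half or double the true value).
#'
#' @param sHat point estimate (> 0).
#' @param sTrue true richness (> 0).
#' @return list with elements sqLogError and logBias.
#' @export
evaluateEstimate <- function(sHat, sTrue) {
    if (any(sHat <= 0) || any(sTrue <= 0))
        stop("log-scale evaluation requires positive estimates and truths",
            call. = FALSE)
    b <- log(sHat) - log(sTrue)
    list(sqLogError = b^2, logBias = b)
}

#' @rdname effortMeasures
#' @export
setMethod("effortMeasures", "AbundanceMatrix", function(x) {
    ab <- abundanceSummary(x)
    inc <- incidenceSummary(x)
    list(singletonProportion = .fk(ab, 1) / ab$sObs,
        specimensPerSpecies = ab$n / ab$sObs,
        uniqueProportion = .qm(inc, 1) / inc$sObs,
        occurrencesPerSpecies = sum(inc$occupancy) / inc$sObs)
})

#' Sampling-effort diagnostics for a matrix
#'
#' The four sampling-intensity measures that correlate with estimator
#' accuracy: the proportion of singletons (F1/S_obs) and specimens per
#' species (abundance-based), and the proportion of uniques (Q1/S_obs) and
#' site occurrences per species (incidence-based).  Incidence input yields
#' only the latter two (the former are NA).
#'
#' @param x an [AbundanceMatrix-class] or [IncidenceMatrix-class].
#' @return named list of the four measures.
#' @rdname effortMeasures
#' @export
setMethod("effortMeasures", "IncidenceMatrix", function(x) {
    inc <- incidenceSummary(x)
    list(singletonProportion = NA_real_,
        specimensPerSpecies = NA_real_,
        uniqueProportion = .qm(inc, 1) / inc$sObs,
        occurrencesPerSpecies = sum(inc$occupancy) / inc$sObs)
})

#' Benchmark richness estimators over many datasets
#'
#' Runs a suite of estimators across datasets with known (or assumed) true
#' richness and reports the log-scale accuracy metrics together with
#' species-pool coverage and sampling-effort diagnostics — the table behind
#' accuracy-vs-coverage and bias-vs-coverage analyses.  True richness is
#' data supplied by the caller (e.g. an expert total or a prior checklist
#' size), never computed.  Datasets failing the inclusion thresholds
#' (strictly more than \code{minSpecimens} specimens from strictly more than
#' \code{minSites} sites, by default > 100 and > 5) are excluded and
#' reported with \code{included = FALSE}.  An estimator inapplicable to a
#' dataset's data type yields an NA row, not a failure.
#'
#' @param datasets list of lists, each with elements \code{matrix} (an
#'   [AbundanceMatrix-class] or [IncidenceMatrix-class]), \code{sTrue}, and
#'   optionally \code{label}.
#' @param estimators estimator names accepted by [estimateRichness()].
#' @param inclusion named numeric vector with \code{minSpecimens} and
#'   \code{minSites} thresholds (strict inequalities).
#' @param variant Chao denominator convention.
#' @return data.frame with one row per (dataset, estimator): label,
#'   estimator, sHat, sTrue, sqLogError, logBias, coverage, the four effort
#'   measures, nSites, nSpecimens, included.
#' @export
benchmarkEstimators <- function(datasets,
    estimators = c("chao1", "chao2", "cne"),
    inclusion = c(minSpecimens = 100, minSites = 5),
    variant = "bias_corrected") {
    rows <- lapply(seq_along(datasets), function(di) {
        d <- datasets[[di]]
        label <- if (!is.null(d$label)) d$label else paste0("dataset", di)
        x <- d$matrix
        isAb <- is(x, "AbundanceMatrix")
        nSpecimens <- if (isAb) sum(counts(x)) else NA_real_
        ns <- nSites(x)
        included <- ns > inclusion[["minSites"]] &&
            (!isAb || nSpecimens > inclusion[["minSpecimens"]])
        if (!included) {
            message("dataset '", label, "' excluded by inclusion thresholds")
            return(data.frame(label = label, estimator = estimators,
                sHat = NA_real_, sTrue = d$sTrue, sqLogError = NA_real_,
                logBias = NA_real_, coverage = NA_real_,
                singletonProportion = NA_real_,
                specimensPerSpecies = NA_real_, uniqueProportion = NA_real_,
                occurrencesPerSpecies = NA_real_, nSites = ns,
                nSpecimens = nSpecimens, included = FALSE))
        }
        est <- estimateRichness(x, methods = estimators, variant = variant)
        eff <- effortMeasures(x)
        sObs <- nSpecies(x)
        acc <- lapply(est$point, function(p)
            if (is.na(p) || p <= 0) list(sqLogError = NA_real_,
                logBias = NA_real_) else evaluateEstimate(p, d$sTrue))
        data.frame(label = label, estimator = est$estimator,
            sHat = est$point, sTrue = d$sTrue,
            sqLogError = vapply(acc, `[[`, numeric(1), "sqLogError"),
            logBias = vapply(acc, `[[`, numeric(1), "logBias"),
            coverage = sObs / d$sTrue,
            singletonProportion = eff$singletonProportion,
            specimensPerSpecies = eff$specimensPerSpecies,
            uniqueProportion = eff$uniqueProportion,
            occurrencesPerSpecies = eff$occurrencesPerSpecies,
            nSites = ns, nSpecimens = nSpecimens, included = TRUE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Species accumulation curve over random site orders
#'
#' For each prefix length k, the mean number of distinct species contained in
#' the first k sites, averaged over random permutations of the site
#' accumulation order; the band holds the 2.5\% and 97.5\% permutation
#' quantiles.  Deterministic given the seed.  The curve is non-decreasing and
#' ends exactly at the observed richness.
#'
#' @param x an [AbundanceMatrix-class] or [IncidenceMatrix-class].
#' @param nPermutations number of random site orders (default 10000).
#' @param seed RNG seed.
#' @return an [AccumulationCurve-class].
#' @export
accumulationCurve <- function(x, nPermutations = 10000, seed) {
    p <- presence(x)
    n <- nrow(p)
    if (n < 1) stop("at least one site required", call. = FALSE)
    S <- ncol(p)
    siteList <- lapply(seq_len(S), function(j) which(p[, j]))
    withSeed(seed, {
        rich <- matrix(0L, nPermutations, n)
        for (r in seq_len(nPermutations)) {
            ord <- sample.int(n)
            pos <- integer(n)
            pos[ord] <- seq_len(n)    # pos[i] = rank of site i in this order
            first <- vapply(siteList, function(ix) min(pos[ix]), numeric(1))
            rich[r, ] <- cumsum(tabulate(first, nbins = n))
        }
        curve <- data.frame(nSites = seq_len(n),
            mean = colMeans(rich),
            lower = apply(rich, 2, stats::quantile, 0.025),
            upper = apply(rich, 2, stats::quantile, 0.975))
        new("AccumulationCurve", curve = curve,
            nPermutations = nPermutations, seed = as.numeric(seed))
    })
}
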