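#' Construct an AbundanceMatrix
#'
#' @param counts numeric matrix of non-negative integer counts with site row
#'   names and species column names; a data.frame is coerced.
#' @param dropEmpty drop all-zero rows and columns before validation
#'   (default TRUE).  All-zero species are non-observations and all-zero
#'   sites carry no information for the estimators.
#' @return an [AbundanceMatrix-class].
#' @examples
#' m <- AbundanceMatrix(rbind(T1 = c(a = 1, b = 2, c = 3),
#'                            T2 = c(a = 0, b = 1, c = 2)))
#' nSites(m); nSpecies(m)
#' @export
AbundanceMatrix <- function(counts, dropEmpty = TRUE) {
    if (is.data.frame(counts)) counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    if (dropEmpty && length(counts)) {
        counts <- counts[rowSums(counts) > 0, colSums(counts) > 0,
            drop = FALSE]
    }
    new("AbundanceMatrix", counts = counts)
}

#' Construct an IncidenceMatrix
#'
#' @param presence logical (or 0/1 numeric) matrix with site row names and
#'   species column names.
#' @param dropEmpty drop all-zero rows and columns before validation.
#' @return an [IncidenceMatrix-class].
#' @export
IncidenceMatrix <- function(presence, dropEmpty = TRUE) {
    if (is.data.frame(presence)) presence <- as.matrix(presence)
    if (!is.logical(presence)) {
        dn <- dimnames(presence)
        presence <- matrix(presence > 0, nrow = nrow(presence),
            dimnames = dn)
    }
    if (dropEmpty && length(presence))
        presence <- presence[rowSums(presence) > 0,
            colSums(presence) > 0, drop = FALSE]
    new("IncidenceMatrix", presence = presence)
}

#' Construct a KnownPool
#'
#' @param species character vector of taxon labels known prior to sampling.
#' @param groupName label for the taxon group.
#' @return a [KnownPool-class].
#' @export
KnownPool <- function(species, groupName = "group") {
    new("KnownPool", groupName = groupName,
        species = unique(as.character(species)))
}

#' @name accessors
#' @title Accessors for faunest objects
#' @param x a faunest object.
#' @return \code{siteIds}, \code{speciesIds}: character vectors;
#'   \code{nSites}, \code{nSpecies}: integers; \code{counts},
#'   \code{presence}: the underlying matrix; \code{richness},
#'   \code{roundedRichness}: the (rounded) point estimate of a
#'   [RichnessEstimate-class]; \code{poolSize}: checklist or true pool size.
NULL

#' @rdname accessors
#' @export
setMethod("siteIds", "AbundanceMatrix", function(x) rownames(x@counts))
#' @rdname accessors
#' @export
setMethod("siteIds", "IncidenceMatrix", function(x) rownames(x@presence))
#' @rdname accessors
#' @export
setMethod("speciesIds", "AbundanceMatrix", function(x) colnames(x@counts))
#' @rdname accessors
#' @export
setMethod("speciesIds", "IncidenceMatrix", function(x) colnames(x@presence))
#' @rdname accessors
#' @export
setMethod("nSites", "AbundanceMatrix", function(x) nrow(x@counts))
#' @rdname accessors
#' @export
setMethod("nSites", "IncidenceMatrix", function(x) nrow(x@presence))
#' @rdname accessors
#' @export
setMethod("nSpecies", "AbundanceMatrix", function(x) ncol(x@counts))
#' @rdname accessors
#' @export
setMethod("nSpecies", "IncidenceMatrix", function(x) ncol(x@presence))
#' @rdname accessors
#' @export
setMethod("counts", "AbundanceMatrix", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("presence", "IncidenceMatrix", function(x) x@presence)
#' @rdname accessors
#' @export
setMethod("presence", "AbundanceMatrix", function(x) x@counts > 0)

#' @rdname asIncidence
#' @export
setMethod("asIncidence", "AbundanceMatrix", function(x)
    IncidenceMatrix(x@counts > 0, dropEmpty = FALSE))
#' @rdname asIncidence
#' @export
setMethod("asIncidence", "IncidenceMatrix", function(x) x)

#' @rdname accessors
#' @export
setMethod("richness", "RichnessEstimate", function(x) x@point)
#' @rdname accessors
#' @export
setMethod("roundedRichness", "RichnessEstimate", function(x) x@pointRounded)
#' @rdname accessors
#' @export
setMethod("poolSize", "KnownPool", function(x) length(x@species))
#' @rdname accessors
#' @export
setMethod("poolSize", "SyntheticCommunity", function(x) x@trueRichness)

setMethod("show", "AbundanceMatrix", function(object) {
    cat(sprintf("AbundanceMatrix: %d sites x %d species, %d specimens\n",
        nSites(object), nSpecies(object), sum(object@counts)))
})

setMethod("show", "IncidenceMatrix", function(object) {
    cat(sprintf("IncidenceMatrix: %d sites x %d species, %d occurrences\n",
        nSites(object), nSpecies(object), sum(object@presence)))
})

setMethod("show", "KnownPool", function(object) {
    cat(sprintf("KnownPool '%s': %d species\n", object@groupName,
        poolSize(object)))
})

setMethod("show", "RichnessEstimate", function(object) {
    cat(sprintf("RichnessEstimate [%s]: %.4g (reported %d), S_obs = %d\n",
        object@estimator, object@point, as.integer(object@pointRounded),
        as.integer(object@sObs)))
})

setMethod("show", "CNEEstimate", function(object) {
    callNextMethod()
    cat(sprintf("  Q1-hat = %.4g, Q2-hat = %.4g over %d sites\n",
        object@q1Hat, object@q2Hat, nrow(object@perSite)))
})

setMethod("show", "PrestonFit", function(object) {
    callNextMethod()
    cat(sprintf("  mode %.3g at octave %.3g, width %.3g, veiled richness %.4g\n",
        object@modeHeight, object@modeLocation, object@width,
        object@veiledRichness))
})

setMethod("show", "SyntheticCommunity", function(object) {
    cat(sprintf("SyntheticCommunity: pool %d species, %d sites; sampled %d species / %d specimens\n",
        object@trueRichness, nrow(object@trueOccupancy),
        nSpecies(object@sampled), sum(counts(object@sampled))))
})

setMethod("show", "AccumulationCurve", function(object) {
    cat(sprintf("AccumulationCurve over %d sites (%g permutations), final richness %g\n",
        nrow(object@curve), object@nPermutations,
        object@curve$mean[nrow(object@curve)]))
})

setMethod("show", "PermutationTestResult", function(object) {
    cat(sprintf("PermutationTestResult [%s, %s]: observed = %.4g, p = %.4g (%g permutations)\n",
        object@statistic, object@alternative, object@observed,
        object@pValue, object@nPermutations))
})

#' Write a site-by-species matrix as delimited text
#'
#' Sites as rows, species as columns, first column \code{site}.
#'
#' @param x an [AbundanceMatrix-class] or [IncidenceMatrix-class].
#' @param path output file path.
#' @param sep field delimiter.
#' @return invisibly, the path.
#' @export
writeMatrix <- function(x, path, sep = "\t") {
    m <- if (is(x, "AbundanceMatrix")) counts(x) else presence(x) * 1L
    df <- data.frame(site = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a site-by-species matrix from delimited text
#'
#' Expects the layout written by [writeMatrix()]: one header row, first
#' column the site id, remaining columns species counts (or 0/1 incidence).
#'
#' @param path input file path.
#' @param sep field delimiter; NULL auto-detects tab vs comma from the
#'   header line.
#' @param incidence return an [IncidenceMatrix-class] instead.
#' @return an [AbundanceMatrix-class] or [IncidenceMatrix-class].
#' @export
readMatrix <- function(path, sep = NULL, incidence = FALSE) {
    if (is.null(sep)) sep <- .detectSep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
        check.names = FALSE, stringsAsFactors = FALSE, comment.char = "#")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    if (incidence) IncidenceMatrix(m) else AbundanceMatrix(m)
}
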