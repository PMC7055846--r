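#' Read inventory species records from delimited text
#'
#' Parses a records file (one row per determination event) into a
#' data.frame of species records.  Column roles are supplied through
#' \code{formatConfig} rather than fixed names, because inventory files vary
#' in layout.  Two taxonomic quality flags are derived during parsing:
#' \describe{
#'   \item{genusOnly}{the taxon label ends in an unqualified "sp.", i.e. the
#'     specimen was determined only to genus level.  Such records are removed
#'     by [filterRecords()] before richness estimation.}
#'   \item{indetDistinct}{the author field carries "sp. indet.": an
#'     unspecified species judged to be distinct; retained as its own
#'     species.}
#' }
#'
#' @param path delimited-text file (UTF-8, one header row; comma or tab,
#'   auto-detected unless \code{sep} is given).
#' @param formatConfig named list mapping roles to column names; required
#'   roles: \code{taxon}, \code{site}; optional: \code{count},
#'   \code{sample}, \code{author}, \code{known}.  A missing/NULL
#'   \code{count} role yields incidence-only records.
#' @param sep field delimiter override.
#' @return data.frame with columns taxon, site, sample, count (NA for
#'   incidence records), genusOnly, indetDistinct, knownPrior.
#' @export
readRecords <- function(path,
    formatConfig = list(taxon = "taxon", site = "site", count = "count"),
    sep = NULL) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    if (is.null(sep)) sep <- .detectSep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
        check.names = FALSE, stringsAsFactors = FALSE, comment.char = "")
    getcol <- function(role, required = FALSE) {
        nm <- formatConfig[[role]]
        if (is.null(nm)) {
            if (required)
                stop(sprintf("formatConfig must map required column '%s'",
                    role), call. = FALSE)
            return(NULL)
        }
        if (!nm %in% names(df))
            stop(sprintf("column '%s' (role '%s') not found in %s",
                nm, role, path), call. = FALSE)
        df[[nm]]
    }
    taxon <- trimws(as.character(getcol("taxon", required = TRUE)))
    site <- as.character(getcol("site", required = TRUE))
    cnt <- getcol("count")
    if (is.null(cnt)) {
        count <- rep(NA_real_, nrow(df))
    } else {
        count <- suppressWarnings(as.numeric(cnt))
        bad <- which(is.na(count) | count != round(count) | count < 0)
        if (length(bad))
            stop(sprintf("non-integer count in row %d ('%s')",
                bad[1], as.character(cnt[bad[1]])), call. = FALSE)
    }
    smp <- getcol("sample")
    author <- getcol("author")
    known <- getcol("known")
    indet <- if (is.null(author)) rep(FALSE, nrow(df)) else
        grepl("sp\\. indet\\.", author, fixed = FALSE)
    genusOnly <- grepl("(^|\\s)sp\\.$", taxon) & !indet
    rec <- data.frame(taxon = taxon, site = site,
        sample = if (is.null(smp)) NA_character_ else as.character(smp),
        count = count, genusOnly = genusOnly, indetDistinct = indet,
        knownPrior = if (is.null(known)) NA else as.logical(known),
        stringsAsFactors = FALSE)
    zero <- !is.na(rec$count) & rec$count == 0
    if (any(zero)) {
        warning(sprintf("dropping %d record(s) with count 0 (non-observations)",
            sum(zero)))
        rec <- rec[!zero, , drop = FALSE]
    }
    rec
}

#' Remove genus-level determinations before richness analysis
#'
#' Records determined only to genus level (\code{genusOnly}) are removed;
#' "sp. indet." records are kept under the assumption that they represent
#' distinct species.  The removal tally is attached as attribute
#' \code{"removed"} (list with nRecords, nTaxa, taxa).
#'
#' @param records data.frame from [readRecords()].
#' @return the filtered records, with attribute \code{"removed"}.
#' @export
filterRecords <- function(records) {
    drop <- records$genusOnly
    removed <- list(nRecords = sum(drop),
        nTaxa = length(unique(records$taxon[drop])),
        taxa = unique(records$taxon[drop]))
    out <- records[!drop, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "removed") <- removed
    out
}

#' Aggregate records into a site-by-species matrix
#'
#' Counts are summed per (site, species) over samples; samples from the same
#' site are pooled, so "site" is the estimation unit.  If any record lacks a
#' count the whole set is demoted to incidence (with a warning when counts
#' and incidence records are mixed), matching inventory groups for which
#' abundance was not reported consistently.
#'
#' @param records filtered records data.frame.
#' @return an [AbundanceMatrix-class], or an [IncidenceMatrix-class] when any
#'   record is incidence-only.
#' @export
buildMatrix <- function(records) {
    if (is.null(records) || nrow(records) == 0)
        stop("no records to build a matrix from", call. = FALSE)
    anyInc <- any(is.na(records$count))
    if (anyInc && any(!is.na(records$count)))
        warning("mixed abundance/incidence records; demoting group to incidence")
    site <- factor(records$site, levels = unique(records$site))
    taxon <- factor(records$taxon, levels = unique(records$taxon))
    if (anyInc) {
        m <- as.matrix(table(site, taxon)) > 0
        dimnames(m) <- list(levels(site), levels(taxon))
        IncidenceMatrix(m)
    } else {
        m <- matrix(0, nlevels(site), nlevels(taxon),
            dimnames = list(levels(site), levels(taxon)))
        agg <- tapply(records$count, list(site, taxon), sum)
        agg[is.na(agg)] <- 0
        m[rownames(agg), colnames(agg)] <- agg
        AbundanceMatrix(m)
    }
}

#' Read a prior species checklist
#'
#' One taxon label per line (blank lines and lines starting with '#'
#' ignored).
#'
#' @param path text file path.
#' @param groupName label for the group.
#' @return a [KnownPool-class].
#' @export
readKnownPool <- function(path, groupName = basename(path)) {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    KnownPool(lines, groupName = groupName)
}
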