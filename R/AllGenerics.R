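#' @rdname accessors
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))

#' @rdname accessors
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname accessors
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))

#' Convert abundance data to incidence
#'
#' Thresholds counts at >= 1; an [IncidenceMatrix-class] passes through
#' unchanged.
#'
#' @param x an [AbundanceMatrix-class] or [IncidenceMatrix-class].
#' @return an [IncidenceMatrix-class].
#' @export
setGeneric("asIncidence", function(x) standardGeneric("asIncidence"))

#' @rdname accessors
#' @export
setGeneric("richness", function(x) standardGeneric("richness"))

#' @rdname accessors
#' @export
setGeneric("roundedRichness", function(x) standardGeneric("roundedRichness"))

#' @rdname accessors
#' @export
setGeneric("poolSize", function(x) standardGeneric("poolSize"))

#' @rdname chao1
#' @export
setGeneric("chao1", function(x, ...) standardGeneric("chao1"))

#' @rdname ace
#' @export
setGeneric("ace", function(x, ...) standardGeneric("ace"))

#' @rdname chao2
#' @export
setGeneric("chao2", function(x, ...) standardGeneric("chao2"))

#' @rdname jackknifeRichness
#' @export
setGeneric("jackknifeRichness",
    function(x, ...) standardGeneric("jackknifeRichness"))

#' @rdname bootstrapRichness
#' @export
setGeneric("bootstrapRichness",
    function(x, ...) standardGeneric("bootstrapRichness"))

#' @rdname prestonRichness
#' @export
setGeneric("prestonRichness",
    function(x, ...) standardGeneric("prestonRichness"))

#' @rdname cneEstimate
#' @export
setGeneric("cneEstimate", function(x, ...) standardGeneric("cneEstimate"))

#' @rdname effortMeasures
#' @export
setGeneric("effortMeasures", function(x) standardGeneric("effortMeasures"))
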