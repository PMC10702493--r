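#' Accessors for core classes
#'
#' `codes()`, `cellSize()`, `ecoregionId()` and `nodataCode()` read the
#' slots of a [LandscapeGrid-class]; `landscapes()`, `worldParams()`,
#' `classLegend()`, `ecoregionTable()`, `countryTable()` and
#' `overlapTable()` read a [SyntheticWorld-class].
#'
#' @param x the object.
#' @return The slot contents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("codes", function(x) standardGeneric("codes"))
#' @rdname accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname accessors
#' @export
setGeneric("ecoregionId", function(x) standardGeneric("ecoregionId"))
#' @rdname accessors
#' @export
setGeneric("nodataCode", function(x) standardGeneric("nodataCode"))
#' @rdname accessors
#' @export
setGeneric("landscapes", function(x) standardGeneric("landscapes"))
#' @rdname accessors
#' @export
setGeneric("worldParams", function(x) standardGeneric("worldParams"))
#' @rdname accessors
#' @export
setGeneric("classLegend", function(x) standardGeneric("classLegend"))
#' @rdname accessors
#' @export
setGeneric("ecoregionTable", function(x) standardGeneric("ecoregionTable"))
#' @rdname accessors
#' @export
setGeneric("countryTable", function(x) standardGeneric("countryTable"))
#' @rdname accessors
#' @export
setGeneric("overlapTable", function(x) standardGeneric("overlapTable"))

#' @rdname accessors
setMethod("codes", "LandscapeGrid", function(x) x@codes)
#' @rdname accessors
setMethod("cellSize", "LandscapeGrid", function(x) x@cellSize)
#' @rdname accessors
setMethod("ecoregionId", "LandscapeGrid", function(x) x@ecoregionId)
#' @rdname accessors
setMethod("nodataCode", "LandscapeGrid", function(x) x@nodataCode)
#' @rdname accessors
setMethod("landscapes", "SyntheticWorld", function(x) x@landscapes)
#' @rdname accessors
setMethod("worldParams", "SyntheticWorld", function(x) x@params)
#' @rdname accessors
setMethod("classLegend", "SyntheticWorld", function(x) x@legend)
#' @rdname accessors
setMethod("ecoregionTable", "SyntheticWorld", function(x) x@ecoregions)
#' @rdname accessors
setMethod("countryTable", "SyntheticWorld", function(x) x@countries)
#' @rdname accessors
setMethod("overlapTable", "SyntheticWorld", function(x) x@overlaps)
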