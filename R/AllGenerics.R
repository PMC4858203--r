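#' @rdname homologousPositions
#' @export
setGeneric("homologousPositions", function(x, ...)
  standardGeneric("homologousPositions"))

#' @rdname homologyMask
#' @export
setGeneric("homologyMask", function(x, ...) standardGeneric("homologyMask"))

#' @rdname accessors
#' @export
setGeneric("patternName", function(x) standardGeneric("patternName"))

#' @rdname accessors
#' @export
setGeneric("referenceCopy", function(x) standardGeneric("referenceCopy"))

#' @rdname accessors
#' @export
setGeneric("testCopy", function(x) standardGeneric("testCopy"))

#' @rdname enumerateUnitTriplets
#' @export
setGeneric("enumerateUnitTriplets", function(x, ...)
  standardGeneric("enumerateUnitTriplets"))

#' @rdname accessors
#' @export
setGeneric("tripletCounts", function(x) standardGeneric("tripletCounts"))

#' @rdname accessors
#' @export
setGeneric("censusTotal", function(x) standardGeneric("censusTotal"))

#' @rdname accessors
#' @export
setGeneric("sporeId", function(x) standardGeneric("sporeId"))

#' @rdname accessors
#' @export
setGeneric("mutationPositions", function(x) standardGeneric("mutationPositions"))

#' @rdname accessors
#' @export
setGeneric("mutationClasses", function(x) standardGeneric("mutationClasses"))

#' @rdname accessors
#' @export
setGeneric("nCT", function(x) standardGeneric("nCT"))

#' @rdname accessors
#' @export
setGeneric("nGA", function(x) standardGeneric("nGA"))

#' @rdname accessors
#' @export
setGeneric("nOther", function(x) standardGeneric("nOther"))

#' @rdname accessors
#' @export
setGeneric("siteCounts", function(x) standardGeneric("siteCounts"))

#' @rdname accessors
#' @export
setGeneric("sitePercent", function(x) standardGeneric("sitePercent"))

#' @rdname accessors
#' @export
setGeneric("nSpores", function(x) standardGeneric("nSpores"))
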