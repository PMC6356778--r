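#' @rdname ReferenceGenome-class
#' @param x,object an object.
#' @export
setGeneric("refLabel", function(x) standardGeneric("refLabel"))

#' @rdname ReferenceGenome-class
#' @export
setGeneric("refSequences", function(x) standardGeneric("refSequences"))

#' @rdname ReferenceGenome-class
#' @export
setGeneric("refDivergence", function(x) standardGeneric("refDivergence"))

#' @rdname Pedigree-class
#' @export
setGeneric("pedigreeTable", function(x) standardGeneric("pedigreeTable"))

#' @rdname Pedigree-class
#' @export
setGeneric("founders", function(x) standardGeneric("founders"))

#' @rdname GenotypeCalls-class
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeCalls-class
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))

#' @rdname GenotypeCalls-class
#' @export
setGeneric("altDepths", function(x) standardGeneric("altDepths"))

#' @rdname GenotypeCalls-class
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @rdname RelatednessResult-class
#' @export
setGeneric("rawRelatedness", function(x) standardGeneric("rawRelatedness"))

#' @rdname RelatednessResult-class
#' @export
setGeneric("scaledRelatedness", function(x) standardGeneric("scaledRelatedness"))
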