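#' Accessors for panel and spectrum objects
#'
#' @param x a \linkS4class{HaplotypePanel} or \linkS4class{TrinucSpectrum}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname accessors
#' @export
setMethod("haplotypes", "HaplotypePanel", function(x) x@haplotypes)

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname accessors
#' @export
setMethod("snpIds", "HaplotypePanel", function(x) x@snpId)

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "HaplotypePanel", function(x) x@sampleId)

#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname accessors
#' @export
setMethod("populations", "HaplotypePanel", function(x) x@population)

#' @rdname accessors
#' @export
setGeneric("channelCounts", function(x) standardGeneric("channelCounts"))

#' @rdname accessors
#' @export
setMethod("channelCounts", "TrinucSpectrum", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("channelProportions", function(x) standardGeneric("channelProportions"))

#' @rdname accessors
#' @export
setMethod("channelProportions", "TrinucSpectrum", function(x) x@proportions)

#' @rdname accessors
#' @export
setGeneric("weightedFrequencies", function(x) standardGeneric("weightedFrequencies"))

#' @rdname accessors
#' @export
setMethod("weightedFrequencies", "TrinucSpectrum", function(x) x@weighted)

#' @rdname accessors
#' @export
setGeneric("nMutations", function(x) standardGeneric("nMutations"))

#' @rdname accessors
#' @export
setMethod("nMutations", "TrinucSpectrum", function(x) x@nTotal)
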