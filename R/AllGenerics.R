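#' @include AllClasses.R
NULL

#' @export
setGeneric("genotypeCounts", function(x) standardGeneric("genotypeCounts"))
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))
#' @export
setGeneric("alleleFreqs", function(x) standardGeneric("alleleFreqs"))
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))
#' @export
setGeneric("nSnp", function(x) standardGeneric("nSnp"))

#' @export
setGeneric("additiveCoding", function(x, freqs) standardGeneric("additiveCoding"))
#' @export
setGeneric("dominanceCoding", function(x, freqs) standardGeneric("dominanceCoding"))

#' @export
setGeneric("genomicRelationship", function(x, definition = "II", ...)
  standardGeneric("genomicRelationship"))
#' @export
setGeneric("additiveRelationship", function(x) standardGeneric("additiveRelationship"))
#' @export
setGeneric("dominanceRelationship", function(x) standardGeneric("dominanceRelationship"))
#' @export
setGeneric("grmDefinition", function(x) standardGeneric("grmDefinition"))
#' @export
setGeneric("normalizedCoding", function(pair, design) standardGeneric("normalizedCoding"))

#' @export
setGeneric("sigmaA", function(x) standardGeneric("sigmaA"))
#' @export
setGeneric("sigmaD", function(x) standardGeneric("sigmaD"))
#' @export
setGeneric("sigmaE", function(x) standardGeneric("sigmaE"))
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))
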