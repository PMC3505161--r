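#' @importFrom BiocGenerics counts
NULL

#' @export
setGeneric("sampleDesign", function(object, ...) standardGeneric("sampleDesign"))

#' @export
setGeneric("countLevel", function(object) standardGeneric("countLevel"))

#' @export
setGeneric("normMethod", function(object) standardGeneric("normMethod"))

#' @export
setGeneric("normConstants", function(object) standardGeneric("normConstants"))

#' @export
setGeneric("normOffsets", function(object) standardGeneric("normOffsets"))

#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))

#' @export
setGeneric("modelDF", function(object) standardGeneric("modelDF"))

#' @export
setGeneric("pearsonStats", function(object) standardGeneric("pearsonStats"))

#' @export
setGeneric("fittedMeans", function(object) standardGeneric("fittedMeans"))

#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @export
setGeneric("blockingEffects", function(object, ...)
    standardGeneric("blockingEffects"))

#' @export
setGeneric("commonDispersion", function(object)
    standardGeneric("commonDispersion"))

#' @export
setGeneric("geneDispersions", function(object, ...)
    standardGeneric("geneDispersions"))
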