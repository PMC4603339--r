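#' @importFrom BiocGenerics counts
#' @export counts
NULL

#' Fragment count matrix of a HomeologCounts object
#' @param object a [HomeologCounts-class] object.
#' @return integer matrix, genes x libraries.
#' @export
setMethod("counts", "HomeologCounts", function(object) {
  SummarizedExperiment::assay(object, "counts")
})

#' Group labels of a HomeologCounts object
#' @param object a [HomeologCounts-class] object.
#' @return factor of library group labels.
#' @export
setGeneric("groups", function(object) standardGeneric("groups"))

#' @rdname groups
#' @export
setMethod("groups", "HomeologCounts", function(object) {
  SummarizedExperiment::colData(object)$group
})

#' Median-of-ratios size factors
#'
#' The per-library scaling constant equal to the median, over genes with a
#' finite geometric mean across libraries, of the ratio of the library's
#' count to the gene's geometric mean.
#'
#' @param object a counts matrix or [HomeologCounts-class] object.
#' @return positive numeric vector, one size factor per library.
#' @export
setGeneric("sizeFactors", function(object) standardGeneric("sizeFactors"))

#' @rdname sizeFactors
#' @export
setMethod("sizeFactors", "matrix", function(object) {
  estimateSizeFactorsMoR(object)
})

#' @rdname sizeFactors
#' @export
setMethod("sizeFactors", "HomeologCounts", function(object) {
  estimateSizeFactorsMoR(counts(object))
})
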