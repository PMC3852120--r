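#' @rdname RegionGenotypes-class
#' @param object,x a combSKAT object
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname RegionGenotypes-class
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname RegionGenotypes-class
#' @export
setGeneric("mafs", function(x) standardGeneric("mafs"))

#' @rdname SkatResult-class
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))

#' @rdname SkatResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname HaplotypePairSet-class
#' @export
setGeneric("haplotypePairs", function(x) standardGeneric("haplotypePairs"))

#' @rdname HaplotypePairSet-class
#' @export
setGeneric("haplotypeFreqs", function(x) standardGeneric("haplotypeFreqs"))

#' @rdname HaplotypeGrouping-class
#' @export
setGeneric("haplotypeGroups", function(x) standardGeneric("haplotypeGroups"))

#' @rdname HaplotypeGrouping-class
#' @export
setGeneric("referenceGroup", function(x) standardGeneric("referenceGroup"))

#' @rdname CombinedResult-class
#' @export
setGeneric("combinedPvalues", function(x) standardGeneric("combinedPvalues"))

#' Design-matrix extraction
#'
#' Returns the plain numeric matrix carried by a design-matrix-like object
#' (collapsed genotypes or the haplotype group matrix).
#'
#' @param x a CollapsedGenotypes or HaplotypeDesignMatrix object.
#' @return a numeric matrix with n rows.
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))
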