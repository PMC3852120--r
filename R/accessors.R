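#' @rdname RegionGenotypes-class
#' @export
setMethod("dosages", "RegionGenotypes", function(x) x@dosages)

#' @rdname RegionGenotypes-class
#' @export
setMethod("variantIds", "RegionGenotypes", function(x) x@variantIds)

#' @rdname RegionGenotypes-class
#' @export
setMethod("mafs", "RegionGenotypes", function(x) x@maf)

#' @rdname SkatResult-class
#' @export
setMethod("statistic", "SkatResult", function(x) x@Q)

#' @rdname SkatResult-class
#' @export
setMethod("pValue", "SkatResult", function(x) x@pValue)

#' @rdname HaplotypePairSet-class
#' @export
setMethod("haplotypePairs", "HaplotypePairSet", function(x) x@pairs)

#' @rdname HaplotypePairSet-class
#' @export
setMethod("haplotypeFreqs", "HaplotypePairSet", function(x) x@haplotypeFreq)

#' @rdname HaplotypeGrouping-class
#' @export
setMethod("haplotypeGroups", "HaplotypeGrouping", function(x) x@groups)

#' @rdname HaplotypeGrouping-class
#' @export
setMethod("referenceGroup", "HaplotypeGrouping",
    function(x) x@groups[[x@referenceIndex]])

#' @rdname CollapsedGenotypes-class
#' @export
setMethod("designMatrix", "CollapsedGenotypes", function(x) x@matrix)

#' @rdname HaplotypeDesignMatrix-class
#' @export
setMethod("designMatrix", "HaplotypeDesignMatrix", function(x) x@matrix)

#' @rdname CombinedResult-class
#' @export
setMethod("combinedPvalues", "CombinedResult", function(x)
    c(genotype = x@p1, haplotype = x@p2,
      minp = x@minpPvalue, sump = x@sumpPvalue))

setMethod("show", "RegionGenotypes", function(object) {
    cat("RegionGenotypes:", nrow(object@dosages), "samples x",
        ncol(object@dosages), "variants\n")
    cat("  MAF range:", sprintf("%.4g", min(object@maf)), "-",
        sprintf("%.4g", max(object@maf)), "\n")
    cat("  missing dosages:", sum(is.na(object@dosages)), "\n")
})

setMethod("show", "CollapsedGenotypes", function(object) {
    cat("CollapsedGenotypes:", nrow(object@matrix), "samples x",
        ncol(object@matrix), "columns",
        if (object@hasSuperVariant) "(incl. rare super-variant)" else
            "(no rare variants)", "\n")
    cat("  MAF threshold:", object@threshold, "\n")
})

setMethod("show", "HaplotypePairSet", function(object) {
    cat("HaplotypePairSet:", nrow(object@pairs), "individuals,",
        length(object@haplotypeFreq), "distinct haplotypes\n")
})

setMethod("show", "HaplotypeGrouping", function(object) {
    cat("HaplotypeGrouping:", length(object@groups), "groups (",
        object@scheme, ")\n", sep = "")
    cat("  group sizes:", vapply(object@groups, length, 1L), "\n")
    cat("  reference group frequency:",
        sprintf("%.4g", object@groupFreq[object@referenceIndex]), "\n")
})

setMethod("show", "NullModelFit", function(object) {
    cat("NullModelFit (", object@family, "): n = ", length(object@y),
        ", covariates = ", ncol(object@covariates), "\n", sep = "")
})

setMethod("show", "SkatResult", function(object) {
    cat("SkatResult: Q =", sprintf("%.6g", object@Q),
        " p =", sprintf("%.4g", object@pValue),
        " [", object@method, "]\n")
})

setMethod("show", "CorrelationEstimate", function(object) {
    cat("CorrelationEstimate: rho =", sprintf("%.4f", object@rho),
        "from", object@nPermutations, "permutations\n")
})

setMethod("show", "CombinedResult", function(object) {
    cat("CombinedResult (p-values from", object@pvalueSource, "null)\n")
    cat(sprintf("  genotype test:  p1 = %.4g\n", object@p1))
    cat(sprintf("  haplotype test: p2 = %.4g\n", object@p2))
    cat(sprintf("  MinP-val: stat = %.4g, p = %.4g\n",
                object@minpStat, object@minpPvalue))
    cat(sprintf("  SumP-val: stat = %.4g, p = %.4g\n",
                object@sumpStat, object@sumpPvalue))
    cat(sprintf("  rho-hat = %.4f (%d permutations)\n",
                object@rho@rho, object@rho@nPermutations))
})

setMethod("show", "HaplotypePool", function(object) {
    cat("HaplotypePool:", object@poolSize, "chromosomes,",
        nrow(object@hapMatrix), "distinct haplotypes,",
        ncol(object@hapMatrix), "segregating sites\n")
    cat("  rare sites (minor freq < 1%):",
        sum(pmin(object@siteFreqs, 1 - object@siteFreqs) < 0.01), "\n")
})

setMethod("show", "DiseaseModel", function(object) {
    cat("DiseaseModel:", object@basis, "basis,", object@scenario,
        "scenario\n")
    cat("  causal rare items:", length(object@causalRare),
        " (OR ", object@orRare, ")\n", sep = "")
    if (length(object@causalCommon))
        cat("  causal common item present (OR ", object@orCommon, ")\n",
            sep = "")
})

setMethod("show", "CaseControlSample", function(object) {
    cat("CaseControlSample:", object@nCases, "cases /", object@nControls,
        "controls,", ncol(object@genotypes@dosages), "variants\n")
})
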