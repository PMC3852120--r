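#' @import methods
NULL

.checkDosageEntries <- function(m) {
    v <- m[!is.na(m)]
    all(v %in% c(0, 1, 2))
}

#' RegionGenotypes: per-region minor-allele dosage matrix
#'
#' Container for the genotype dosages of one genomic region: an n x L matrix
#' of minor-allele counts in \{0, 1, 2\} (NA allowed for missing calls),
#' variant identifiers and per-variant sample minor-allele frequencies
#' computed over non-missing entries only.
#'
#' @slot dosages numeric matrix, n samples x L variants, entries 0/1/2/NA.
#' @slot variantIds character vector of length L.
#' @slot maf numeric vector of length L, sample MAF in [0, 0.5].
#' @exportClass RegionGenotypes
setClass("RegionGenotypes",
    representation(dosages = "matrix", variantIds = "character",
                   maf = "numeric"),
    validity = function(object) {
        msg <- NULL
        L <- ncol(object@dosages)
        if (L < 1L) msg <- c(msg, "at least one variant is required")
        if (!.checkDosageEntries(object@dosages))
            msg <- c(msg, "dosage entries must be 0, 1, 2 or NA")
        if (length(object@variantIds) != L)
            msg <- c(msg, "variantIds length must equal ncol(dosages)")
        if (length(object@maf) != L)
            msg <- c(msg, "maf length must equal ncol(dosages)")
        badMaf <- !is.na(object@maf) & (object@maf < 0 | object@maf > 0.5)
        if (any(badMaf))
            msg <- c(msg, "maf values must lie in [0, 0.5]")
        allMiss <- colSums(!is.na(object@dosages)) == 0L
        if (any(allMiss))
            msg <- c(msg, paste0("variant(s) with all dosages missing: ",
                paste(object@variantIds[allMiss], collapse = ", ")))
        if (is.null(msg)) TRUE else msg
    })

#' CollapsedGenotypes: genotype matrix after rare-variant collapsing
#'
#' Common variants (sample MAF at or above the threshold) keep their own
#' columns; all rare variants are replaced by a single burden super-variant
#' column, the per-individual sum of rare minor alleles capped at 2.
#'
#' @slot matrix numeric design matrix, n x L'.
#' @slot hasSuperVariant logical flag, TRUE when a rare column was formed.
#' @slot threshold MAF threshold that defined rarity.
#' @exportClass CollapsedGenotypes
setClass("CollapsedGenotypes",
    representation(matrix = "matrix", hasSuperVariant = "logical",
                   threshold = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (object@hasSuperVariant) {
            sv <- object@matrix[, ncol(object@matrix)]
            if (!all(sv[!is.na(sv)] %in% c(0, 1, 2)))
                msg <- c(msg, "super-variant entries must be in {0,1,2}")
        }
        if (object@threshold <= 0 || object@threshold >= 0.5)
            msg <- c(msg, "threshold must lie in (0, 0.5)")
        if (is.null(msg)) TRUE else msg
    })

#' HaplotypePairSet: the two region haplotypes of each individual
#'
#' @slot pairs character matrix n x 2 of haplotype identifiers (allele
#'   strings over the region's sites), one ordered pair per individual.
#' @slot haplotypeFreq named numeric, pooled sample frequency of every
#'   observed haplotype; sums to 1 over the 2n chromosomes.
#' @exportClass HaplotypePairSet
setClass("HaplotypePairSet",
    representation(pairs = "matrix", haplotypeFreq = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (ncol(object@pairs) != 2L)
            msg <- c(msg, "pairs must have exactly two columns")
        ids <- unique(as.vector(object@pairs))
        if (!all(ids %in% names(object@haplotypeFreq)))
            msg <- c(msg, "every observed haplotype needs a frequency entry")
        if (abs(sum(object@haplotypeFreq) - 1) > 1e-8)
            msg <- c(msg, "haplotype frequencies must sum to 1")
        if (is.null(msg)) TRUE else msg
    })

#' HaplotypeGrouping: partition of haplotypes into frequency groups
#'
#' Groups are ordered so that the last one (the reference, omitted from the
#' regression matrix) carries the largest total frequency.
#'
#' @slot groups list of disjoint character vectors of haplotype identifiers.
#' @slot referenceIndex index of the most common group (always M).
#' @slot scheme "common-vs-pooled-rare" or "three-bin-fallback".
#' @slot groupFreq total pooled frequency of each group.
#' @exportClass HaplotypeGrouping
setClass("HaplotypeGrouping",
    representation(groups = "list", referenceIndex = "integer",
                   scheme = "character", groupFreq = "numeric"),
    validity = function(object) {
        msg <- NULL
        M <- length(object@groups)
        if (M < 2L) msg <- c(msg, "at least two haplotype groups are required")
        ids <- unlist(object@groups)
        if (anyDuplicated(ids))
            msg <- c(msg, "groups must be disjoint")
        if (object@referenceIndex != M)
            msg <- c(msg, "reference group must be the last group")
        if (M >= 2L &&
            object@groupFreq[M] < max(object@groupFreq) - 1e-12)
            msg <- c(msg, "reference group must have the largest frequency")
        if (is.null(msg)) TRUE else msg
    })

#' HaplotypeDesignMatrix: per-individual haplotype-group counts
#'
#' Column j counts how many of individual i's two haplotypes fall in group
#' H_j, for j = 1..M-1; the most common group H_M is the omitted reference.
#'
#' @slot matrix integer matrix n x (M-1), entries in \{0,1,2\}.
#' @exportClass HaplotypeDesignMatrix
setClass("HaplotypeDesignMatrix",
    representation(matrix = "matrix"),
    validity = function(object) {
        if (!all(object@matrix %in% c(0L, 1L, 2L)))
            return("entries must be in {0,1,2}")
        if (any(rowSums(object@matrix) > 2))
            return("row sums cannot exceed 2")
        TRUE
    })

#' NullModelFit: reduced model of phenotype on covariates only
#'
#' The fit of Y = a + Cc + eps (gaussian least squares, or logistic ML for a
#' dichotomous phenotype), shared by the score tests and the residual
#' permutation engine. Residuals are on the response scale.
#'
#' @slot family "gaussian" or "binomial".
#' @slot coefficients intercept followed by covariate effects.
#' @slot fitted fitted values on the response scale.
#' @slot residuals response-scale residuals Y - fitted.
#' @slot dispersion residual variance estimate (gaussian; 1 for binomial).
#' @slot covariates the n x K covariate matrix (0 columns when none).
#' @slot y the phenotype vector.
#' @exportClass NullModelFit
setClass("NullModelFit",
    representation(family = "character", coefficients = "numeric",
                   fitted = "numeric", residuals = "numeric",
                   dispersion = "numeric", covariates = "matrix",
                   y = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (!object@family %in% c("gaussian", "binomial"))
            msg <- c(msg, "family must be gaussian or binomial")
        n <- length(object@y)
        if (length(object@fitted) != n || length(object@residuals) != n)
            msg <- c(msg, "fitted/residual lengths must match y")
        if (max(abs(object@y - object@fitted - object@residuals)) > 1e-8)
            msg <- c(msg, "residuals must equal y - fitted")
        if (is.null(msg)) TRUE else msg
    })

#' SkatResult: variance-component score test result
#'
#' @slot Q the nonnegative score statistic.
#' @slot eigenvalues weights of the null mixture of 1-df chi-squares.
#' @slot pValue p-value in (0, 1].
#' @slot method "davies", "moment-matched" or "permutation".
#' @exportClass SkatResult
setClass("SkatResult",
    representation(Q = "numeric", eigenvalues = "numeric",
                   pValue = "numeric", method = "character"),
    validity = function(object) {
        msg <- NULL
        if (object@Q < 0) msg <- c(msg, "Q must be nonnegative")
        if (object@pValue <= 0 || object@pValue > 1)
            msg <- c(msg, "pValue must lie in (0, 1]")
        if (is.null(msg)) TRUE else msg
    })

#' CorrelationEstimate: permutation estimate of the transform correlation
#'
#' Pearson correlation between the inverse-normal transforms of the two
#' tests' permutation p-values, with a clamped copy used inside the
#' combined-test formulas.
#'
#' @slot rho raw Pearson estimate in [-1, 1].
#' @slot nPermutations number of permutation replicates used.
#' @slot clampedRho copy clamped into [-0.999, 0.999].
#' @exportClass CorrelationEstimate
setClass("CorrelationEstimate",
    representation(rho = "numeric", nPermutations = "integer",
                   clampedRho = "numeric"),
    validity = function(object) {
        if (abs(object@clampedRho) > 0.999)
            return("clampedRho must lie in [-0.999, 0.999]")
        TRUE
    })

#' CombinedResult: the two underlying p-values and both combined tests
#'
#' @slot p1 genotype-test p-value.
#' @slot p2 haplotype-test p-value.
#' @slot rho CorrelationEstimate used in the combined null.
#' @slot minpStat min(p1, p2).
#' @slot minpPvalue p-value of the MinP-val test.
#' @slot sumpStat y1 + y2 (inverse-normal transforms).
#' @slot sumpPvalue p-value of the SumP-val test.
#' @slot pvalueSource "theoretical" or "permutation".
#' @slot normalityPvalue Shapiro-Wilk gate p-value (NA when the gate was
#'   not run).
#' @exportClass CombinedResult
setClass("CombinedResult",
    representation(p1 = "numeric", p2 = "numeric",
                   rho = "CorrelationEstimate",
                   minpStat = "numeric", minpPvalue = "numeric",
                   sumpStat = "numeric", sumpPvalue = "numeric",
                   pvalueSource = "character", normalityPvalue = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (abs(object@minpStat - min(object@p1, object@p2)) > 1e-12)
            msg <- c(msg, "minpStat must equal min(p1, p2)")
        pv <- c(object@minpPvalue, object@sumpPvalue)
        if (any(pv <= 0 | pv > 1))
            msg <- c(msg, "combined p-values must lie in (0, 1]")
        if (!object@pvalueSource %in% c("theoretical", "permutation"))
            msg <- c(msg, "pvalueSource must be theoretical or permutation")
        if (is.null(msg)) TRUE else msg
    })

#' PermutationPlan: reproducible permutation schedule
#'
#' Replicate r draws its permutation from a counter-derived sub-seed, so any
#' replicate is reproducible in isolation and identical (seed, n) pairs give
#' identical permutation sequences.
#'
#' @slot nPermutations number of replicates.
#' @slot seed base integer seed.
#' @exportClass PermutationPlan
setClass("PermutationPlan",
    representation(nPermutations = "integer", seed = "integer"),
    validity = function(object) {
        if (object@nPermutations < 0L) return("nPermutations must be >= 0")
        TRUE
    })

#' PermutationReplicates: null statistic and p-value replicates
#'
#' @slot statsGenotype genotype SKAT statistics, one per replicate.
#' @slot statsHaplotype haplotype SKAT statistics, one per replicate.
#' @slot pvalsGenotype per-replicate genotype p-values in (0, 1].
#' @slot pvalsHaplotype per-replicate haplotype p-values in (0, 1].
#' @exportClass PermutationReplicates
setClass("PermutationReplicates",
    representation(statsGenotype = "numeric", statsHaplotype = "numeric",
                   pvalsGenotype = "numeric", pvalsHaplotype = "numeric"),
    validity = function(object) {
        n <- length(object@statsGenotype)
        if (length(object@statsHaplotype) != n ||
            length(object@pvalsGenotype) != n ||
            length(object@pvalsHaplotype) != n)
            return("all replicate vectors must have equal length")
        pv <- c(object@pvalsGenotype, object@pvalsHaplotype)
        if (length(pv) && any(pv <= 0 | pv > 1))
            return("replicate p-values must lie in (0, 1]")
        TRUE
    })

#' HaplotypePool: population pool of region haplotypes
#'
#' A synthetic stand-in for a forward/coalescent population simulation:
#' distinct binary haplotypes over L segregating sites with multiplicities
#' summing to the pool size (in chromosomes).
#'
#' @slot hapMatrix integer 0/1 matrix, distinct haplotypes x sites.
#' @slot counts multiplicity of each distinct haplotype.
#' @slot siteFreqs derived-allele frequency of each site in the pool.
#' @slot poolSize total number of chromosomes.
#' @exportClass HaplotypePool
setClass("HaplotypePool",
    representation(hapMatrix = "matrix", counts = "integer",
                   siteFreqs = "numeric", poolSize = "integer"),
    validity = function(object) {
        msg <- NULL
        if (any(object@counts < 1L)) msg <- c(msg, "counts must be >= 1")
        if (sum(object@counts) != object@poolSize)
            msg <- c(msg, "counts must sum to the pool size")
        if (any(object@siteFreqs <= 0 | object@siteFreqs >= 1))
            msg <- c(msg, "every site must be segregating (0 < freq < 1)")
        if (length(object@siteFreqs) != ncol(object@hapMatrix))
            msg <- c(msg, "siteFreqs length must match the site count")
        if (is.null(msg)) TRUE else msg
    })

#' DiseaseModel: phenotype-generating specification
#'
#' Genotype- or haplotype-based logistic disease model with baseline
#' prevalence 0.01 and per-scenario odds ratios: "Rare" (rare OR 4, no
#' common causal), "Both" (3 and 1.2), "Common" (1.5 and 2).
#'
#' @slot basis "genotype" or "haplotype".
#' @slot scenario "Rare", "Both", "Common" or "null".
#' @slot causalRare site indices (genotype basis) or haplotype identifier
#'   strings (haplotype basis) of the causal rare items.
#' @slot causalCommon the single causal common item, or empty.
#' @slot orRare odds ratio shared by all causal rare items.
#' @slot orCommon odds ratio of the causal common item (NA when absent).
#' @slot prevalence baseline disease probability.
#' @exportClass DiseaseModel
setClass("DiseaseModel",
    representation(basis = "character", scenario = "character",
                   causalRare = "ANY", causalCommon = "ANY",
                   orRare = "numeric", orCommon = "numeric",
                   prevalence = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (!object@basis %in% c("genotype", "haplotype"))
            msg <- c(msg, "basis must be genotype or haplotype")
        if (!object@scenario %in% c("Rare", "Both", "Common", "null"))
            msg <- c(msg, "scenario must be Rare, Both, Common or null")
        if (object@prevalence <= 0 || object@prevalence >= 1)
            msg <- c(msg, "prevalence must lie in (0, 1)")
        if (is.null(msg)) TRUE else msg
    })

#' CaseControlSample: one simulated data replicate
#'
#' @slot genotypes RegionGenotypes of the sampled individuals.
#' @slot haplotypePairs HaplotypePairSet of the same individuals.
#' @slot phenotype binary vector, cases first.
#' @slot nCases number of cases.
#' @slot nControls number of controls.
#' @exportClass CaseControlSample
setClass("CaseControlSample",
    representation(genotypes = "RegionGenotypes",
                   haplotypePairs = "HaplotypePairSet",
                   phenotype = "numeric", nCases = "integer",
                   nControls = "integer"),
    validity = function(object) {
        msg <- NULL
        if (sum(object@phenotype == 1) != object@nCases ||
            sum(object@phenotype == 0) != object@nControls)
            msg <- c(msg, "phenotype must contain exactly the requested ",
                     "case/control counts")
        if (is.null(msg)) TRUE else msg
    })
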