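#' Construct a RegionGenotypes object
#'
#' Wraps a dosage matrix for one region. Sample minor-allele frequencies are
#' computed per variant over non-missing entries. Dosages are stored as
#' given; where a column's counted allele is the major allele in the sample
#' (allele frequency above 0.5, as can happen for derived-allele dosages
#' from simulated pools), rare-variant collapsing re-orients it internally.
#'
#' @param dosages numeric matrix of allele counts in \{0,1,2\}, samples in
#'   rows, variants in columns; NA marks a missing call.
#' @param variantIds optional character vector of variant labels.
#' @return a \linkS4class{RegionGenotypes} object.
#' @examples
#' g <- RegionGenotypes(matrix(c(0, 1, 2, 0, 0, 1), nrow = 3))
#' mafs(g)
#' @export
RegionGenotypes <- function(dosages, variantIds = colnames(dosages)) {
    dosages <- as.matrix(dosages)
    if (is.null(variantIds))
        variantIds <- paste0("var", seq_len(ncol(dosages)))
    f <- .alleleFreq(dosages)
    new("RegionGenotypes", dosages = dosages,
        variantIds = as.character(variantIds), maf = pmin(f, 1 - f))
}

# counted-allele frequency per column over non-missing entries
.alleleFreq <- function(dosages) {
    colMeans(dosages, na.rm = TRUE) / 2
}

# dosage matrix re-oriented so every column counts the sample minor allele
.minorDosages <- function(G) {
    d <- G@dosages
    flip <- .alleleFreq(d) > 0.5
    if (any(flip)) d[, flip] <- 2 - d[, flip]
    d
}

#' Mean-impute missing dosages
#'
#' Replaces missing entries of each variant column by the column mean of the
#' non-missing dosages, preserving the sample allele frequency.
#'
#' @param m numeric matrix with possible NAs.
#' @return the matrix with NAs replaced.
#' @export
meanImpute <- function(m) {
    if (!anyNA(m)) return(m)
    for (j in which(colSums(is.na(m)) > 0L)) {
        mj <- m[, j]
        m[is.na(mj), j] <- mean(mj, na.rm = TRUE)
    }
    m
}

#' Collapse rare variants into a burden super-variant
#'
#' Variants with sample MAF below the threshold are replaced by a single
#' super-variant column: for each individual the sum of minor alleles across
#' the rare variants, capped at 2. Common variants keep their own columns
#' unchanged. With no rare variant present, the output matrix is just the
#' common-variant dosages; with no common variant, it is the single
#' super-variant column.
#'
#' Missing dosages are mean-imputed per variant before collapsing.
#'
#' @param G a \linkS4class{RegionGenotypes} object.
#' @param threshold sample-MAF rarity threshold in (0, 0.5); default 0.01.
#' @return a \linkS4class{CollapsedGenotypes} object.
#' @examples
#' G <- RegionGenotypes(cbind(c(1, 0, 0, 0), c(1, 0, 0, 0),
#'                            c(2, 1, 1, 0)))
#' designMatrix(collapseRareVariants(G, threshold = 0.2))
#' @export
collapseRareVariants <- function(G, threshold = 0.01) {
    stopifnot(is(G, "RegionGenotypes"))
    if (threshold <= 0 || threshold >= 0.5)
        stop("threshold must lie in (0, 0.5)")
    rare <- G@maf < threshold
    d <- meanImpute(G@dosages)
    common <- d[, !rare, drop = FALSE]
    colnames(common) <- G@variantIds[!rare]
    if (any(rare)) {
        minor <- meanImpute(.minorDosages(G))[, rare, drop = FALSE]
        super <- pmin(2, rowSums(minor))
        # imputed fractional contributions are rounded back onto {0,1,2}
        super <- pmin(2, pmax(0, round(super)))
        m <- cbind(common, superVariant = super)
    } else {
        m <- common
    }
    new("CollapsedGenotypes", matrix = m, hasSuperVariant = any(rare),
        threshold = threshold)
}
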