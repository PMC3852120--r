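#' Read a region-definition table
#'
#' Delimited text with header columns \code{name, chrom, start, end} and an
#' optional \code{category} column (used for priority mapping). Coordinates
#' are 1-based inclusive.
#'
#' @param path file path (tab- or comma-delimited, autodetected).
#' @return data.frame of region definitions.
#' @export
readRegionTable <- function(path) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl(",", header)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    need <- c("name", "chrom", "start", "end")
    if (!all(need %in% names(df)))
        stop("region table needs columns: ", paste(need, collapse = ", "))
    if (any(df$start > df$end)) stop("region with start > end")
    df
}

#' Read a phenotype/covariate table
#'
#' @param path delimited file with header; first column sample id.
#' @param phenoCol name of the phenotype column.
#' @param covarCols character vector of covariate column names (may be
#'   empty).
#' @return list with \code{ids}, \code{y} and covariate matrix \code{C}
#'   (samples with missing phenotype are dropped).
#' @export
readSampleTable <- function(path, phenoCol = "phenotype",
                            covarCols = character(0)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl(",", header)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    if (anyDuplicated(df[[1]])) stop("sample ids must be unique")
    if (!phenoCol %in% names(df))
        stop("phenotype column '", phenoCol, "' not found")
    keep <- !is.na(df[[phenoCol]])
    df <- df[keep, , drop = FALSE]
    C <- if (length(covarCols))
        as.matrix(df[, covarCols, drop = FALSE]) else NULL
    list(ids = as.character(df[[1]]), y = df[[phenoCol]], C = C)
}

.regionWindow <- function(region, flank) {
    c(max(1, region$start - flank), region$end + flank)
}

.readVcfGt <- function(vcfPath, region = NULL, flank = 10000) {
    vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    pos <- as.numeric(fix[, "POS"])
    keep <- rep(TRUE, length(pos))
    if (!is.null(region)) {
        w <- .regionWindow(region, flank)
        keep <- fix[, "CHROM"] == as.character(region$chrom) &
            pos >= w[1] & pos <= w[2]
        if (!any(keep))
            stop("no variants in region ", region$name, " (", region$chrom,
                 ":", w[1], "-", w[2], ")")
    }
    biall <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
        !grepl(",", fix[, "ALT"])
    if (any(keep & !biall))
        warning(sum(keep & !biall), " non-biallelic-SNP record(s) skipped")
    keep <- keep & biall
    gt <- vcfR::extract.gt(vcf, element = "GT")
    gt <- gt[keep, , drop = FALSE]
    ids <- fix[keep, "ID"]
    noId <- is.na(ids) | ids == "."
    ids[noId] <- paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])[noId]
    list(gt = gt, ids = ids, chrom = fix[keep, "CHROM"],
         pos = pos[keep])
}

#' Read region genotypes from a VCF
#'
#' Decodes GT fields of biallelic SNPs inside the flank-extended region
#' into dosages, then orients each variant to count the sample minor
#' allele (columns with ALT frequency above 0.5 are flipped). Missing
#' genotypes ("./.") become NA and are excluded from the MAF denominator.
#'
#' @param vcfPath path to a VCF file (plain text or bgzipped).
#' @param region one-row region definition (list or data.frame row with
#'   name, chrom, start, end), or NULL for all variants.
#' @param flank bases added on both sides; default 10000.
#' @return a \linkS4class{RegionGenotypes}.
#' @export
readRegionGenotypes <- function(vcfPath, region = NULL, flank = 10000) {
    v <- .readVcfGt(vcfPath, region, flank)
    alleles <- apply(v$gt, c(1, 2), function(g) {
        if (is.na(g)) return(NA_real_)
        a <- strsplit(g, "[/|]")[[1]]
        if (any(a == ".")) return(NA_real_)
        sum(as.numeric(a))
    })
    d <- t(alleles)  # samples x variants
    altFreq <- colMeans(d, na.rm = TRUE) / 2
    flip <- !is.na(altFreq) & altFreq > 0.5
    if (any(flip)) d[, flip] <- 2 - d[, flip]
    RegionGenotypes(d, variantIds = v$ids)
}

#' Read phased haplotype pairs from a VCF
#'
#' Requires every GT field to be phased ("|" separator); an unphased entry
#' aborts with the offending sample and site. Each individual's two
#' haplotypes are the allele strings over the region's biallelic SNPs, in
#' GT order.
#'
#' @inheritParams readRegionGenotypes
#' @return a \linkS4class{HaplotypePairSet}.
#' @export
readHaplotypePairs <- function(vcfPath, region = NULL, flank = 10000) {
    v <- .readVcfGt(vcfPath, region, flank)
    unphased <- which(!grepl("|", v$gt, fixed = TRUE) & !is.na(v$gt),
                      arr.ind = TRUE)
    if (nrow(unphased))
        stop("unphased genotype for sample ",
             colnames(v$gt)[unphased[1, 2]], " at site ",
             v$ids[unphased[1, 1]])
    if (anyNA(v$gt))
        stop("missing genotypes are not supported in phased input")
    a1 <- substr(v$gt, 1, 1)
    a2 <- substr(v$gt, 3, 3)
    h1 <- apply(matrix(a1, nrow(v$gt)), 2, paste, collapse = "")
    h2 <- apply(matrix(a2, nrow(v$gt)), 2, paste, collapse = "")
    H <- HaplotypePairSet(cbind(h1, h2))
    H
}

#' Write genotypes (and optionally phased haplotypes) as plain-text VCF
#'
#' Minimal VCFv4.2 writer used for round-trip testing and for exporting
#' simulated replicates. With \code{phased=TRUE} the GT fields are written
#' from the haplotype pairs with the "|" separator, otherwise from dosages
#' with "/".
#'
#' @param x a \linkS4class{CaseControlSample} or
#'   \linkS4class{RegionGenotypes}.
#' @param path output path.
#' @param phased write phased GT from the haplotype pairs (requires a
#'   CaseControlSample).
#' @param chrom,startPos chromosome label and first-variant position used
#'   for the synthetic coordinates (one variant per base onward).
#' @return invisibly, the path.
#' @export
writeVcfText <- function(x, path, phased = FALSE, chrom = "1",
                         startPos = 1000L) {
    if (is(x, "CaseControlSample")) {
        G <- x@genotypes
        pairs <- x@haplotypePairs@pairs
    } else {
        G <- x
        pairs <- NULL
        if (phased) stop("phased output needs a CaseControlSample")
    }
    d <- G@dosages
    n <- nrow(d); L <- ncol(d)
    samples <- paste0("S", seq_len(n))
    if (phased) {
        al1 <- do.call(rbind, strsplit(pairs[, 1], ""))
        al2 <- do.call(rbind, strsplit(pairs[, 2], ""))
        gtmat <- matrix(paste0(al1, "|", al2), n, L)
    } else {
        code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
        gtmat <- matrix("./.", n, L)
        ok <- !is.na(d)
        gtmat[ok] <- code[as.character(d[ok])]
    }
    lines <- c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"))
    for (j in seq_len(L)) {
        lines <- c(lines, paste(c(chrom, startPos + j - 1L,
                                  G@variantIds[j], "A", "G", ".", "PASS",
                                  ".", "GT", gtmat[, j]), collapse = "\t"))
    }
    writeLines(lines, path)
    invisible(path)
}

#' Map variants to regions
#'
#' Assigns every variant to exactly one region: a variant overlapping one
#' flank-extended gene goes to that gene; a variant hitting several genes
#' is resolved by the category priority coding > intronic > utr5 > utr3
#' when the region table carries a \code{category} column, and otherwise by
#' the nearest gene body (with a warning). Variants hitting no gene are
#' grouped into inter-gene blocks named after the flanking genes.
#'
#' @param variants data.frame with columns \code{chrom, pos} and optionally
#'   \code{id}.
#' @param regions region-definition data.frame (see
#'   \code{\link{readRegionTable}}).
#' @param flank flank size in bases; default 10000.
#' @return the \code{variants} data.frame with an appended \code{region}
#'   column.
#' @export
mapVariantsToRegions <- function(variants, regions, flank = 10000) {
    stopifnot(all(c("chrom", "pos") %in% names(variants)),
              all(c("name", "chrom", "start", "end") %in% names(regions)))
    vr <- GenomicRanges::GRanges(as.character(variants$chrom),
        IRanges::IRanges(variants$pos, variants$pos))
    gr <- GenomicRanges::GRanges(as.character(regions$chrom),
        IRanges::IRanges(pmax(1, regions$start - flank),
                         regions$end + flank))
    body <- GenomicRanges::GRanges(as.character(regions$chrom),
        IRanges::IRanges(regions$start, regions$end))
    hits <- GenomicRanges::findOverlaps(vr, gr)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    hasCategory <- "category" %in% names(regions)
    prio <- c(coding = 1, intronic = 2, utr5 = 3, utr3 = 4)
    assignment <- rep(NA_character_, nrow(variants))
    multiWarned <- FALSE
    for (i in unique(qh)) {
        cand <- sh[qh == i]
        if (length(cand) == 1L) {
            assignment[i] <- regions$name[cand]
        } else if (hasCategory) {
            p <- prio[as.character(regions$category[cand])]
            p[is.na(p)] <- 5
            assignment[i] <- regions$name[cand[which.min(p)]]
        } else {
            if (!multiWarned) {
                warning("variant(s) within the flank of multiple genes ",
                        "and no category column: using nearest gene body")
                multiWarned <- TRUE
            }
            dist <- GenomicRanges::distance(vr[i], body[cand])
            assignment[i] <- regions$name[cand[which.min(dist)]]
        }
    }
    # inter-gene blocks for the unassigned, named by flanking gene bodies
    un <- which(is.na(assignment))
    for (i in un) {
        chr <- as.character(variants$chrom[i])
        onChr <- regions[as.character(regions$chrom) == chr, , drop = FALSE]
        if (!nrow(onChr)) {
            assignment[i] <- paste0("intergenic_", chr)
            next
        }
        onChr <- onChr[order(onChr$start), , drop = FALSE]
        before <- onChr$name[onChr$end < variants$pos[i]]
        after <- onChr$name[onChr$start > variants$pos[i]]
        left <- if (length(before)) before[length(before)] else "telomere"
        right <- if (length(after)) after[1] else "telomere"
        assignment[i] <- paste0("intergenic_", left, "_", right)
    }
    variants$region <- assignment
    variants
}

#' Combined region test on one prepared dataset
#'
#' The full single-region pipeline: rare-variant collapsing, haplotype
#' grouping and regression-matrix construction, reduced-model fit, both
#' SKAT tests, permutation estimation of the transform correlation, the
#' bivariate-normality gate, and both combined tests. When the gate (or the
#' \code{pvalueSource} override) selects "permutation", underlying and
#' combined p-values are empirical with add-one correction.
#'
#' @param G a \linkS4class{RegionGenotypes}.
#' @param H a \linkS4class{HaplotypePairSet} on the same samples.
#' @param y phenotype vector.
#' @param C optional covariate matrix.
#' @param family "gaussian" or "binomial".
#' @param mafThreshold collapse threshold; default 0.01.
#' @param hapFreqThreshold common-haplotype threshold; default 0.01.
#' @param permsRho permutations for correlation estimation; default 500.
#' @param permsEmpirical permutations for empirical p-values; default 1000.
#' @param alphaGenomewide genome-wide level for the normality gate.
#' @param pvalueSource "gate" (decide by Shapiro-Wilk), "theoretical" or
#'   "permutation".
#' @param seed RNG seed.
#' @return a \linkS4class{CombinedResult}.
#' @export
combinedRegionTest <- function(G, H, y, C = NULL,
                               family = c("gaussian", "binomial"),
                               mafThreshold = 0.01,
                               hapFreqThreshold = 0.01,
                               permsRho = 500L, permsEmpirical = 1000L,
                               alphaGenomewide = 1.38e-6,
                               pvalueSource = c("gate", "theoretical",
                                                "permutation"),
                               seed = 1L) {
    family <- match.arg(family)
    pvalueSource <- match.arg(pvalueSource)
    Xg <- designMatrix(collapseRareVariants(G, mafThreshold))
    grouping <- groupHaplotypes(H, hapFreqThreshold)
    Xh <- designMatrix(buildHaplotypeMatrix(H, grouping))
    fit <- fitNullModel(y, C, family)
    resG <- skatTest(Xg, fit)
    resH <- skatTest(Xh, fit)
    plan <- permutationPlan(permsRho, seed)
    reps <- runPermutations(Xg, Xh, fit, plan, pvalues = "analytic")
    rho <- estimateCorrelation(reps@pvalsGenotype, reps@pvalsHaplotype)
    gate <- normalityGate(.invNorm(reps@pvalsGenotype),
                          .invNorm(reps@pvalsHaplotype), alphaGenomewide)
    source <- switch(pvalueSource, gate = gate$source, pvalueSource)
    if (source == "theoretical") {
        combineTests(pValue(resG), pValue(resH), rho,
                     source = "theoretical",
                     normalityPvalue = gate$pvalue)
    } else {
        planE <- permutationPlan(permsEmpirical, seed + 1L)
        repsE <- runPermutations(Xg, Xh, fit, planE, pvalues = "rank")
        p1 <- empiricalPvalue(statistic(resG), repsE@statsGenotype)
        p2 <- empiricalPvalue(statistic(resH), repsE@statsHaplotype)
        combineTests(p1, p2, rho, source = "permutation",
                     permP1 = repsE@pvalsGenotype,
                     permP2 = repsE@pvalsHaplotype,
                     normalityPvalue = gate$pvalue)
    }
}

#' Genome-wide combined region tests from VCF input
#'
#' Runs the single-region pipeline over every region of a definition table,
#' reading unphased genotypes and phased haplotypes from VCF. Per-region
#' failures are caught and reported as rows with a status message rather
#' than aborting the run. The Bonferroni threshold 0.05/#regions is
#' attached as the \code{"bonferroni"} attribute.
#'
#' @param vcfPath unphased VCF (dosage source).
#' @param phasedVcfPath phased VCF (haplotype source).
#' @param regions region-definition data.frame.
#' @param y phenotype vector (aligned with the VCF sample order).
#' @param C optional covariate matrix.
#' @param family,flank,seed,... passed through to
#'   \code{\link{combinedRegionTest}}.
#' @return data.frame with one row per region: variant count, the four
#'   p-values, rho-hat, p-value source, gate p-value and status.
#' @export
testRegions <- function(vcfPath, phasedVcfPath, regions, y, C = NULL,
                        family = "gaussian", flank = 10000, seed = 1L,
                        ...) {
    rows <- lapply(seq_len(nrow(regions)), function(i) {
        region <- regions[i, , drop = FALSE]
        out <- data.frame(region = region$name, n_snps = NA_integer_,
                          p_genotype_skat = NA_real_,
                          p_haplotype_skat = NA_real_,
                          p_minp = NA_real_, p_sump = NA_real_,
                          rho_hat = NA_real_,
                          pvalue_source = NA_character_,
                          normality_pvalue = NA_real_, status = "ok")
        res <- tryCatch({
            G <- readRegionGenotypes(vcfPath, region, flank)
            H <- readHaplotypePairs(phasedVcfPath, region, flank)
            r <- combinedRegionTest(G, H, y, C, family = family,
                                    seed = seed + i, ...)
            out$n_snps <- ncol(dosages(G))
            out$p_genotype_skat <- r@p1
            out$p_haplotype_skat <- r@p2
            out$p_minp <- r@minpPvalue
            out$p_sump <- r@sumpPvalue
            out$rho_hat <- r@rho@rho
            out$pvalue_source <- r@pvalueSource
            out$normality_pvalue <- r@normalityPvalue
            out
        }, error = function(e) {
            out$status <- conditionMessage(e)
            out
        })
        res
    })
    out <- do.call(rbind, rows)
    attr(out, "bonferroni") <- bonferroniThreshold(nrow(regions))
    out
}
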