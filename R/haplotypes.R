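#' Construct a HaplotypePairSet
#'
#' @param pairs character matrix (or 2-column data.frame) with one row per
#'   individual holding the identifiers of its two region haplotypes.
#' @param haplotypeFreq optional named frequency vector; computed from the
#'   pooled 2n chromosomes when omitted.
#' @return a \linkS4class{HaplotypePairSet} object.
#' @export
HaplotypePairSet <- function(pairs, haplotypeFreq = NULL) {
    pairs <- as.matrix(pairs)
    storage.mode(pairs) <- "character"
    if (is.null(haplotypeFreq)) {
        tab <- table(as.vector(pairs))
        haplotypeFreq <- as.numeric(tab) / sum(tab)
        names(haplotypeFreq) <- names(tab)
    }
    new("HaplotypePairSet", pairs = pairs, haplotypeFreq = haplotypeFreq)
}

#' Group haplotypes by frequency
#'
#' Every haplotype with pooled sample frequency at or above
#' \code{commonThreshold} forms its own singleton group; all rarer
#' haplotypes are pooled into one group. If no haplotype reaches the
#' threshold, a three-bin fallback is used instead: frequency below 0.05\%,
#' between 0.05\% and 0.1\% (closed interval), and above 0.1\%; empty bins
#' are dropped. The most common group is placed last and serves as the
#' reference omitted from the regression matrix. Frequency ties for the
#' reference are broken towards the group containing the lexicographically
#' smallest haplotype label, so the choice is deterministic.
#'
#' @param H a \linkS4class{HaplotypePairSet}.
#' @param commonThreshold frequency above which a haplotype is common;
#'   default 0.01.
#' @return a \linkS4class{HaplotypeGrouping}.
#' @examples
#' H <- HaplotypePairSet(cbind(c("A", "A", "B"), c("A", "B", "B")))
#' haplotypeGroups(groupHaplotypes(H, commonThreshold = 0.3))
#' @export
groupHaplotypes <- function(H, commonThreshold = 0.01) {
    stopifnot(is(H, "HaplotypePairSet"))
    freq <- H@haplotypeFreq
    if (length(freq) < 2L)
        stop("only one distinct haplotype observed; ",
             "the haplotype test is undefined for this region")
    common <- names(freq)[freq >= commonThreshold]
    rare <- setdiff(names(freq), common)
    if (length(common)) {
        groups <- c(lapply(sort(common), function(h) h),
                    if (length(rare)) list(sort(rare)))
        scheme <- "common-vs-pooled-rare"
    } else {
        # all haplotypes rare: three frequency bins on the sample
        # frequencies (sub-chromosome resolution at small n is accepted)
        message("no haplotype reaches the common threshold; ",
                "using the three-bin frequency fallback")
        bins <- list(names(freq)[freq < 5e-4],
                     names(freq)[freq >= 5e-4 & freq <= 1e-3],
                     names(freq)[freq > 1e-3])
        groups <- lapply(Filter(length, bins), sort)
        scheme <- "three-bin-fallback"
    }
    if (length(groups) < 2L)
        stop("fewer than two haplotype groups could be formed")
    gfreq <- vapply(groups, function(g) sum(freq[g]), numeric(1))
    minLab <- vapply(groups, function(g) min(g), character(1))
    ord <- order(gfreq, rank(minLab) * -1)  # reference last; ties by label
    groups <- groups[ord]
    gfreq <- gfreq[ord]
    new("HaplotypeGrouping", groups = groups,
        referenceIndex = length(groups), scheme = scheme, groupFreq = gfreq)
}

#' Build the haplotype regression matrix
#'
#' Entry (i, j) counts how many of individual i's two haplotypes belong to
#' group H_j, for j = 1..M-1; the reference group H_M (the most common) is
#' omitted, so each row sums to 2 minus the individual's count of reference
#' haplotypes.
#'
#' @param H a \linkS4class{HaplotypePairSet}.
#' @param grouping a \linkS4class{HaplotypeGrouping} covering every
#'   haplotype observed in \code{H}.
#' @return a \linkS4class{HaplotypeDesignMatrix}.
#' @export
buildHaplotypeMatrix <- function(H, grouping) {
    stopifnot(is(H, "HaplotypePairSet"), is(grouping, "HaplotypeGrouping"))
    groups <- grouping@groups
    M <- length(groups)
    map <- integer(0)
    for (j in seq_len(M))
        map[groups[[j]]] <- j
    ids <- unique(as.vector(H@pairs))
    missing <- ids[!ids %in% names(map)]
    if (length(missing))
        stop("haplotype(s) absent from the grouping: ",
             paste(utils::head(missing, 5), collapse = ", "))
    n <- nrow(H@pairs)
    g1 <- map[H@pairs[, 1]]
    g2 <- map[H@pairs[, 2]]
    R <- matrix(0L, n, M - 1L,
                dimnames = list(NULL, paste0("H", seq_len(M - 1L))))
    for (j in seq_len(M - 1L))
        R[, j] <- (g1 == j) + (g2 == j)
    new("HaplotypeDesignMatrix", matrix = R)
}
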