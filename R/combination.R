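.PEPS <- 1e-12

# clamp p-values strictly inside (0, 1); warn when clamping was needed
.clampP <- function(p, warn = TRUE) {
    out <- pmin(pmax(p, .PEPS), 1 - .PEPS)
    if (warn && any(p <= 0 | p >= 1, na.rm = TRUE))
        warning("p-value(s) at or outside (0, 1) clamped to [",
                .PEPS, ", 1 - ", .PEPS, "]")
    out
}

.clampRho <- function(rho) pmin(pmax(rho, -0.999), 0.999)

# internal quiet transform (rank-based permutation p-values legitimately
# reach 1 and are clamped without a warning)
.invNorm <- function(p) stats::qnorm(.clampP(p, warn = FALSE),
                                     lower.tail = FALSE)

#' Inverse standard normal transform of a p-value
#'
#' Returns y = Phi^{-1}(1 - p), so small p-values map to large positive
#' values; under a uniform null the transform is standard normal. Inputs at
#' or outside (0, 1) are clamped to [1e-12, 1 - 1e-12] with a warning.
#'
#' @param p p-value(s).
#' @return numeric transform(s).
#' @examples
#' inverseNormal(0.025)  # 1.959964
#' @export
inverseNormal <- function(p) {
    stats::qnorm(.clampP(p), lower.tail = FALSE)
}

#' Standard bivariate normal CDF
#'
#' P(Y1 <= q1, Y2 <= q2) for a standard bivariate normal with correlation
#' \code{rho}, evaluated by the TVPACK algorithm (absolute accuracy well
#' below 1e-7 in two dimensions).
#'
#' @param q1,q2 evaluation points.
#' @param rho correlation with |rho| <= 0.999.
#' @return the probability.
#' @examples
#' bivariateNormalCdf(0, 0, 0.5)  # 1/4 + asin(0.5) / (2*pi)
#' @export
bivariateNormalCdf <- function(q1, q2, rho) {
    stopifnot(abs(rho) <= 0.999)
    if (rho == 0) return(stats::pnorm(q1) * stats::pnorm(q2))
    corr <- matrix(c(1, rho, rho, 1), 2)
    as.numeric(mvtnorm::pmvnorm(upper = c(q1, q2), corr = corr,
                                algorithm = mvtnorm::TVPACK()))
}

# permutation estimates use the clamped copy; a directly supplied
# correlation may be exactly 1 (the degenerate case is rho = -1, where the
# SumP null variance vanishes)
.rhoValue <- function(rho) {
    if (is(rho, "CorrelationEstimate")) rho@clampedRho
    else pmin(pmax(rho, -0.999), 1)
}

#' SumP-val combined p-value
#'
#' The SumP-val statistic is y1 + y2, the sum of the inverse-normal
#' transforms of the two underlying p-values. Under the null it is normal
#' with mean zero and variance 2 + 2*rho, where rho is the correlation of
#' the transforms; the test rejects for large values.
#'
#' @param p1,p2 the genotype- and haplotype-test p-values.
#' @param rho a \linkS4class{CorrelationEstimate} or a plain correlation.
#' @return the combined p-value.
#' @examples
#' sumpPvalue(0.05, 0.05, rho = 0)  # about 0.0100
#' @export
sumpPvalue <- function(p1, p2, rho) {
    r <- .rhoValue(rho)
    s <- inverseNormal(p1) + inverseNormal(p2)
    stats::pnorm(s, mean = 0, sd = sqrt(2 + 2 * r), lower.tail = FALSE)
}

#' MinP-val combined p-value
#'
#' The MinP-val statistic is x = min(p1, p2), rejecting for small values.
#' With q = Phi^{-1}(1 - x), its null CDF under the correlated
#' bivariate-normal model is 1 - P(Y1 <= q, Y2 <= q; rho), which is the
#' reported p-value. At rho = 0 this reduces to 1 - (1 - x)^2, and as
#' rho -> 1 it tends to x itself.
#'
#' @inheritParams sumpPvalue
#' @return the combined p-value.
#' @examples
#' minpPvalue(0.05, 0.20, rho = 0)  # 1 - 0.95^2 = 0.0975
#' @export
minpPvalue <- function(p1, p2, rho) {
    r <- .rhoValue(rho)
    x <- min(.clampP(c(p1, p2)))
    if (r > 0.999) return(x)  # exact perfectly-correlated limit
    q <- stats::qnorm(1 - x)
    1 - bivariateNormalCdf(q, q, r)
}

#' Estimate the transform correlation from permutation replicates
#'
#' The correlation rho entering the combined-test null is estimated as the
#' Pearson correlation between the inverse-normal transforms of the two
#' tests' permutation p-values.
#'
#' @param p1,p2 equal-length vectors of permutation p-values for the
#'   genotype and haplotype tests (one entry per permutation replicate).
#' @return a \linkS4class{CorrelationEstimate}.
#' @export
estimateCorrelation <- function(p1, p2) {
    stopifnot(length(p1) == length(p2), length(p1) >= 2L)
    y1 <- .invNorm(p1)
    y2 <- .invNorm(p2)
    if (stats::sd(y1) == 0 || stats::sd(y2) == 0)
        stop("zero variance in a transformed permutation margin; ",
             "permutation statistics are degenerate")
    rho <- stats::cor(y1, y2)
    new("CorrelationEstimate", rho = rho,
        nPermutations = length(p1), clampedRho = .clampRho(rho))
}

#' Bivariate-normality gate for theoretical combined p-values
#'
#' The theoretical MinP/SumP p-values assume the transformed pair is
#' bivariate normal. The gate applies a Shapiro-Wilk test to each
#' transformed margin with a Bonferroni factor of 2 (a conservative proxy
#' for the multivariate test): when the minimum adjusted p-value is not
#' significant at the genome-wide level, theoretical p-values are used,
#' otherwise permutation p-values.
#'
#' @param y1,y2 transformed permutation pairs (at least 20 replicates).
#' @param alphaGenomewide genome-wide significance level for the gate.
#' @return list with \code{source} ("theoretical" or "permutation") and
#'   \code{pvalue} (the minimum Bonferroni-adjusted Shapiro-Wilk p-value).
#' @export
normalityGate <- function(y1, y2, alphaGenomewide = 1.38e-6) {
    stopifnot(length(y1) == length(y2), length(y1) >= 20L)
    p <- c(stats::shapiro.test(y1)$p.value,
           stats::shapiro.test(y2)$p.value)
    padj <- min(1, 2 * min(p))
    list(source = if (padj <= alphaGenomewide) "permutation" else
             "theoretical",
         pvalue = padj)
}

#' Bonferroni region-wise significance threshold
#'
#' @param nRegions number of regions tested genome-wide.
#' @param alpha family-wise error rate; default 0.05.
#' @return the per-region threshold alpha / nRegions.
#' @examples
#' bonferroniThreshold(36146)  # 1.38e-06
#' @export
bonferroniThreshold <- function(nRegions, alpha = 0.05) {
    alpha / nRegions
}

#' Assemble a combined-test result
#'
#' Computes both combined tests from a pair of underlying p-values and a
#' correlation estimate, either theoretically (correlated bivariate-normal
#' null) or from supplied permutation-replicate p-value pairs (empirical
#' add-one p-values of the observed statistics against the permuted
#' combined statistics).
#'
#' @param p1,p2 observed genotype- and haplotype-test p-values.
#' @param rho a \linkS4class{CorrelationEstimate} (or plain correlation).
#' @param source "theoretical" or "permutation".
#' @param permP1,permP2 per-replicate permutation p-values, required when
#'   \code{source = "permutation"}.
#' @param normalityPvalue optional gate p-value to record.
#' @return a \linkS4class{CombinedResult}.
#' @export
combineTests <- function(p1, p2, rho,
                         source = c("theoretical", "permutation"),
                         permP1 = NULL, permP2 = NULL,
                         normalityPvalue = NA_real_) {
    source <- match.arg(source)
    if (!is(rho, "CorrelationEstimate"))
        rho <- new("CorrelationEstimate", rho = as.numeric(rho),
                   nPermutations = 0L, clampedRho = .clampRho(rho))
    p1c <- .clampP(p1, warn = FALSE)
    p2c <- .clampP(p2, warn = FALSE)
    minpStat <- min(p1, p2)
    sumpStat <- .invNorm(p1c) + .invNorm(p2c)
    if (source == "theoretical") {
        minp <- minpPvalue(p1c, p2c, rho)
        sump <- sumpPvalue(p1c, p2c, rho)
    } else {
        if (is.null(permP1) || is.null(permP2))
            stop("permutation-source combined p-values need permP1/permP2")
        permMin <- pmin(permP1, permP2)
        permSum <- .invNorm(permP1) + .invNorm(permP2)
        # MinP rejects for small statistics, SumP for large ones
        minp <- empiricalPvalue(-minpStat, -permMin)
        sump <- empiricalPvalue(sumpStat, permSum)
    }
    new("CombinedResult", p1 = p1, p2 = p2, rho = rho,
        minpStat = minpStat, minpPvalue = minp,
        sumpStat = sumpStat, sumpPvalue = sump,
        pvalueSource = source, normalityPvalue = normalityPvalue)
}
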