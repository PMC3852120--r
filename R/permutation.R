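#' Create a permutation plan
#'
#' @param nPermutations number of permutation replicates; defaults follow
#'   common practice here: 500 for correlation estimation, 1000 for
#'   empirical p-values.
#' @param seed base integer seed; replicate r derives its own sub-seed from
#'   (seed, r), so identical plans give identical permutation sequences and
#'   any replicate can be regenerated in isolation.
#' @return a \linkS4class{PermutationPlan}.
#' @export
permutationPlan <- function(nPermutations = 500L, seed = 1L) {
    new("PermutationPlan", nPermutations = as.integer(nPermutations),
        seed = as.integer(seed))
}

# counter-based sub-seed for replicate r, kept below 2^31
.replicateSeed <- function(seed, r) {
    as.integer((as.numeric(seed) * 1103515245 + as.numeric(r) * 12345 +
                    20130821) %% 2147483647)
}

# evaluate expr under a temporary RNG state
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

# the permutation of replicate r as an index vector
.replicatePermutation <- function(plan, r, n) {
    .withSeed(.replicateSeed(plan@seed, r), sample.int(n))
}

# Y* = mu-hat + permuted residuals (response scale)
.applyPermutation <- function(fit, perm) {
    fit@fitted + fit@residuals[perm]
}

#' Permute residuals under the reduced model
#'
#' Generates one null phenotype replicate Y* = mu-hat + pi(eps-hat), where
#' pi is the uniformly random permutation determined by the plan's seed and
#' the replicate index. Permuting residuals rather than the raw phenotype
#' preserves the covariate structure while breaking the phenotype-genotype
#' link. For a binomial fit without covariates the fitted value is constant,
#' so the scheme coincides with plain phenotype permutation (which is exact
#' in that case); with covariates it is the same response-scale
#' approximation as the gaussian scheme.
#'
#' @param fit a \linkS4class{NullModelFit}.
#' @param plan a \linkS4class{PermutationPlan}.
#' @param replicateIndex which replicate to generate (1-based).
#' @return the permuted phenotype vector.
#' @export
permutePhenotype <- function(fit, plan, replicateIndex) {
    stopifnot(is(fit, "NullModelFit"), is(plan, "PermutationPlan"))
    perm <- .replicatePermutation(plan, replicateIndex, length(fit@y))
    .applyPermutation(fit, perm)
}

#' Run the permutation replicates for both SKAT tests
#'
#' For each replicate, the reduced-model fit is reused (no per-replicate
#' re-estimation): residuals are permuted and both SKAT statistics are
#' recomputed on the permuted phenotype. Per-replicate p-values are either
#' analytic (the chi-square-mixture tail of each statistic, used when the
#' combined p-values are theoretical) or rank-based within the replicate
#' set (used for fully empirical p-values).
#'
#' @param Xg genotype design matrix (or \linkS4class{CollapsedGenotypes}).
#' @param Xh haplotype design matrix (or
#'   \linkS4class{HaplotypeDesignMatrix}).
#' @param fit the \linkS4class{NullModelFit}.
#' @param plan a \linkS4class{PermutationPlan}.
#' @param pvalues "analytic" or "rank".
#' @return a \linkS4class{PermutationReplicates}.
#' @export
runPermutations <- function(Xg, Xh, fit, plan,
                            pvalues = c("analytic", "rank")) {
    pvalues <- match.arg(pvalues)
    if (is(Xg, "CollapsedGenotypes")) Xg <- designMatrix(Xg)
    if (is(Xh, "HaplotypeDesignMatrix")) Xh <- designMatrix(Xh)
    B <- plan@nPermutations
    n <- length(fit@y)
    if (B == 0L)
        return(new("PermutationReplicates",
                   statsGenotype = numeric(0), statsHaplotype = numeric(0),
                   pvalsGenotype = numeric(0), pvalsHaplotype = numeric(0)))
    perms <- vapply(seq_len(B),
                    function(r) .replicatePermutation(plan, r, n),
                    integer(n))
    E <- matrix(fit@residuals[perms], n, B)
    scale <- if (fit@family == "gaussian") 2 * fit@dispersion else 2
    sg <- colSums(crossprod(as.matrix(Xg), E)^2) / scale
    sh <- colSums(crossprod(as.matrix(Xh), E)^2) / scale
    if (any(!is.finite(sg)) || any(!is.finite(sh)))
        stop("non-finite permuted statistic at replicate ",
             which(!is.finite(sg) | !is.finite(sh))[1])
    if (pvalues == "analytic") {
        lg <- .kernelEigenvalues(as.matrix(Xg), fit)
        lh <- .kernelEigenvalues(as.matrix(Xh), fit)
        pg <- .mixtureTailFast(sg, lg)
        ph <- .mixtureTailFast(sh, lh)
    } else {
        # share of replicates with a statistic at least as large
        pg <- (B + 1 - rank(sg, ties.method = "min")) / B
        ph <- (B + 1 - rank(sh, ties.method = "min")) / B
    }
    new("PermutationReplicates", statsGenotype = sg, statsHaplotype = sh,
        pvalsGenotype = pg, pvalsHaplotype = ph)
}

# mixture weights of the null distribution of a SKAT statistic
.kernelEigenvalues <- function(X, fit) {
    K <- .projectedKernel(X, fit)
    lambda <- eigen(K, symmetric = TRUE, only.values = TRUE)$values / 2
    lambda[lambda > 1e-10 * max(lambda, 1e-300)]
}

#' Empirical permutation p-value
#'
#' The add-one convention p = (#\{replicates >= observed\} + 1) / (B + 1);
#' ties count toward rejection and the p-value can never be zero.
#'
#' @param observed the observed statistic (rejection for large values).
#' @param replicates vector of permutation-replicate statistics.
#' @return the empirical p-value.
#' @examples
#' empiricalPvalue(10, 1:999)  # 1/1000
#' @export
empiricalPvalue <- function(observed, replicates) {
    stopifnot(length(replicates) >= 1L)
    (sum(replicates >= observed) + 1) / (length(replicates) + 1)
}
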