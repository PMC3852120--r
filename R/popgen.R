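#' Generate a synthetic haplotype pool
#'
#' Builds a random Kingman-coalescent genealogy over the pool chromosomes
#' (exponential epoch times with rate k(k-1)/2 while k lineages remain) and
#' places one mutation per site on a branch chosen with probability
#' proportional to branch length; the site's derived allele is carried by
#' all chromosomes below that branch. This yields site frequencies close to
#' the neutral 1/x spectrum, a majority of rare sites, and realistic
#' linkage disequilibrium through the shared tree. Non-segregating sites
#' cannot arise (every branch subtends a proper subset of leaves) but are
#' guarded against anyway.
#'
#' This generator is a synthetic stand-in for demographically explicit
#' forward simulations: it targets the qualitative regime (roughly 30-38
#' segregating sites, rare-site majority) rather than any specific
#' demographic model.
#'
#' @param LTarget number of segregating sites; default 33.
#' @param poolSize number of chromosomes in the pool; default 40000.
#' @param seed RNG seed.
#' @return a \linkS4class{HaplotypePool}.
#' @export
generatePool <- function(LTarget = 33L, poolSize = 40000L, seed = 1L) {
    stopifnot(LTarget >= 5L, poolSize >= 4L)
    .withSeed(seed, .generatePoolImpl(as.integer(LTarget),
                                      as.integer(poolSize)))
}

.generatePoolImpl <- function(L, n) {
    nNodes <- 2L * n - 1L
    parent <- integer(nNodes)
    nodeTime <- numeric(nNodes)
    active <- seq_len(n)
    # epoch durations while k lineages remain, k = n..2
    ks <- n:2
    epochs <- cumsum(stats::rexp(n - 1L) / (ks * (ks - 1) / 2))
    # pre-drawn pair choices: i-th event picks 2 distinct of k = n-i+1
    u1 <- floor(stats::runif(n - 1L) * ks) + 1L
    u2 <- floor(stats::runif(n - 1L) * (ks - 1L)) + 1L
    u2 <- ifelse(u2 >= u1, u2 + 1L, u2)
    k <- n
    nextNode <- n + 1L
    for (i in seq_len(n - 1L)) {
        c1 <- active[u1[i]]; c2 <- active[u2[i]]
        parent[c1] <- nextNode
        parent[c2] <- nextNode
        nodeTime[nextNode] <- epochs[i]
        active[u1[i]] <- nextNode
        active[u2[i]] <- active[k]
        nextNode <- nextNode + 1L
        k <- k - 1L
    }
    root <- nNodes
    nonRoot <- seq_len(nNodes - 1L)
    branchLen <- nodeTime[parent[nonRoot]] - nodeTime[nonRoot]
    # children lists for subtree descent
    kids1 <- integer(nNodes); kids2 <- integer(nNodes)
    for (v in nonRoot) {
        p <- parent[v]
        if (kids1[p] == 0L) kids1[p] <- v else kids2[p] <- v
    }
    hap <- matrix(0L, n, L)
    mutNodes <- sample(nonRoot, L, replace = TRUE, prob = branchLen)
    for (s in seq_len(L)) {
        carriers <- .subtreeLeaves(mutNodes[s], kids1, kids2, n)
        while (length(carriers) == 0L || length(carriers) >= n) {
            # cannot occur on a proper branch, but guard anyway
            carriers <- .subtreeLeaves(sample(nonRoot, 1L,
                                              prob = branchLen),
                                       kids1, kids2, n)
        }
        hap[carriers, s] <- 1L
    }
    key <- do.call(paste0, lapply(seq_len(L), function(j) hap[, j]))
    tab <- table(key)
    distinct <- names(tab)
    hapMat <- do.call(rbind, lapply(strsplit(distinct, ""), as.integer))
    rownames(hapMat) <- distinct
    colnames(hapMat) <- paste0("site", seq_len(L))
    new("HaplotypePool", hapMatrix = hapMat,
        counts = as.integer(tab), siteFreqs = colMeans(hap),
        poolSize = n)
}

# leaves (chromosome indices) below a node, iteratively with a
# preallocated stack
.subtreeLeaves <- function(node, kids1, kids2, n) {
    if (node <= n) return(node)
    stack <- integer(n)
    stack[1L] <- node
    top <- 1L
    leaves <- integer(n)
    nl <- 0L
    while (top > 0L) {
        v <- stack[top]
        top <- top - 1L
        if (v <= n) {
            nl <- nl + 1L
            leaves[nl] <- v
        } else {
            stack[top + 1L] <- kids1[v]
            stack[top + 2L] <- kids2[v]
            top <- top + 2L
        }
    }
    leaves[seq_len(nl)]
}

# per-scenario odds ratios for causal rare and common items
.scenarioOddsRatios <- function(scenario) {
    switch(scenario,
           Rare = c(rare = 4, common = NA_real_),
           Both = c(rare = 3, common = 1.2),
           Common = c(rare = 1.5, common = 2),
           null = c(rare = NA_real_, common = NA_real_),
           stop("unknown scenario: ", scenario))
}

#' Select causal variants or haplotypes for a disease model
#'
#' Samples ceiling(proportion x #rare) of the rare items (pool frequency
#' below 1\%) uniformly as causal, plus one uniformly chosen common item
#' for the "Both" and "Common" scenarios. Odds ratios are fixed per
#' scenario: "Rare" 4 (no common causal), "Both" 3 and 1.2, "Common" 1.5
#' and 2. The scenario "null" selects nothing (type-I-error simulations).
#'
#' @param pool a \linkS4class{HaplotypePool}.
#' @param basis "genotype" (causal SNPs) or "haplotype" (causal
#'   haplotypes).
#' @param scenario "Rare", "Both", "Common" or "null".
#' @param proportion fraction of rare items made causal (0.5, 0.2 or 0.1
#'   in the study design).
#' @param seed RNG seed.
#' @param rareThreshold pool-frequency rarity threshold; default 0.01.
#' @return a \linkS4class{DiseaseModel}.
#' @export
selectCausal <- function(pool, basis = c("genotype", "haplotype"),
                         scenario = c("Rare", "Both", "Common", "null"),
                         proportion = 0.5, seed = 1L,
                         rareThreshold = 0.01) {
    basis <- match.arg(basis)
    scenario <- match.arg(scenario)
    or <- .scenarioOddsRatios(scenario)
    if (scenario == "null")
        return(new("DiseaseModel", basis = basis, scenario = scenario,
                   causalRare = integer(0), causalCommon = integer(0),
                   orRare = NA_real_, orCommon = NA_real_,
                   prevalence = 0.01))
    .withSeed(seed, {
        if (basis == "genotype") {
            f <- pmin(pool@siteFreqs, 1 - pool@siteFreqs)
            rare <- which(f < rareThreshold)
            common <- which(f >= rareThreshold)
        } else {
            f <- pool@counts / pool@poolSize
            rare <- rownames(pool@hapMatrix)[f < rareThreshold]
            common <- rownames(pool@hapMatrix)[f >= rareThreshold]
        }
        if (length(rare) < 1L)
            stop("pool has no rare ", basis, " item to make causal")
        nCausal <- ceiling(proportion * length(rare))
        causalRare <- sort(sample(rare, nCausal))
        causalCommon <- if (scenario %in% c("Both", "Common")) {
            if (length(common) < 1L)
                stop("scenario ", scenario, " needs a common causal ",
                     basis, " item, but the pool has none")
            sample(common, 1L)
        } else if (basis == "genotype") integer(0) else character(0)
        new("DiseaseModel", basis = basis, scenario = scenario,
            causalRare = causalRare, causalCommon = causalCommon,
            orRare = unname(or["rare"]), orCommon = unname(or["common"]),
            prevalence = 0.01)
    })
}

#' Disease probability under the genotype-based model
#'
#' logit P(A) = logit(prevalence) + sum over causal rare variants of
#' g_l log(OR_rare) + g_common log(OR_common) when a common causal variant
#' is present; non-causal variants contribute nothing.
#'
#' @param g dosage vector over the region's sites (derived-allele counts),
#'   or a matrix with one row per individual.
#' @param model a \linkS4class{DiseaseModel} with genotype basis.
#' @return disease probability (vector for matrix input).
#' @examples
#' # one causal rare allele at OR 4: odds (0.01/0.99)*4
#' @export
diseaseProbabilityGenotype <- function(g, model) {
    stopifnot(is(model, "DiseaseModel"), model@basis == "genotype")
    if (!is.matrix(g)) g <- matrix(g, nrow = 1)
    eta <- stats::qlogis(model@prevalence)
    if (length(model@causalRare))
        eta <- eta + rowSums(g[, model@causalRare, drop = FALSE]) *
            log(model@orRare)
    if (length(model@causalCommon))
        eta <- eta + g[, model@causalCommon] * log(model@orCommon)
    stats::plogis(eta)
}

#' Disease probability under the haplotype-based model
#'
#' logit P(A) = logit(prevalence) + sum over the individual's two
#' haplotypes of 1\{h in H_r\} log(d_r) + 1\{h in H_c\} log(d_c).
#'
#' @param h1,h2 haplotype identifier(s); vectors give one probability per
#'   individual.
#' @param model a \linkS4class{DiseaseModel} with haplotype basis.
#' @return disease probability (vectorised).
#' @export
diseaseProbabilityHaplotype <- function(h1, h2, model) {
    stopifnot(is(model, "DiseaseModel"), model@basis == "haplotype")
    eta <- stats::qlogis(model@prevalence)
    if (length(model@causalRare))
        eta <- eta + ((h1 %in% model@causalRare) +
                      (h2 %in% model@causalRare)) * log(model@orRare)
    if (length(model@causalCommon))
        eta <- eta + ((h1 %in% model@causalCommon) +
                      (h2 %in% model@causalCommon)) * log(model@orCommon)
    stats::plogis(eta)
}

#' Sample a case-control replicate from a pool
#'
#' Repeatedly draws two haplotypes with replacement proportional to pool
#' counts (defining an individual's genotype as their element-wise sum),
#' assigns a Bernoulli phenotype with the model's disease probability, and
#' keeps individuals until both the case and the control quota are filled.
#' Cases are stored first.
#'
#' @param pool a \linkS4class{HaplotypePool}.
#' @param model a \linkS4class{DiseaseModel} (scenario "null" gives
#'   constant disease probability equal to the prevalence).
#' @param nCases,nControls quotas; default 500 each.
#' @param seed RNG seed.
#' @param maxDraws abort threshold on total individuals drawn.
#' @return a \linkS4class{CaseControlSample}.
#' @export
sampleCaseControl <- function(pool, model, nCases = 500L,
                              nControls = 500L, seed = 1L,
                              maxDraws = 1e8) {
    stopifnot(is(pool, "HaplotypePool"), is(model, "DiseaseModel"))
    .withSeed(seed, .sampleCaseControlImpl(pool, model, as.integer(nCases),
                                           as.integer(nControls), maxDraws))
}

.sampleCaseControlImpl <- function(pool, model, nCases, nControls,
                                   maxDraws) {
    ids <- rownames(pool@hapMatrix)
    prob <- pool@counts / pool@poolSize
    caseG <- list(); caseH <- list()
    ctrlG <- list(); ctrlH <- list()
    gotCase <- 0L; gotCtrl <- 0L
    drawn <- 0
    # expected yield ~1% cases: size batches accordingly
    batch <- max(2000L, 110L * nCases)
    while (gotCase < nCases || gotCtrl < nControls) {
        if (drawn >= maxDraws)
            stop("case/control quota unreachable after ", drawn,
                 " draws (", gotCase, " cases, ", gotCtrl,
                 " controls found); the disease model is pathological")
        i1 <- sample.int(length(ids), batch, replace = TRUE, prob = prob)
        i2 <- sample.int(length(ids), batch, replace = TRUE, prob = prob)
        drawn <- drawn + batch
        G <- pool@hapMatrix[i1, , drop = FALSE] +
            pool@hapMatrix[i2, , drop = FALSE]
        pA <- if (model@scenario == "null") {
            rep(model@prevalence, batch)
        } else if (model@basis == "genotype") {
            diseaseProbabilityGenotype(G, model)
        } else {
            diseaseProbabilityHaplotype(ids[i1], ids[i2], model)
        }
        pheno <- stats::rbinom(batch, 1L, pA)
        needCase <- which(pheno == 1L)[seq_len(
            min(nCases - gotCase, sum(pheno == 1L)))]
        needCtrl <- which(pheno == 0L)[seq_len(
            min(nControls - gotCtrl, sum(pheno == 0L)))]
        if (length(needCase)) {
            caseG[[length(caseG) + 1L]] <- G[needCase, , drop = FALSE]
            caseH[[length(caseH) + 1L]] <- cbind(ids[i1[needCase]],
                                                 ids[i2[needCase]])
            gotCase <- gotCase + length(needCase)
        }
        if (length(needCtrl)) {
            ctrlG[[length(ctrlG) + 1L]] <- G[needCtrl, , drop = FALSE]
            ctrlH[[length(ctrlH) + 1L]] <- cbind(ids[i1[needCtrl]],
                                                 ids[i2[needCtrl]])
            gotCtrl <- gotCtrl + length(needCtrl)
        }
    }
    G <- rbind(do.call(rbind, caseG), do.call(rbind, ctrlG))
    rownames(G) <- NULL
    H <- rbind(do.call(rbind, caseH), do.call(rbind, ctrlH))
    pheno <- c(rep(1, nCases), rep(0, nControls))
    new("CaseControlSample",
        genotypes = RegionGenotypes(G, colnames(pool@hapMatrix)),
        haplotypePairs = HaplotypePairSet(H),
        phenotype = pheno, nCases = nCases, nControls = nControls)
}

#' Run a power / type-I-error study over simulated replicates
#'
#' For each configured scenario, draws replicate case-control datasets from
#' fresh (or partially reused) haplotype pools, applies the four tests
#' (genotype SKAT, haplotype SKAT, MinP-val, SumP-val) with
#' permutation-based p-values, and reports each test's rejection share at
#' the chosen level. For the "null" scenario the share is the empirical
#' type-I error; the binomial one-sided 99\% bound for B replicates at the
#' nominal level is included for calibration checks (0.067 at 1000
#' replicates and level 0.05).
#'
#' @param scenarios data.frame with columns basis ("genotype"/"haplotype")
#'   and scenario ("Rare"/"Both"/"Common"/"null"); a "null" row may use
#'   either basis.
#' @param proportion fraction of rare items causal.
#' @param nReplicates replicate datasets per scenario.
#' @param nPermutations permutations for the empirical p-values.
#' @param alpha rejection level; default 0.05.
#' @param nCases,nControls per-replicate quotas; default 500 each.
#' @param LTarget,poolSize pool dimensions.
#' @param replicatesPerPool how many replicates share one generated pool
#'   (1 = a fresh pool per replicate).
#' @param seed base seed.
#' @return data.frame with one row per scenario: rejection shares of the
#'   four tests, the replicate count, and the 99\% binomial bound. The
#'   per-replicate p-value matrices are attached as the \code{"pvalues"}
#'   attribute (a list, one nReplicates x 4 matrix per scenario row).
#' @export
runPowerStudy <- function(scenarios, proportion = 0.5,
                          nReplicates = 100L, nPermutations = 200L,
                          alpha = 0.05, nCases = 500L, nControls = 500L,
                          LTarget = 33L, poolSize = 40000L,
                          replicatesPerPool = 1L, seed = 1L) {
    stopifnot(all(c("basis", "scenario") %in% names(scenarios)))
    bound <- stats::qbinom(0.99, nReplicates, alpha) / nReplicates
    out <- lapply(seq_len(nrow(scenarios)), function(si) {
        basis <- as.character(scenarios$basis[si])
        scen <- as.character(scenarios$scenario[si])
        pv <- matrix(NA_real_, nReplicates, 4,
                     dimnames = list(NULL, c("genotype_skat",
                         "haplotype_skat", "minp", "sump")))
        pool <- NULL
        for (r in seq_len(nReplicates)) {
            rseed <- .replicateSeed(seed, (si - 1L) * nReplicates + r)
            if (is.null(pool) || (r - 1L) %% replicatesPerPool == 0L)
                pool <- generatePool(LTarget, poolSize, seed = rseed)
            model <- selectCausal(pool, basis, scen, proportion,
                                  seed = rseed)
            cc <- sampleCaseControl(pool, model, nCases, nControls,
                                    seed = rseed + 1L)
            pv[r, ] <- .fourTestPvalues(cc, nPermutations, seed = rseed + 2L)
        }
        rej <- pv < alpha
        summary <- data.frame(basis = basis, scenario = scen,
                   proportion = proportion, n_replicates = nReplicates,
                   n_permutations = nPermutations, alpha = alpha,
                   power_genotype_skat = mean(rej[, 1]),
                   power_haplotype_skat = mean(rej[, 2]),
                   power_minp = mean(rej[, 3]),
                   power_sump = mean(rej[, 4]),
                   binomial_bound_99 = bound)
        list(summary = summary, pvalues = pv)
    })
    res <- do.call(rbind, lapply(out, `[[`, "summary"))
    attr(res, "pvalues") <- lapply(out, `[[`, "pvalues")
    res
}

# the four tests on one replicate, fully permutation-based p-values
.fourTestPvalues <- function(cc, nPermutations, seed,
                             mafThreshold = 0.01, hapThreshold = 0.01) {
    Xg <- designMatrix(collapseRareVariants(cc@genotypes, mafThreshold))
    grouping <- suppressMessages(
        groupHaplotypes(cc@haplotypePairs, hapThreshold))
    Xh <- designMatrix(buildHaplotypeMatrix(cc@haplotypePairs, grouping))
    fit <- fitNullModel(cc@phenotype, family = "binomial")
    scale <- 2
    qg <- as.numeric(crossprod(crossprod(Xg, fit@residuals))) / scale
    qh <- as.numeric(crossprod(crossprod(Xh, fit@residuals))) / scale
    plan <- permutationPlan(nPermutations, seed)
    reps <- runPermutations(Xg, Xh, fit, plan, pvalues = "rank")
    p1 <- empiricalPvalue(qg, reps@statsGenotype)
    p2 <- empiricalPvalue(qh, reps@statsHaplotype)
    rho <- estimateCorrelation(reps@pvalsGenotype, reps@pvalsHaplotype)
    comb <- combineTests(p1, p2, rho, source = "permutation",
                         permP1 = reps@pvalsGenotype,
                         permP2 = reps@pvalsHaplotype)
    c(genotype_skat = p1, haplotype_skat = p2,
      minp = comb@minpPvalue, sump = comb@sumpPvalue)
}
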