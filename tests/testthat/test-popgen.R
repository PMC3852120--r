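test_that("generated pools conserve chromosomes, segregate every site
           and are seed-deterministic", {
    pool <- generatePool(20, 2000, seed = 1)
    expect_equal(sum(pool@counts), 2000L)
    expect_equal(ncol(pool@hapMatrix), 20L)
    expect_true(all(pool@siteFreqs > 0 & pool@siteFreqs < 1))
    pool2 <- generatePool(20, 2000, seed = 1)
    expect_identical(pool@hapMatrix, pool2@hapMatrix)
    expect_identical(pool@counts, pool2@counts)
    expect_false(identical(pool@siteFreqs,
                           generatePool(20, 2000, seed = 2)@siteFreqs))
})

test_that("pools carry a majority of rare sites at the default pool
           size", {
    # neutral-SFS expectation at 40000 chromosomes: well over half the
    # sites below 1% minor frequency on average
    fr <- vapply(1:25, function(s) {
        p <- generatePool(33, 40000, seed = 400 + s)
        mean(pmin(p@siteFreqs, 1 - p@siteFreqs) < 0.01)
    }, numeric(1))
    expect_gt(mean(fr), 0.5)
})

test_that("causal selection follows the scenario odds-ratio table and
           the ceiling rule", {
    pool <- generatePool(25, 4000, seed = 3)
    rare <- sum(pmin(pool@siteFreqs, 1 - pool@siteFreqs) < 0.01)
    m <- selectCausal(pool, "genotype", "Rare", 0.5, seed = 4)
    expect_equal(m@orRare, 4)
    expect_length(m@causalCommon, 0)
    expect_length(m@causalRare, ceiling(0.5 * rare))
    m <- selectCausal(pool, "genotype", "Both", 0.2, seed = 5)
    expect_equal(c(m@orRare, m@orCommon), c(3, 1.2))
    expect_length(m@causalCommon, 1)
    m <- selectCausal(pool, "genotype", "Common", 0.1, seed = 6)
    expect_equal(c(m@orRare, m@orCommon), c(1.5, 2))
    mh <- selectCausal(pool, "haplotype", "Rare", 0.5, seed = 7)
    expect_true(all(mh@causalRare %in% rownames(pool@hapMatrix)))
})

test_that("a pool without common items rejects scenarios that need
           one", {
    pool <- generatePool(25, 4000, seed = 3)
    # force every site rare by shrinking the frequency vector copy
    poolRare <- pool
    poolRare@siteFreqs <- rep(1 / 4000, 25)
    expect_error(selectCausal(poolRare, "genotype", "Common", 0.5,
                              seed = 1), "Common")
})

test_that("genotype disease probabilities follow the logistic model
           arithmetic", {
    pool <- generatePool(20, 4000, seed = 8)
    m <- selectCausal(pool, "genotype", "Rare", 0.5, seed = 9)
    g0 <- rep(0, 20)
    expect_equal(diseaseProbabilityGenotype(g0, m), 0.01)
    g1 <- g0; g1[m@causalRare[1]] <- 1
    expect_equal(diseaseProbabilityGenotype(g1, m),
                 0.0404040 / 1.0404040, tolerance = 1e-6)
    # dosage 2 at one causal site equals two separate dosage-1 sites
    g2 <- g0; g2[m@causalRare[1]] <- 2
    g11 <- g0; g11[m@causalRare[1:2]] <- 1
    expect_equal(diseaseProbabilityGenotype(g2, m),
                 diseaseProbabilityGenotype(g11, m))
})

test_that("haplotype disease probabilities follow the indicator
           arithmetic", {
    pool <- generatePool(20, 4000, seed = 10)
    ids <- rownames(pool@hapMatrix)
    m <- new("DiseaseModel", basis = "haplotype", scenario = "Both",
             causalRare = ids[1], causalCommon = ids[2],
             orRare = 4, orCommon = 1.2, prevalence = 0.01)
    expect_equal(diseaseProbabilityHaplotype(ids[3], ids[4], m), 0.01)
    odds <- 0.01 / 0.99 * 16
    expect_equal(diseaseProbabilityHaplotype(ids[1], ids[1], m),
                 odds / (1 + odds), tolerance = 1e-7)
    m2 <- new("DiseaseModel", basis = "haplotype", scenario = "Both",
              causalRare = ids[1], causalCommon = ids[2],
              orRare = 3, orCommon = 1.2, prevalence = 0.01)
    odds2 <- 0.01 / 0.99 * 3.6
    expect_equal(diseaseProbabilityHaplotype(ids[1], ids[2], m2),
                 odds2 / (1 + odds2), tolerance = 1e-7)
})

test_that("both disease models agree with a literal log-odds oracle on
           random configurations", {
    oracleG <- function(g, causal, orR, commonIdx, orC, prev) {
        lo <- log(prev / (1 - prev))
        for (l in causal) lo <- lo + g[l] * log(orR)
        if (length(commonIdx)) lo <- lo + g[commonIdx] * log(orC)
        1 / (1 + exp(-lo))
    }
    pool <- generatePool(20, 4000, seed = 11)
    withr::with_seed(12, {
        for (i in 1:1000) {
            causal <- sample(20, sample(1:5, 1))
            commonIdx <- if (runif(1) < 0.5) sample(setdiff(1:20, causal),
                                                    1) else integer(0)
            m <- new("DiseaseModel", basis = "genotype",
                     scenario = if (length(commonIdx)) "Both" else "Rare",
                     causalRare = causal, causalCommon = commonIdx,
                     orRare = sample(c(1.5, 3, 4), 1),
                     orCommon = if (length(commonIdx)) 1.2 else NA_real_,
                     prevalence = 0.01)
            g <- rbinom(20, 2, 0.3)
            expect_equal(diseaseProbabilityGenotype(g, m),
                         oracleG(g, causal, m@orRare, commonIdx,
                                 m@orCommon, 0.01),
                         tolerance = 1e-12)
        }
    })
})

test_that("case-control sampling fills exact quotas with genotypes equal
           to the haplotype sums", {
    pool <- generatePool(20, 4000, seed = 13)
    m <- selectCausal(pool, "genotype", "Both", 0.5, seed = 14)
    cc <- sampleCaseControl(pool, m, 120, 80, seed = 15)
    expect_equal(cc@nCases, 120L)
    expect_equal(sum(cc@phenotype), 120)
    expect_equal(length(cc@phenotype), 200L)
    # cases stored first
    expect_equal(cc@phenotype, c(rep(1, 120), rep(0, 80)))
    h <- haplotypePairs(cc@haplotypePairs)
    splitBits <- function(x) do.call(rbind, lapply(strsplit(x, ""),
                                                   as.integer))
    expect_equal(unname(dosages(cc@genotypes)),
                 unname(splitBits(h[, 1]) + splitBits(h[, 2])))
    # determinism
    cc2 <- sampleCaseControl(pool, m, 120, 80, seed = 15)
    expect_identical(dosages(cc@genotypes), dosages(cc2@genotypes))
})

test_that("under the null, cases and controls are exchangeable", {
    pool <- generatePool(20, 4000, seed = 16)
    m <- selectCausal(pool, scenario = "null")
    diffs <- vapply(1:30, function(s) {
        cc <- sampleCaseControl(pool, m, 100, 100, seed = 600 + s)
        d <- dosages(cc@genotypes)
        mean(colMeans(d[cc@phenotype == 1, , drop = FALSE]) -
             colMeans(d[cc@phenotype == 0, , drop = FALSE]))
    }, numeric(1))
    expect_lt(abs(mean(diffs)), 0.01)
})

test_that("the Rare genotype model enriches causal carriers among
           cases", {
    higher <- vapply(1:60, function(s) {
        pool <- generatePool(20, 4000, seed = 700 + s)
        m <- selectCausal(pool, "genotype", "Rare", 0.5, seed = 800 + s)
        cc <- sampleCaseControl(pool, m, 100, 100, seed = 900 + s)
        d <- dosages(cc@genotypes)[, m@causalRare, drop = FALSE]
        carriers <- rowSums(d) > 0
        mean(carriers[cc@phenotype == 1]) >=
            mean(carriers[cc@phenotype == 0])
    }, logical(1))
    expect_gte(mean(higher), 0.95)
})

test_that("the power study table is deterministic and detects a Common
           genotype signal", {
    scen <- data.frame(basis = c("genotype", "genotype"),
                       scenario = c("null", "Common"))
    out <- runPowerStudy(scen, proportion = 0.5, nReplicates = 20L,
                         nPermutations = 100L, nCases = 100L,
                         nControls = 100L, LTarget = 20L,
                         poolSize = 4000L, replicatesPerPool = 5L,
                         seed = 31L)
    out2 <- runPowerStudy(scen, proportion = 0.5, nReplicates = 20L,
                          nPermutations = 100L, nCases = 100L,
                          nControls = 100L, LTarget = 20L,
                          poolSize = 4000L, replicatesPerPool = 5L,
                          seed = 31L)
    expect_identical(out$power_minp, out2$power_minp)
    expect_identical(attr(out, "pvalues"), attr(out2, "pvalues"))
    expect_equal(nrow(out), 2L)
    pv <- attr(out, "pvalues")[[2]]
    expect_true(all(pv > 0 & pv <= 1))
    # the Common-scenario genotype test should see far smaller p-values
    expect_lt(median(pv[, "genotype_skat"]),
              median(attr(out, "pvalues")[[1]][, "genotype_skat"]))
})
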