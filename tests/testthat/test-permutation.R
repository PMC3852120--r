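test_that("the identity permutation reconstructs the phenotype exactly",
{
    withr::with_seed(1, {
        y <- rnorm(40)
        C <- cbind(age = rnorm(40))
    })
    fit <- fitNullModel(y, C)
    expect_equal(combSKAT:::.applyPermutation(fit, seq_len(40)), y)
})

test_that("permuted phenotypes preserve the mean and the covariate
           structure", {
    withr::with_seed(2, {
        C <- cbind(age = rnorm(50))
        y <- 3 + 0.8 * C[, 1] + rnorm(50)
    })
    fit <- fitNullModel(y, C)
    plan <- permutationPlan(200, seed = 3)
    corFit <- cor(fit@fitted, C[, 1])
    cors <- vapply(1:200, function(r) {
        ystar <- permutePhenotype(fit, plan, r)
        expect_equal(mean(ystar), mean(y))
        cor(ystar, C[, 1])
    }, numeric(1))
    # permuted replicates keep the fitted covariate signal, up to the
    # noise contributed by the shuffled residuals
    resNoise <- sd(fit@residuals) / sd(y)
    expect_lt(abs(mean(cors) - cor(y, C[, 1])), 0.2)
    expect_gt(mean(cors), corFit * sd(fit@fitted) / sd(y) - 3 * resNoise /
                  sqrt(50))
})

test_that("permutation streams are deterministic and replicable in
           isolation", {
    fit <- fitNullModel(withr::with_seed(4, rnorm(30)))
    plan <- permutationPlan(25, seed = 9)
    X1 <- matrix(withr::with_seed(5, rbinom(60, 2, 0.3)), 30)
    r1 <- runPermutations(X1, X1, fit, plan)
    r2 <- runPermutations(X1, X1, fit, plan)
    expect_identical(r1@statsGenotype, r2@statsGenotype)
    expect_identical(r1@pvalsHaplotype, r2@pvalsHaplotype)
    # replicate 7 in isolation matches its slot in the stream
    y7 <- permutePhenotype(fit, plan, 7)
    e7 <- y7 - fit@fitted
    q7 <- sum(crossprod(X1, e7)^2) / (2 * fit@dispersion)
    expect_equal(q7, r1@statsGenotype[7])
})

test_that("an empty plan yields empty replicate containers", {
    fit <- fitNullModel(withr::with_seed(6, rnorm(20)))
    X <- matrix(1:20, 20)
    r <- runPermutations(X, X, fit, permutationPlan(0, 1))
    expect_length(r@statsGenotype, 0)
    expect_length(r@pvalsHaplotype, 0)
})

test_that("empirical p-values follow the add-one rank arithmetic", {
    expect_equal(empiricalPvalue(1000, 1:999), 1 / 1000)
    expect_equal(empiricalPvalue(5, rep(5, 200)), 1)
    reps <- withr::with_seed(7, sample(seq(0.001, 0.999, length.out = 999)))
    expect_equal(empiricalPvalue(median(reps), reps), 501 / 1000)
})

test_that("rank-based replicate p-values are the within-stream
           exceedance shares", {
    fit <- fitNullModel(withr::with_seed(8, rnorm(40)))
    X <- matrix(withr::with_seed(9, rbinom(80, 2, 0.3)), 40)
    r <- runPermutations(X, X, fit, permutationPlan(100, seed = 10),
                         pvalues = "rank")
    manual <- vapply(r@statsGenotype,
                     function(s) mean(r@statsGenotype >= s), numeric(1))
    expect_equal(r@pvalsGenotype, manual)
    expect_true(all(r@pvalsGenotype > 0 & r@pvalsGenotype <= 1))
})

test_that("the double-permutation empirical p-value is calibrated under
           the null", {
    # outer repetitions of: null data -> statistic -> 200-permutation
    # empirical p; the resulting p-values must be near-uniform
    pv <- vapply(1:400, function(s) {
        withr::with_seed(s + 4000, {
            X <- matrix(rbinom(120, 2, 0.3), 60)
            y <- rnorm(60)
        })
        fit <- fitNullModel(y)
        q <- sum(crossprod(X, fit@residuals)^2) / (2 * fit@dispersion)
        r <- runPermutations(X, X, fit, permutationPlan(200, seed = s))
        empiricalPvalue(q, r@statsGenotype)
    }, numeric(1))
    ks <- suppressWarnings(ks.test(pv, "punif"))
    expect_gt(ks$p.value, 0.01)
    expect_lt(abs(mean(pv < 0.05) - 0.05), 0.035)
})

test_that("correlation estimates are stable across independent
           permutation streams", {
    cc <- makeReplicate(seed = 301, scenario = "Common", n = 300)
    Xg <- designMatrix(collapseRareVariants(cc@genotypes))
    grouping <- suppressMessages(groupHaplotypes(cc@haplotypePairs))
    Xh <- designMatrix(buildHaplotypeMatrix(cc@haplotypePairs, grouping))
    fit <- fitNullModel(cc@phenotype, family = "binomial")
    est <- vapply(c(21, 22), function(s) {
        r <- runPermutations(Xg, Xh, fit, permutationPlan(500, seed = s))
        estimateCorrelation(r@pvalsGenotype, r@pvalsHaplotype)@rho
    }, numeric(1))
    bound <- 3 * (1 - mean(est)^2) / sqrt(500)
    expect_lt(abs(est[1] - est[2]), max(bound, 0.05))
})

test_that("the full theoretical-branch pipeline keeps its nominal size
           on gaussian nulls", {
    # null replicates drawn from one pool; gaussian trait independent of
    # genotype; MinP/SumP with theoretical p-values at rho-hat
    pool <- generatePool(20, 4000, seed = 55)
    model <- selectCausal(pool, scenario = "null")
    nSim <- 1000
    rej <- matrix(FALSE, nSim, 4)
    for (s in seq_len(nSim)) {
        cc <- sampleCaseControl(pool, model, 100, 100, seed = 7000 + s)
        y <- withr::with_seed(17000 + s, rnorm(200))
        r <- suppressMessages(combinedRegionTest(
            cc@genotypes, cc@haplotypePairs, y, family = "gaussian",
            permsRho = 100L, pvalueSource = "theoretical",
            seed = 27000 + s))
        rej[s, ] <- combinedPvalues(r) < 0.05
    }
    alphaHat <- colMeans(rej)
    expect_true(all(alphaHat <= 0.067))
    expect_true(all(alphaHat >= qbinom(0.005, nSim, 0.05) / nSim))
})
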