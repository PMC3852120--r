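test_that("inverse normal transform hits reference quantiles and
           round-trips", {
    expect_equal(inverseNormal(0.5), 0)
    expect_equal(inverseNormal(0.025), 1.959964, tolerance = 1e-6)
    for (p in c(1e-6, 1e-3, 0.1, 0.5, 0.9, 0.999))
        expect_lt(abs(1 - pnorm(inverseNormal(p)) - p), 1e-10)
    expect_warning(y <- inverseNormal(0), "clamped")
    expect_true(is.finite(y))
})

test_that("bivariate normal CDF matches product and arcsine closed
           forms", {
    expect_equal(bivariateNormalCdf(0, 0, 0), 0.25)
    expect_equal(bivariateNormalCdf(0, 0, 0.5),
                 1 / 4 + asin(0.5) / (2 * pi), tolerance = 1e-9)
    for (q in list(c(1.2, -0.7), c(0, 2), c(-1, -1)))
        expect_lt(abs(bivariateNormalCdf(q[1], q[2], 0) -
                      pnorm(q[1]) * pnorm(q[2])), 1e-10)
})

test_that("SumP-val p-value has its closed-form anchor points", {
    expect_equal(sumpPvalue(0.5, 0.5, 0.7), 0.5)
    expect_equal(sumpPvalue(0.05, 0.05, 0),
                 pnorm(2 * qnorm(0.95) / sqrt(2), lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(round(sumpPvalue(0.05, 0.05, 0), 4), 0.0100)
    # perfectly correlated margins: the sum is z-equivalent to either one
    for (p in c(0.01, 0.2, 0.8))
        expect_equal(sumpPvalue(p, p, 1), p, tolerance = 1e-6)
})

test_that("MinP-val p-value interpolates between independence and
           perfect correlation", {
    expect_equal(minpPvalue(0.05, 0.3, 0), 1 - 0.95^2, tolerance = 1e-9)
    expect_equal(minpPvalue(0.05, 0.3, 1), 0.05)
    expect_lt(abs(minpPvalue(0.05, 0.3, 0.99) - 0.05), 1e-2)
    # bounds x <= p <= 2x - x^2 and monotone non-increasing in rho
    for (x in c(0.01, 0.05, 0.2)) {
        prev <- Inf
        for (rho in c(0, 0.3, 0.6, 0.9)) {
            p <- minpPvalue(x, 0.9, rho)
            expect_gte(p, x - 1e-12)
            expect_lte(p, 2 * x - x^2 + 1e-12)
            expect_lte(p, prev + 1e-12)
            prev <- p
        }
    }
})

test_that("combined p-values match Monte-Carlo oracles on an (x, rho)
           grid", {
    nmc <- 1e6
    for (rho in c(0, 0.5, 0.9)) {
        y <- withr::with_seed(11, {
            z1 <- rnorm(nmc); z2 <- rnorm(nmc)
            cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2)
        })
        for (x in c(0.01, 0.05, 0.2)) {
            q <- qnorm(1 - x)
            mc <- mean(pmax(y[, 1], y[, 2]) > q)
            se <- sqrt(mc * (1 - mc) / nmc)
            expect_lt(abs(minpPvalue(x, 0.9999, rho) - mc),
                      max(3 * se, 1e-4))
        }
        # SumP at p1 = p2 = 0.05
        s <- qnorm(0.95) * 2
        mc <- mean(y[, 1] + y[, 2] > s)
        se <- sqrt(mc * (1 - mc) / nmc)
        expect_lt(abs(sumpPvalue(0.05, 0.05, rho) - mc),
                  max(3 * se, 1e-4))
    }
})

test_that("sump p-value is monotone increasing in each margin", {
    for (rho in c(0, 0.5)) {
        ps <- vapply(c(0.01, 0.05, 0.2, 0.5, 0.9),
                     function(p) sumpPvalue(p, 0.3, rho), numeric(1))
        expect_true(all(diff(ps) > 0))
    }
})

test_that("theoretical combined p-values are uniform under a correlated
           bivariate-normal null", {
    n <- 50000
    for (rho in c(0, 0.6, 0.9)) {
        y <- withr::with_seed(round(100 * rho) + 13, {
            z1 <- rnorm(n); z2 <- rnorm(n)
            cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2)
        })
        p1 <- 1 - pnorm(y[, 1])
        p2 <- 1 - pnorm(y[, 2])
        # vectorised minp p-value through the critical-curve identity
        pv <- vapply(seq(50), function(i)
            minpPvalue(p1[i], p2[i], rho), numeric(1))
        # spot values lie in (0,1); full-vector KS on the sump p-values
        expect_true(all(pv > 0 & pv <= 1))
        sump <- pnorm(qnorm(1 - p1) + qnorm(1 - p2), 0,
                      sqrt(2 + 2 * rho), lower.tail = FALSE)
        ks <- suppressWarnings(ks.test(sump, "punif"))
        expect_gt(ks$p.value, 0.01)
        # minp uniformity via the monotone statistic transform:
        # P(min p < x_c(u)) = u for each u on a grid
        for (u in c(0.01, 0.05, 0.1, 0.5)) {
            xc <- combSKAT:::.minpCritical(u, rho)
            emp <- mean(pmin(p1, p2) < xc)
            expect_lt(abs(emp - u), 4 * sqrt(u * (1 - u) / n))
        }
    }
})

test_that("correlation estimation reproduces the Pearson formula and
           clamps degenerate cases", {
    p1 <- c(0.1, 0.4, 0.25, 0.8, 0.6)
    p2 <- c(0.2, 0.5, 0.15, 0.7, 0.9)
    est <- estimateCorrelation(p1, p2)
    y1 <- qnorm(1 - p1); y2 <- qnorm(1 - p2)
    manual <- sum((y1 - mean(y1)) * (y2 - mean(y2))) /
        sqrt(sum((y1 - mean(y1))^2) * sum((y2 - mean(y2))^2))
    expect_equal(est@rho, manual)
    dup <- estimateCorrelation(p1, p1)
    expect_equal(dup@rho, 1)
    expect_equal(dup@clampedRho, 0.999)
    expect_error(estimateCorrelation(rep(0.5, 10), p1[c(1:5, 1:5)]),
                 "zero variance")
})

test_that("independent uniform p-values give a small estimated
           correlation", {
    ok <- vapply(1:40, function(s) {
        withr::with_seed(s, {
            est <- estimateCorrelation(runif(500), runif(500))
            abs(est@rho) < 0.12
        })
    }, logical(1))
    expect_gte(mean(ok), 0.99)
})

test_that("the normality gate keeps theoretical p-values for normal
           pairs and flags exponential margins", {
    theoretical <- vapply(1:25, function(s) {
        withr::with_seed(s, {
            g <- normalityGate(rnorm(500), rnorm(500),
                               alphaGenomewide = 1e-6)
            g$source == "theoretical"
        })
    }, logical(1))
    expect_gte(mean(theoretical), 0.95)
    flagged <- vapply(1:25, function(s) {
        withr::with_seed(s, {
            g <- normalityGate(rexp(500) - 1, rnorm(500),
                               alphaGenomewide = 1e-6)
            g$source == "permutation"
        })
    }, logical(1))
    expect_gte(mean(flagged), 0.95)
    expect_error(normalityGate(rep(1, 30), rnorm(30)))
})

test_that("the Bonferroni threshold over the genome-wide region count is
           reported", {
    expect_equal(signif(bonferroniThreshold(36146), 3), 1.38e-6)
    expect_equal(bonferroniThreshold(100, alpha = 0.01), 1e-4)
})

test_that("combineTests assembles both statistics and supports the
           empirical branch", {
    r <- combineTests(0.02, 0.3, rho = 0.4)
    expect_equal(r@minpStat, 0.02)
    expect_equal(r@sumpStat, qnorm(0.98) + qnorm(0.7))
    expect_identical(r@pvalueSource, "theoretical")
    expect_equal(r@minpPvalue, minpPvalue(0.02, 0.3, 0.4))
    # empirical branch: observed min p smaller than all replicates
    permP1 <- seq(0.1, 1, length.out = 99)
    permP2 <- seq(0.15, 1, length.out = 99)
    re <- combineTests(0.01, 0.5, rho = 0.4, source = "permutation",
                       permP1 = permP1, permP2 = permP2)
    expect_equal(re@minpPvalue, 1 / 100)
    expect_identical(re@pvalueSource, "permutation")
})
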