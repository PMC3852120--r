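#' Simulate correlated noncentral chi-squared statistic pairs
#'
#' The two underlying test statistics are modelled as squares of a
#' bivariate normal pair with means (sqrt(a), sqrt(b)), unit variances and
#' correlation \code{rho}, so that marginally S_g ~ chi^2_1(NCP a) and
#' S_h ~ chi^2_1(NCP b).
#'
#' @param a NCP of the more powerful underlying test (>= 0).
#' @param b NCP of the less powerful test; default a/2.
#' @param rho correlation of the underlying normals, in [0, 1).
#' @param nSims number of pairs; default 500000.
#' @param seed RNG seed.
#' @return an nSims x 2 matrix with columns Sg and Sh.
#' @export
simulateStatisticPairs <- function(a, b = a / 2, rho = 0,
                                   nSims = 500000L, seed = 1L) {
    stopifnot(a >= 0, b >= 0, rho >= 0, rho < 1)
    .withSeed(seed, {
        z1 <- stats::rnorm(nSims)
        z2 <- stats::rnorm(nSims)
        y1 <- sqrt(a) + z1
        y2 <- sqrt(b) + rho * z1 + sqrt(1 - rho^2) * z2
        cbind(Sg = y1^2, Sh = y2^2)
    })
}

#' Closed-form power of a 1-df chi-squared test
#'
#' Survival probability of a noncentral chi-square with 1 df and the given
#' NCP beyond the (1 - alpha) quantile of the central chi-square.
#'
#' @param ncp noncentrality parameter (>= 0).
#' @param alpha type-I error level; default 0.05.
#' @return the power.
#' @examples
#' underlyingPower(10.5)  # 0.90 to two decimals
#' @export
underlyingPower <- function(ncp, alpha = 0.05) {
    stats::pchisq(stats::qchisq(1 - alpha, df = 1), df = 1, ncp = ncp,
                  lower.tail = FALSE)
}

# critical value of min(p1, p2) such that the theoretical MinP p-value
# equals alpha at correlation rho (monotone, solved by uniroot)
.minpCritical <- function(alpha, rho) {
    if (rho == 0) return(1 - sqrt(1 - alpha))
    f <- function(x) minpPvalue(x, 1 - 1e-9, rho) - alpha
    stats::uniroot(f, c(alpha / 2 * 1e-3, alpha), tol = 1e-12)$root
}

#' Power of the combined tests under the theoretical model
#'
#' Simulates statistic pairs, converts each to central-chi-square survival
#' p-values, and applies both combined tests with theoretical p-values at
#' the scenario's true correlation (rejection decided through the exact
#' critical value on the statistic scale, which gives decisions identical
#' to per-pair p-value evaluation). Underlying-test powers are closed form.
#'
#' @inheritParams simulateStatisticPairs
#' @param alpha type-I error level.
#' @return one-row data.frame with the four powers, their Monte-Carlo
#'   standard errors and the scenario parameters.
#' @export
combinedPower <- function(a, b = a / 2, rho = 0, alpha = 0.05,
                          nSims = 500000L, seed = 1L) {
    S <- simulateStatisticPairs(a, b, rho, nSims, seed)
    p1 <- stats::pchisq(S[, 1], df = 1, lower.tail = FALSE)
    p2 <- stats::pchisq(S[, 2], df = 1, lower.tail = FALSE)
    xc <- .minpCritical(alpha, rho)
    minpRej <- pmin(p1, p2) < xc
    sumStat <- .invNorm(p1) + .invNorm(p2)
    sumpRej <- sumStat > stats::qnorm(1 - alpha) * sqrt(2 + 2 * rho)
    pm <- mean(minpRej)
    ps <- mean(sumpRej)
    data.frame(a = a, b = b, rho = rho, alpha = alpha, nSims = nSims,
               power_minp = pm, power_sump = ps,
               power_test_g = underlyingPower(a, alpha),
               power_test_h = underlyingPower(b, alpha),
               mc_se_minp = sqrt(pm * (1 - pm) / nSims),
               mc_se_sump = sqrt(ps * (1 - ps) / nSims))
}

#' Power surface over an NCP / correlation grid
#'
#' Evaluates \code{combinedPower} over the cross of an NCP grid and a
#' correlation grid, with the weaker test's NCP set either to a/2 or to a
#' fixed fraction of 10.5 (the anchor NCP giving 90\% power at alpha 0.05).
#' Adds the power differences of each combined test against the better and
#' the worse underlying test.
#'
#' @param aGrid NCPs of the stronger test; default 1:20.
#' @param rhoGrid correlations; default c(0, 0.3, 0.6, 0.9).
#' @param bRule "half" (b = a/2) or "fraction" (a fixed at 10.5 and
#'   b = fraction * 10.5).
#' @param fraction fraction(s) of 10.5 used when \code{bRule="fraction"}.
#' @param alpha type-I error level.
#' @param nSims simulated pairs per grid cell.
#' @param seed base seed; each cell derives its own sub-seed.
#' @return long-format data.frame, one row per grid cell.
#' @export
powerSurface <- function(aGrid = 1:20, rhoGrid = c(0, 0.3, 0.6, 0.9),
                         bRule = c("half", "fraction"), fraction = NULL,
                         alpha = 0.05, nSims = 500000L, seed = 1L) {
    bRule <- match.arg(bRule)
    if (bRule == "fraction") {
        stopifnot(!is.null(fraction))
        cells <- expand.grid(a = 10.5, frac = fraction, rho = rhoGrid)
        cells$b <- cells$frac * 10.5
    } else {
        cells <- expand.grid(a = aGrid, rho = rhoGrid)
        cells$b <- cells$a / 2
    }
    rows <- lapply(seq_len(nrow(cells)), function(i) {
        combinedPower(cells$a[i], cells$b[i], cells$rho[i], alpha, nSims,
                      seed = .replicateSeed(seed, i))
    })
    out <- do.call(rbind, rows)
    better <- pmax(out$power_test_g, out$power_test_h)
    worse <- pmin(out$power_test_g, out$power_test_h)
    out$minp_diff_better <- out$power_minp - better
    out$minp_diff_worse <- out$power_minp - worse
    out$sump_diff_better <- out$power_sump - better
    out$sump_diff_worse <- out$power_sump - worse
    out
}
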