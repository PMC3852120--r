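#' Fit the reduced (covariates-only) model
#'
#' Fits Y = a + Cc + eps by least squares (gaussian) or logistic maximum
#' likelihood (binomial). The fit carries response-scale residuals and is
#' shared by the score tests and the residual permutation engine.
#'
#' @param y phenotype vector (quantitative, or 0/1 for binomial).
#' @param C optional n x K covariate matrix (no intercept column).
#' @param family "gaussian" or "binomial".
#' @return a \linkS4class{NullModelFit}.
#' @examples
#' fit <- fitNullModel(rnorm(30))
#' fit@coefficients  # intercept = mean(y)
#' @export
fitNullModel <- function(y, C = NULL,
                         family = c("gaussian", "binomial")) {
    family <- match.arg(family)
    y <- as.numeric(y)
    n <- length(y)
    if (is.null(C)) {
        C <- matrix(numeric(0), nrow = n, ncol = 0)
    } else {
        C <- as.matrix(C)
        if (is.null(colnames(C))) colnames(C) <- paste0("C", seq_len(ncol(C)))
    }
    if (n <= ncol(C) + 1L)
        stop("need more samples than covariates plus intercept")
    if (family == "binomial" && !all(y %in% c(0, 1)))
        stop("binomial family requires a 0/1 phenotype")
    Z <- cbind(`(Intercept)` = 1, C)
    qrZ <- qr(Z)
    if (qrZ$rank < ncol(Z)) {
        bad <- colnames(Z)[qrZ$pivot[-seq_len(qrZ$rank)]]
        stop("covariate matrix is rank deficient; collinear column(s): ",
             paste(bad, collapse = ", "))
    }
    if (family == "gaussian") {
        fit <- stats::lm.fit(Z, y)
        mu <- fit$fitted.values
        res <- y - mu
        disp <- sum(res^2) / (n - ncol(Z))
        coefs <- fit$coefficients
    } else {
        fit <- stats::glm.fit(Z, y, family = stats::binomial())
        mu <- fit$fitted.values
        res <- y - mu
        disp <- 1
        coefs <- fit$coefficients
    }
    new("NullModelFit", family = family, coefficients = coefs,
        fitted = as.numeric(mu), residuals = as.numeric(res),
        dispersion = disp, covariates = C, y = y)
}
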