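#' EM bias correction for one covariate
#'
#' Preliminary coefficients for a covariate share a common additive bias
#' across taxa because the sampling fractions are only identified up to a
#' design-space component. Pooling across taxa, the coefficients are modeled
#' as a three-component Gaussian mixture: a null component centered at the
#' bias delta with per-taxon spread nu_j0 (the coefficient's standard error),
#' and decreased / increased components centered at delta + l1 and
#' delta + l2 with inflated spreads nu_j0 + kappa1 and nu_j0 + kappa2. The
#' location of the null component is the bias estimate.
#'
#' The M-step updates for delta, l1, l2 and the mixing proportions are
#' closed-form weighted means (l1 and l2 clipped to their sign constraints);
#' kappa1 and kappa2 are updated by one-dimensional likelihood maximisation
#' (ECM). Initialisation: delta at the median coefficient, mixing
#' proportions (0.75, 0.125, 0.125), l1/l2 at the 10th/90th centered
#' percentiles clipped to their signs, kappa at 1.
#'
#' @param betaStarK numeric vector of preliminary coefficients for one
#'   covariate (one entry per taxon).
#' @param nu0sq per-taxon variance of the coefficient (the covariate's
#'   diagonal entry of the sandwich covariance).
#' @param tol convergence tolerance on the log-likelihood change
#'   (default 1e-5).
#' @param maxIter maximum EM iterations (default 100).
#' @param minTaxa minimum number of taxa required (default 10).
#' @return a \linkS4class{MixtureFit}.
#' @export
emBiasCorrection <- function(betaStarK, nu0sq, tol = 1e-5, maxIter = 100L,
                             minTaxa = 10L) {
    keep <- is.finite(betaStarK) & is.finite(nu0sq)
    x <- betaStarK[keep]
    nu0 <- sqrt(pmax(nu0sq[keep], 0))
    d <- length(x)
    if (d < minTaxa)
        stop("EM bias correction needs at least ", minTaxa, " taxa")
    nu0 <- pmax(nu0, 1e-8)

    delta <- stats::median(x)
    pi <- c(0.75, 0.125, 0.125)
    cq <- stats::quantile(x - delta, c(0.10, 0.90), names = FALSE)
    spread <- max(stats::sd(x), 1e-3)
    l1 <- if (cq[1] < 0) cq[1] else -0.1 * spread
    l2 <- if (cq[2] > 0) cq[2] else 0.1 * spread
    kappa1 <- 1; kappa2 <- 1

    kapMax <- 10 * spread + 1
    llOld <- -Inf; converged <- FALSE; it <- 0L
    for (it in seq_len(maxIter)) {
        nu1 <- nu0 + kappa1
        nu2 <- nu0 + kappa2
        f0 <- pi[1] * stats::dnorm(x, delta, nu0)
        f1 <- pi[2] * stats::dnorm(x, delta + l1, nu1)
        f2 <- pi[3] * stats::dnorm(x, delta + l2, nu2)
        tot <- f0 + f1 + f2
        tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
        P0 <- f0 / tot; P1 <- f1 / tot; P2 <- f2 / tot

        pi <- pmax(c(mean(P0), mean(P1), mean(P2)), 1e-12)
        pi <- pi / sum(pi)
        w0 <- P0 / nu0^2; w1 <- P1 / nu1^2; w2 <- P2 / nu2^2
        delta <- sum(w0 * x + w1 * (x - l1) + w2 * (x - l2)) /
            sum(w0 + w1 + w2)
        if (sum(P1) > 1e-8)
            l1 <- min(sum(w1 * (x - delta)) / sum(w1), -1e-8)
        if (sum(P2) > 1e-8)
            l2 <- max(sum(w2 * (x - delta)) / sum(w2), 1e-8)
        if (sum(P1) > 1e-8) {
            r1 <- x - delta - l1
            kappa1 <- stats::optimize(function(k) {
                nu <- nu0 + k
                -sum(P1 * (log(nu) + r1^2 / (2 * nu^2)))
            }, interval = c(1e-8, kapMax), maximum = TRUE)$maximum
        }
        if (sum(P2) > 1e-8) {
            r2 <- x - delta - l2
            kappa2 <- stats::optimize(function(k) {
                nu <- nu0 + k
                -sum(P2 * (log(nu) + r2^2 / (2 * nu^2)))
            }, interval = c(1e-8, kapMax), maximum = TRUE)$maximum
        }

        ll <- sum(log(pi[1] * stats::dnorm(x, delta, nu0) +
                      pi[2] * stats::dnorm(x, delta + l1, nu0 + kappa1) +
                      pi[3] * stats::dnorm(x, delta + l2, nu0 + kappa2) +
                      .Machine$double.xmin))
        if (is.finite(ll) && abs(ll - llOld) < tol) {
            llOld <- ll
            converged <- TRUE
            break
        }
        llOld <- ll
    }

    if (!is.finite(delta) || !is.finite(llOld)) {
        ## degenerate fit: fall back to the plain location estimate
        delta <- stats::median(x)
        converged <- FALSE
        llOld <- NA_real_
    }
    new("MixtureFit", delta = delta, pi = pi, l1 = l1, l2 = l2,
        kappa1 = kappa1, kappa2 = kappa2, converged = converged,
        nIter = it, logLik = llOld)
}

## Run EM over the requested design columns; returns the length-p delta
## vector (0 for skipped columns, including the intercept) and the fits.
.emAllColumns <- function(betaStar, sigma, columns = NULL, tol = 1e-5,
                          maxIter = 100L) {
    p <- ncol(betaStar)
    if (is.null(columns)) columns <- seq_len(p)[-1L]
    delta <- setNames(rep(0, p), colnames(betaStar))
    fits <- list()
    for (k in columns) {
        fit <- emBiasCorrection(betaStar[, k], sigma[k, k, ], tol = tol,
                                maxIter = maxIter)
        delta[k] <- fit@delta
        fits[[colnames(betaStar)[k]]] <- fit
    }
    list(delta = delta, fits = fits)
}
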