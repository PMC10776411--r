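#' Center log counts per taxon
#'
#' Log-transforms positive counts and centers each taxon's log counts around
#' its own observed mean, which removes taxon-specific sequencing efficiency
#' exactly. Zeros are treated as missing (complete-data policy) and stay
#' masked throughout the analysis.
#'
#' @param counts taxa-by-samples matrix; may contain fractional values when a
#'   pseudo-count has been added to zeros.
#' @return list with \code{y} (taxa x samples, NA where the count was zero),
#'   \code{mask} (logical, observed entries), \code{nObs} (per-taxon observed
#'   sample count) and \code{dropped} (names of taxa with fewer than two
#'   observed samples, excluded from \code{y}).
#' @export
centerLogCounts <- function(counts) {
    y <- log(counts)
    y[counts == 0] <- NA_real_
    nObs <- rowSums(!is.na(y))
    dropped <- rownames(counts)[nObs < 2L]
    if (length(dropped)) {
        warning("excluding taxa with fewer than 2 positive samples: ",
                paste(dropped, collapse = ", "))
        y <- y[nObs >= 2L, , drop = FALSE]
    }
    y <- y - rowMeans(y, na.rm = TRUE)
    mask <- !is.na(y)
    list(y = y, mask = mask, nObs = rowSums(mask), dropped = dropped)
}

## Per-taxon least-squares operators on the observed rows. Returns, for each
## taxon, the observed index set, (X'X)^-1 (generalized inverse if rank
## deficient) and the hat operator H = (X'X)^-1 X'.
.lsOperators <- function(mask, X) {
    d <- nrow(mask)
    full <- all(mask)
    XtXinvFull <- .safeSolve(crossprod(X))
    Hfull <- XtXinvFull %*% t(X)
    if (full)
        return(list(full = TRUE, XtXinv = XtXinvFull, H = Hfull))
    ops <- vector("list", d)
    for (j in seq_len(d)) {
        if (all(mask[j, ])) {
            ops[[j]] <- list(obs = seq_len(ncol(mask)), XtXinv = XtXinvFull,
                             H = Hfull)
        } else {
            obs <- which(mask[j, ])
            Xj <- X[obs, , drop = FALSE]
            XtXinv <- .safeSolve(crossprod(Xj))
            ops[[j]] <- list(obs = obs, XtXinv = XtXinv,
                             H = XtXinv %*% t(Xj))
        }
    }
    list(full = FALSE, ops = ops)
}

.safeSolve <- function(M) {
    tryCatch(solve(M), error = function(e) MASS::ginv(M))
}

#' Iterative estimation of sampling fractions and preliminary coefficients
#'
#' Alternates between updating the per-sample log sampling fraction (the mean
#' across taxa of each sample's residual, over the taxa observed in that
#' sample) and per-taxon least-squares fits of the corrected responses on the
#' design, until the sampling-fraction update stabilises. The fixed point
#' yields the preliminary coefficient estimates, which share a common
#' additive bias across taxa whenever the sampling fractions are confounded
#' with the design.
#'
#' @param y centered log-count matrix (taxa x samples) with NA at masked
#'   entries, as produced by \code{\link{centerLogCounts}}.
#' @param X design matrix (samples x p) including the intercept.
#' @param tol convergence tolerance on \code{max |delta theta|} (default
#'   1e-5).
#' @param maxIter maximum iterations (default 100).
#' @return list with \code{thetaStar} (per-sample), \code{betaStar}
#'   (taxa x p), \code{converged}, \code{nIter}.
#' @export
iterativeEstimation <- function(y, X, tol = 1e-5, maxIter = 100L) {
    mask <- !is.na(y)
    if (any(rowSums(mask) < ncol(X)))
        stop("every taxon must have at least p observed samples")
    ls <- .lsOperators(mask, X)
    d <- nrow(y); n <- ncol(y)
    theta <- rep(0, n)
    if (ls$full) {
        B <- y %*% t(ls$H)
        converged <- FALSE
        for (it in seq_len(maxIter)) {
            resid <- y - B %*% t(X)
            thetaNew <- colMeans(resid)
            delta <- max(abs(thetaNew - theta))
            theta <- thetaNew
            B <- sweep(y, 2L, theta) %*% t(ls$H)
            if (delta < tol) { converged <- TRUE; break }
        }
    } else {
        B <- matrix(0, d, ncol(X))
        for (j in seq_len(d))
            B[j, ] <- ls$ops[[j]]$H %*% y[j, ls$ops[[j]]$obs]
        converged <- FALSE
        for (it in seq_len(maxIter)) {
            resid <- y - B %*% t(X)
            thetaNew <- colMeans(resid, na.rm = TRUE)
            thetaNew[is.nan(thetaNew)] <- 0
            delta <- max(abs(thetaNew - theta))
            theta <- thetaNew
            for (j in seq_len(d)) {
                obs <- ls$ops[[j]]$obs
                B[j, ] <- ls$ops[[j]]$H %*% (y[j, obs] - theta[obs])
            }
            if (delta < tol) { converged <- TRUE; break }
        }
    }
    if (!converged)
        warning("sampling-fraction iteration did not converge in ", maxIter,
                " iterations")
    dimnames(B) <- list(rownames(y), colnames(X))
    list(thetaStar = setNames(theta, colnames(y)), betaStar = B,
         converged = converged, nIter = it)
}

#' Heteroskedasticity-consistent coefficient covariance
#'
#' Sandwich covariance of the preliminary coefficients for each taxon, using
#' that taxon's observed rows: bread \code{(X'X)^-1}, meat the
#' squared-residual weighted outer products of the design rows.
#'
#' @param y centered log-count matrix with NA at masked entries.
#' @param X design matrix.
#' @param thetaStar per-sample sampling-fraction estimates.
#' @param betaStar taxa x p preliminary coefficients.
#' @return array p x p x taxa of covariance matrices.
#' @export
estimateSigma <- function(y, X, thetaStar, betaStar) {
    mask <- !is.na(y)
    d <- nrow(y); p <- ncol(X)
    resid <- y - rep(thetaStar, each = d) - betaStar %*% t(X)
    r2 <- resid^2
    r2[!mask] <- 0
    ## XX[, (a,b)] = x_a * x_b columnwise; meat entries via one matmul
    pairIdx <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
    XX <- X[, pairIdx[, 1], drop = FALSE] * X[, pairIdx[, 2], drop = FALSE]
    Meat <- r2 %*% XX                       # d x p(p+1)/2
    sig <- array(0, dim = c(p, p, d),
                 dimnames = list(colnames(X), colnames(X), rownames(y)))
    full <- all(mask)
    XtXinvFull <- .safeSolve(crossprod(X))
    M <- matrix(0, p, p)
    lower <- cbind(pairIdx[, 2], pairIdx[, 1])
    for (j in seq_len(d)) {
        M[pairIdx] <- Meat[j, ]
        M[lower] <- Meat[j, ]
        XtXinv <- if (full || all(mask[j, ])) XtXinvFull else
            .safeSolve(crossprod(X[mask[j, ], , drop = FALSE]))
        S <- XtXinv %*% M %*% XtXinv
        sig[, , j] <- (S + t(S)) / 2
    }
    sig
}

#' Assemble final bias-corrected estimates
#'
#' Subtracts the EM bias estimate from every covariate's preliminary
#' coefficients (the intercept is never corrected) and recomputes the
#' per-sample sampling fractions as the mean residual across taxa over
#' observed entries.
#'
#' @param betaStar taxa x p preliminary coefficients.
#' @param delta length-p bias vector (entry for the intercept ignored and
#'   treated as 0).
#' @param y centered log-count matrix with NA at masked entries.
#' @param X design matrix.
#' @return list with \code{betaHat} and \code{thetaHat}.
#' @export
finalizeEstimates <- function(betaStar, delta, y, X) {
    delta <- as.numeric(delta)
    delta[1L] <- 0
    betaHat <- sweep(betaStar, 2L, delta)
    resid <- y - betaHat %*% t(X)
    thetaHat <- colMeans(resid, na.rm = TRUE)
    thetaHat[is.nan(thetaHat)] <- 0
    list(betaHat = betaHat, thetaHat = setNames(thetaHat, colnames(y)))
}

#' Wald test of a linear hypothesis for one taxon
#'
#' Tests \code{A beta = beta0}. For vector contrasts the statistic is the
#' quadratic form with the contrast covariance and refers to a chi-square
#' distribution on \code{rank(A)} degrees of freedom. For scalar contrasts
#' with \code{s0 > 0} the z-statistic denominator is the standard error plus
#' the additive regularization constant (SAM convention), guarding against
#' spuriously small standard errors.
#'
#' @param beta coefficient vector (length p).
#' @param sigma p x p covariance matrix.
#' @param A contrast matrix (q x p) or a vector for a single contrast.
#' @param beta0 hypothesised contrast value(s), default 0.
#' @param s0 additive regularization constant for scalar contrasts
#'   (default 0). For vector contrasts the covariance diagonal is inflated so
#'   each contrast's standard error becomes \code{se + s0}, preserving
#'   correlations.
#' @return list with \code{W} (statistic), \code{p} (p-value), \code{df}.
#' @export
waldTest <- function(beta, sigma, A, beta0 = 0, s0 = 0) {
    if (is.null(dim(A))) A <- matrix(A, nrow = 1L)
    est <- drop(A %*% beta) - beta0
    V <- A %*% sigma %*% t(A)
    q <- nrow(A)
    if (q == 1L) {
        se <- sqrt(max(V[1L], 0))
        z <- est / (se + s0)
        return(list(W = z, p = 2 * stats::pnorm(-abs(z)), df = 1L))
    }
    if (s0 > 0) {
        se <- sqrt(pmax(diag(V), 0))
        infl <- (se + s0)^2 - se^2
        V <- V + diag(infl, q)
    }
    Vi <- tryCatch(solve(V), error = function(e) MASS::ginv(V))
    df <- qr(V)$rank
    W <- drop(t(est) %*% Vi %*% est)
    list(W = W, p = stats::pchisq(W, df = df, lower.tail = FALSE), df = df)
}

#' Multiple-testing adjustment
#'
#' Step-down Holm (default, robust to arbitrary p-value dependence) or
#' step-up Benjamini-Hochberg adjusted p-values.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @param method "holm" or "bh".
#' @return adjusted p-values, monotone and capped at 1.
#' @export
adjustPvalues <- function(p, method = c("holm", "bh")) {
    method <- match.arg(method)
    stats::p.adjust(p, method = if (method == "bh") "BH" else "holm")
}

## Regularization constants: 5th percentile of each column's standard errors.
.regularizationS0 <- function(se) {
    apply(se, 2L, function(x) {
        x <- x[is.finite(x)]
        if (!length(x)) 0 else unname(stats::quantile(x, 0.05, type = 7))
    })
}
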