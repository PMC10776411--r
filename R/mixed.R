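## Profiled ReML for a single response with a subject random intercept
## (q = 1). The variance ratio lambda = var(intercept)/var(resid) is profiled
## out on the log scale; for fixed lambda the GLS coefficients, the residual
## variance and the ReML criterion are closed-form through per-subject
## Woodbury identities, so each criterion evaluation is O(n p^2).
.remlProfile1 <- function(y, X, subj) {
    n <- length(y); p <- ncol(X)
    subj <- as.integer(factor(subj))
    sx <- rowsum(X, subj)
    sy <- drop(rowsum(y, subj))
    ni <- tabulate(subj)
    XtX <- crossprod(X); Xty <- drop(crossprod(X, y)); yty <- sum(y^2)

    pieces <- function(lam) {
        w <- lam / (1 + lam * ni)
        XtVX <- XtX - crossprod(sx * sqrt(w))
        XtVy <- Xty - drop(crossprod(sx, w * sy))
        yVy <- yty - sum(w * sy^2)
        list(XtVX = XtVX, XtVy = XtVy, yVy = yVy,
             logdetV = sum(log1p(lam * ni)))
    }
    crit <- function(loglam) {
        pc <- pieces(exp(loglam))
        ch <- tryCatch(chol(pc$XtVX), error = function(e) NULL)
        if (is.null(ch)) return(1e10)
        beta <- backsolve(ch, forwardsolve(t(ch), pc$XtVy))
        rss <- max(pc$yVy - sum(pc$XtVy * beta), 1e-300)
        (n - p) * log(rss) + pc$logdetV + 2 * sum(log(diag(ch)))
    }
    opt <- stats::optimize(crit, interval = c(-15, 10))
    ## check the no-random-effect boundary
    lam <- if (crit(-15) <= opt$objective) 0 else exp(opt$minimum)
    pc <- pieces(lam)
    XtVXinv <- .safeSolve(pc$XtVX)
    beta <- drop(XtVXinv %*% pc$XtVy)
    rss <- max(pc$yVy - sum(pc$XtVy * beta), 1e-300)
    sigma2 <- rss / (n - p)
    list(beta = beta, sigma2 = sigma2, lambda = lam,
         D = matrix(lam * sigma2, 1L, 1L),
         covBeta = sigma2 * XtVXinv,
         logLik = -0.5 * min(opt$objective, crit(-15)),
         converged = TRUE)
}

## Pieces of the GLS normal equations at fixed variance ratio(s), for any
## observation subset. q = 1 uses grouped-sum identities; q = 2 loops over
## per-subject blocks (which are small).
.glsPieces <- function(y, X, subj, z, lambda, obs) {
    Xo <- X[obs, , drop = FALSE]
    yo <- y[obs]
    so <- factor(subj[obs])
    if (is.null(z)) {
        lam <- as.numeric(lambda)[1L]
        si <- as.integer(so)
        ni <- tabulate(si)
        w <- lam / (1 + lam * ni)
        VinvX <- Xo - (w * rowsum(Xo, si))[si, , drop = FALSE]
        Vinvy <- yo - (w * drop(rowsum(yo, si)))[si]
        logdetV <- sum(log1p(lam * ni))
    } else {
        Lam <- matrix(lambda, 2L, 2L)
        VinvX <- Xo
        Vinvy <- yo
        logdetV <- 0
        zo <- z[obs]
        for (lev in levels(so)) {
            idx <- which(so == lev)
            Zi <- cbind(1, zo[idx])
            Vi <- diag(length(idx)) + Zi %*% Lam %*% t(Zi)
            ch <- chol(Vi)
            logdetV <- logdetV + 2 * sum(log(diag(ch)))
            VinvX[idx, ] <- chol2inv(ch) %*% Xo[idx, , drop = FALSE]
            Vinvy[idx] <- drop(chol2inv(ch) %*% yo[idx])
        }
    }
    XtVX <- crossprod(Xo, VinvX)
    list(Xo = Xo, yo = yo, VinvX = VinvX, Vinvy = Vinvy, XtVX = XtVX,
         XtVXinv = .safeSolve(XtVX), logdetV = logdetV)
}

## ReML for random intercept + slope (q = 2), unstructured D, via optim on a
## log-Cholesky parametrisation of Lambda = D / sigma2.
.remlProfile2 <- function(y, X, subj, z) {
    n <- length(y); p <- ncol(X)
    obs <- seq_len(n)
    crit <- function(par) {
        L <- matrix(c(exp(par[1]), par[2], 0, exp(par[3])), 2L, 2L)
        Lam <- tcrossprod(L)
        pc <- tryCatch(.glsPieces(y, X, subj, z, Lam, obs),
                       error = function(e) NULL)
        if (is.null(pc)) return(1e10)
        ch <- tryCatch(chol(pc$XtVX), error = function(e) NULL)
        if (is.null(ch)) return(1e10)
        XtVy <- drop(crossprod(pc$Xo, pc$Vinvy))
        beta <- backsolve(ch, forwardsolve(t(ch), XtVy))
        rss <- max(sum(pc$yo * pc$Vinvy) - sum(XtVy * beta), 1e-300)
        (n - p) * log(rss) + pc$logdetV + 2 * sum(log(diag(ch)))
    }
    opt <- stats::optim(c(log(0.5), 0, log(0.5)), crit,
                        method = "Nelder-Mead",
                        control = list(maxit = 200L, reltol = 1e-8))
    L <- matrix(c(exp(opt$par[1]), opt$par[2], 0, exp(opt$par[3])), 2L, 2L)
    Lam <- tcrossprod(L)
    pc <- .glsPieces(y, X, subj, z, Lam, obs)
    XtVy <- drop(crossprod(pc$Xo, pc$Vinvy))
    beta <- drop(pc$XtVXinv %*% XtVy)
    rss <- max(sum(pc$yo * pc$Vinvy) - sum(XtVy * beta), 1e-300)
    sigma2 <- rss / (n - p)
    list(beta = beta, sigma2 = sigma2, lambda = Lam, D = sigma2 * Lam,
         covBeta = sigma2 * pc$XtVXinv, logLik = -0.5 * opt$value,
         converged = opt$convergence == 0L)
}

#' Restricted maximum likelihood fit for one taxon
#'
#' Fits the linear mixed model y = X beta + Z alpha + e for a single taxon's
#' (corrected) log abundances, with a subject random intercept (optionally
#' plus a random slope in a continuous variable, unstructured 2 x 2
#' covariance). Variance components are estimated by ReML with the residual
#' variance profiled out; coefficients by generalized least squares at the
#' estimated variance ratio.
#'
#' @param y numeric response vector (observed entries only).
#' @param X design matrix (rows matching \code{y}).
#' @param subject per-observation subject identifiers.
#' @param z optional per-observation slope variable; when supplied the
#'   random structure is intercept + slope.
#' @return list with \code{beta}, \code{covBeta} (GLS covariance),
#'   \code{sigma2} (residual variance), \code{D} (random-effect covariance),
#'   \code{lambda} (variance ratio(s)), \code{logLik} (ReML criterion times
#'   -1/2, up to a constant), \code{converged}.
#' @export
remlFit <- function(y, X, subject, z = NULL) {
    if (length(unique(subject)) < 2L)
        stop("at least two subjects are required")
    if (is.null(z)) .remlProfile1(y, X, subject)
    else .remlProfile2(y, X, subject, z)
}

#' Iterative ReML estimation of sampling fractions and coefficients
#'
#' Mixed-effects analogue of the iterative sampling-fraction algorithm:
#' alternates the per-observation sampling-fraction update with per-taxon
#' GLS fits under the mixed model. Variance components are estimated by ReML
#' in the first sweep and re-estimated once after the sampling-fraction
#' iteration converges; intermediate iterations hold them fixed (the
#' sampling-fraction shift moves the response by per-observation constants,
#' which leaves variance-component estimates essentially unchanged).
#'
#' @param y centered log-count matrix (taxa x observations) with NA at
#'   masked entries.
#' @param X design matrix (observations x p).
#' @param subject per-observation subject identifiers.
#' @param z optional per-observation random-slope variable.
#' @param tol convergence tolerance on \code{max |delta theta|}.
#' @param maxIter maximum sampling-fraction iterations.
#' @param lambdaFixed optional per-taxon list of variance ratios from a
#'   previous fit; when supplied, ReML estimation is skipped entirely and
#'   GLS uses the given values throughout (used by the sensitivity analysis
#'   so that score differences reflect pseudo-counts only).
#' @return list with \code{thetaStar}, \code{betaStar}, \code{sigma}
#'   (p x p x taxa GLS covariances), \code{sigma2}, \code{D} (per-taxon
#'   random-effect covariances), \code{lambda}, \code{logLik},
#'   \code{converged}, \code{remlConverged} (per taxon).
#' @export
iterativeReml <- function(y, X, subject, z = NULL, tol = 1e-5,
                          maxIter = 100L, lambdaFixed = NULL) {
    mask <- !is.na(y)
    d <- nrow(y); n <- ncol(y); p <- ncol(X)
    if (any(rowSums(mask) < p + 1L))
        stop("every taxon must have more than p observed samples")
    obsList <- lapply(seq_len(d), function(j) which(mask[j, ]))
    q2 <- !is.null(z)
    lambda <- vector("list", d)
    remlConv <- rep(TRUE, d)

    fitOne <- function(j, resp) {
        obs <- obsList[[j]]
        tryCatch(
            remlFit(resp[obs], X[obs, , drop = FALSE], subject[obs],
                    if (q2) z[obs] else NULL),
            error = function(e) NULL)
    }

    ## sweep 1: variance components (unless supplied)
    if (is.null(lambdaFixed)) {
        for (j in seq_len(d)) {
            f <- fitOne(j, y[j, ])
            if (is.null(f)) {     # degenerate taxon: fixed-effects fallback
                remlConv[j] <- FALSE
                lambda[[j]] <- if (q2) matrix(0, 2L, 2L) else 0
            } else {
                remlConv[j] <- f$converged
                lambda[[j]] <- f$lambda
            }
        }
    } else {
        lambda <- lambdaFixed
    }

    ## GLS hat operators at fixed variance components
    G <- vector("list", d)
    B <- matrix(0, d, p)
    for (j in seq_len(d)) {
        obs <- obsList[[j]]
        pc <- .glsPieces(y[j, ], X, subject, z, lambda[[j]], obs)
        G[[j]] <- pc$XtVXinv %*% t(pc$VinvX)
        B[j, ] <- G[[j]] %*% y[j, obs]
    }

    ## GLS residuals are oblique to the design space, so the raw
    ## sampling-fraction update accumulates an unidentifiable design-space
    ## component; constrain theta orthogonal to C(X) (that component is the
    ## shared bias the EM step estimates from the coefficients).
    Qx <- qr.Q(qr(X))
    theta <- rep(0, n)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        resid <- y - B %*% t(X)
        thetaNew <- colMeans(resid, na.rm = TRUE)
        thetaNew[is.nan(thetaNew)] <- 0
        thetaNew <- thetaNew - drop(Qx %*% crossprod(Qx, thetaNew))
        dlt <- max(abs(thetaNew - theta))
        theta <- thetaNew
        for (j in seq_len(d)) {
            obs <- obsList[[j]]
            B[j, ] <- G[[j]] %*% (y[j, obs] - theta[obs])
        }
        if (dlt < tol) { converged <- TRUE; break }
    }
    if (!converged)
        warning("sampling-fraction iteration (ReML) did not converge in ",
                maxIter, " iterations")

    ## final per-taxon fit on the corrected responses; re-estimate the
    ## variance components once unless they were supplied
    sig <- array(NA_real_, dim = c(p, p, d),
                 dimnames = list(colnames(X), colnames(X), rownames(y)))
    sigma2 <- rep(NA_real_, d)
    Dlist <- vector("list", d)
    logLik <- rep(NA_real_, d)
    for (j in seq_len(d)) {
        obs <- obsList[[j]]
        resp <- y[j, ] - theta
        f <- if (is.null(lambdaFixed) && remlConv[j]) fitOne(j, resp)
             else NULL
        if (is.null(f)) {
            ## GLS at the current variance components
            pc <- .glsPieces(resp, X, subject, z, lambda[[j]], obs)
            XtVy <- drop(crossprod(pc$Xo, pc$Vinvy))
            beta <- drop(pc$XtVXinv %*% XtVy)
            rss <- max(sum(pc$yo * pc$Vinvy) - sum(XtVy * beta), 1e-300)
            s2 <- rss / max(length(obs) - p, 1L)
            B[j, ] <- beta
            sigma2[j] <- s2
            Dlist[[j]] <- s2 * matrix(lambda[[j]],
                                      nrow = if (q2) 2L else 1L)
            sig[, , j] <- s2 * pc$XtVXinv
        } else {
            B[j, ] <- f$beta
            sigma2[j] <- f$sigma2
            Dlist[[j]] <- f$D
            lambda[[j]] <- f$lambda
            logLik[j] <- f$logLik
            sig[, , j] <- f$covBeta
        }
    }
    ## recompute theta at the refitted coefficients
    resid <- y - B %*% t(X)
    theta <- colMeans(resid, na.rm = TRUE)
    theta[is.nan(theta)] <- 0

    dimnames(B) <- list(rownames(y), colnames(X))
    list(thetaStar = setNames(theta, colnames(y)), betaStar = B, sigma = sig,
         sigma2 = sigma2, D = Dlist, lambda = lambda, logLik = logLik,
         converged = converged, remlConverged = remlConv)
}
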