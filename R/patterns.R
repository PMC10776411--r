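#' Construct a named order-restriction pattern
#'
#' Builds the polyhedral cone \{A beta >= 0\} encoding a hypothesised trend
#' of the g group effects (relative to the reference group at 0), together
#' with the linked parameter pairs used by the maximum-difference norm.
#' Linked pairs are all pairs whose inequality is specified a priori,
#' including transitively, and include the reference (0) wherever the cone
#' bounds coefficients away from it.
#'
#' @param name one of "simple_inc" (monotone increase from the reference),
#'   "simple_dec" (monotone decrease), "tree" (every group at or above the
#'   reference, no order among groups), "umbrella" (increase to a peak, then
#'   decrease).
#' @param g number of non-reference groups (cone dimension).
#' @param peak peak position in 1..g, required for "umbrella".
#' @return object of class \code{patternSpec}: list with \code{name},
#'   \code{A} (g x g constraint matrix), \code{links} (two-column integer
#'   matrix; each row (a, b) contributes beta_a - beta_b to the norm, index
#'   0 denoting the reference) and \code{g}.
#' @export
buildPattern <- function(name = c("simple_inc", "simple_dec", "tree",
                                  "umbrella"), g, peak = NULL) {
    name <- match.arg(name)
    if (g < 1L) stop("g must be at least 1")
    chainLinks <- function(idx) {
        ## all ordered pairs a > b within the chain (indices may include 0)
        if (length(idx) < 2L) return(matrix(integer(0), 0L, 2L))
        cmb <- utils::combn(idx, 2L)
        cbind(a = cmb[2L, ], b = cmb[1L, ])
    }
    if (name == "simple_inc" || name == "simple_dec") {
        A <- diag(g)
        if (g > 1L)
            for (i in 2:g) A[i, i - 1L] <- -1
        links <- chainLinks(0:g)
        if (name == "simple_dec") {
            A <- -A
            links <- links[, 2:1, drop = FALSE]
            colnames(links) <- c("a", "b")
        }
    } else if (name == "tree") {
        A <- diag(g)
        links <- cbind(a = seq_len(g), b = 0L)
    } else {
        if (is.null(peak) || peak < 1L || peak > g)
            stop("umbrella pattern requires peak in 1..g")
        A <- matrix(0, g, g)
        A[1L, 1L] <- 1
        if (peak > 1L)
            for (i in 2:peak) { A[i, i] <- 1; A[i, i - 1L] <- -1 }
        if (peak < g)
            for (i in (peak + 1L):g) { A[i, i - 1L] <- 1; A[i, i] <- -1 }
        up <- chainLinks(0:peak)
        down <- chainLinks(peak:g)
        down <- down[, 2:1, drop = FALSE]
        colnames(down) <- c("a", "b")
        links <- rbind(up, down)
    }
    structure(list(name = name, A = A, links = links, g = as.integer(g),
                   peak = peak),
              class = "patternSpec")
}

#' Weighted isotonic regression (pool adjacent violators)
#'
#' Minimises \code{sum w (y - m)^2} over non-decreasing m.
#'
#' @param y numeric vector.
#' @param w positive weights (default equal).
#' @return the isotonic fit, same length as \code{y}.
#' @export
pavaIsotonic <- function(y, w = rep(1, length(y))) {
    n <- length(y)
    if (n == 0L) return(numeric(0))
    val <- y; wt <- w; idx <- rep(1L, n)  # block sizes
    nb <- n
    repeat {
        viol <- which(diff(val[seq_len(nb)]) < 0)
        if (!length(viol)) break
        i <- viol[1L]
        newW <- wt[i] + wt[i + 1L]
        val[i] <- (wt[i] * val[i] + wt[i + 1L] * val[i + 1L]) / newW
        wt[i] <- newW
        idx[i] <- idx[i] + idx[i + 1L]
        if (i + 1L < nb) {
            val[(i + 1L):(nb - 1L)] <- val[(i + 2L):nb]
            wt[(i + 1L):(nb - 1L)] <- wt[(i + 2L):nb]
            idx[(i + 1L):(nb - 1L)] <- idx[(i + 2L):nb]
        }
        nb <- nb - 1L
    }
    rep(val[seq_len(nb)], idx[seq_len(nb)])
}

#' Constrained (order-restricted) estimate of group effects
#'
#' Projects the unconstrained estimate onto the closed cone of the pattern
#' in the Mahalanobis metric of the coefficient covariance (the convex
#' quadratic program of constrained inference). Solved through the dual as
#' a non-negative least-squares problem; when the covariance is diagonal and
#' the pattern is a simple order, the weighted isotonic-regression fast path
#' is used.
#'
#' @param betaHat length-g unconstrained estimate.
#' @param sigmaG g x g positive-definite covariance.
#' @param spec a \code{patternSpec} from \code{\link{buildPattern}}.
#' @param method "auto" (default; isotonic-regression fast path for simple
#'   orders with diagonal covariance, dual NNLS otherwise), or force "nnls"
#'   or "pava".
#' @return the constrained estimate (length g).
#' @export
constrainedEstimate <- function(betaHat, sigmaG, spec,
                                method = c("auto", "nnls", "pava")) {
    method <- match.arg(method)
    g <- length(betaHat)
    sigmaG <- matrix(sigmaG, g, g)
    offdiag <- sigmaG; diag(offdiag) <- 0
    diagonal <- all(offdiag == 0)
    usePava <- method == "pava" ||
        (method == "auto" && diagonal &&
         spec$name %in% c("simple_inc", "simple_dec"))
    if (usePava) {
        if (!diagonal || !spec$name %in% c("simple_inc", "simple_dec"))
            stop("the isotonic fast path needs a diagonal covariance and a ",
                 "simple order")
        w <- 1 / diag(sigmaG)
        if (spec$name == "simple_inc")
            return(pmax(pavaIsotonic(betaHat, w), 0))
        return(-pmax(pavaIsotonic(-betaHat, w), 0))
    }
    R <- tryCatch(chol(sigmaG), error = function(e)
        stop("sigmaG must be positive definite: ", conditionMessage(e)))
    A <- spec$A
    C <- A %*% t(R)                      # C C' = A Sigma A'
    w <- forwardsolve(t(R), betaHat)     # C w = A betaHat
    sol <- pracma::lsqnonneg(t(C), -w)
    mu <- sol$x
    drop(betaHat + sigmaG %*% t(A) %*% mu)
}

#' Maximum-difference norm of a constrained estimate
#'
#' The largest difference between the estimates of two linked parameters of
#' the pattern (including the implicit reference at 0 where the cone bounds
#' coefficients away from it), taken in the direction the pattern specifies.
#'
#' @param betaOpt constrained estimate (length g).
#' @param spec a \code{patternSpec}.
#' @return non-negative scalar.
#' @export
lInfNorm <- function(betaOpt, spec) {
    bp <- c(0, betaOpt)
    max(bp[spec$links[, 1L] + 1L] - bp[spec$links[, 2L] + 1L])
}

## Vectorised projection of m points onto a 2-dimensional cone {A beta >= 0}
## (A invertible 2x2) in the metric Q = Sigma^-1. Interior points are kept;
## boundary solutions lie on one of the two extreme rays or at the apex.
.projectCone2 <- function(pts, Q, A) {
    m <- nrow(pts)
    feas <- (pts %*% A[1L, ] >= -1e-12) & (pts %*% A[2L, ] >= -1e-12)
    out <- pts
    bad <- which(!feas)
    if (!length(bad)) return(out)
    Rr <- solve(A)                       # columns are the extreme rays
    b <- pts[bad, , drop = FALSE]
    gain <- matrix(0, length(bad), 2L)
    tval <- matrix(0, length(bad), 2L)
    for (i in 1:2) {
        r <- Rr[, i]
        rQr <- drop(t(r) %*% Q %*% r)
        rQb <- drop(b %*% (Q %*% r))
        t_i <- pmax(0, rQb / rQr)
        tval[, i] <- t_i
        gain[, i] <- ifelse(t_i > 0, rQb^2 / rQr, 0)
    }
    pick <- ifelse(gain[, 2L] > gain[, 1L], 2L, 1L)
    tt <- tval[cbind(seq_along(bad), pick)]
    out[bad, ] <- tt * t(Rr[, pick, drop = FALSE])
    ## rows where the chosen t is 0 project to the apex
    out[bad[tt == 0], ] <- 0
    out
}

## W = max over patterns of the norm of the projected point, for a matrix of
## points (m x g). Uses the closed-form 2-D projector when g == 2.
.williamsW <- function(pts, sigmaG, specs) {
    g <- ncol(pts)
    m <- nrow(pts)
    W <- rep(-Inf, m)
    best <- rep(NA_integer_, m)
    if (g == 2L) {
        Q <- solve(sigmaG)
        for (t in seq_along(specs)) {
            proj <- .projectCone2(pts, Q, specs[[t]]$A)
            bp <- cbind(0, proj)
            li <- rep(-Inf, m)
            lk <- specs[[t]]$links
            for (r in seq_len(nrow(lk)))
                li <- pmax(li, bp[, lk[r, 1L] + 1L] - bp[, lk[r, 2L] + 1L])
            upd <- li > W
            W[upd] <- li[upd]
            best[upd] <- t
        }
    } else {
        for (i in seq_len(m)) {
            for (t in seq_along(specs)) {
                bo <- constrainedEstimate(pts[i, ], sigmaG, specs[[t]])
                li <- lInfNorm(bo, specs[[t]])
                if (li > W[i]) { W[i] <- li; best[i] <- t }
            }
        }
    }
    list(W = W, best = best)
}

#' Williams-type pattern test for one taxon
#'
#' Computes the observed statistic \code{W = max_t l_inf(C_t)} over the
#' candidate patterns after constrained estimation, then simulates its null
#' distribution by drawing the group effects independently as centered
#' normals with the estimated variances, applying the identical constrained
#' estimation and scoring to each draw.
#'
#' @param betaHat length-g bias-corrected group-effect estimate.
#' @param sigmaG g x g covariance of the estimate.
#' @param specs list of \code{patternSpec} objects (default: simple
#'   increasing and simple decreasing).
#' @param B number of null draws (default 1000, minimum 100).
#' @param seed optional integer seed.
#' @return list with \code{W}, \code{p}, \code{bestPattern} (name of the
#'   argmax pattern), \code{betaOpt} (constrained estimate under the best
#'   pattern) and \code{B}.
#' @export
patternTest <- function(betaHat, sigmaG, specs = NULL, B = 1000L,
                        seed = NULL) {
    g <- length(betaHat)
    if (B < 100L) stop("B must be at least 100")
    if (is.null(specs))
        specs <- list(buildPattern("simple_inc", g),
                      buildPattern("simple_dec", g))
    sigmaG <- matrix(sigmaG, g, g)
    obs <- .williamsW(matrix(betaHat, 1L), sigmaG, specs)
    if (!is.null(seed)) set.seed(seed)
    sds <- sqrt(pmax(diag(sigmaG), 0))
    draws <- matrix(stats::rnorm(B * g), B, g) %*% diag(sds, g)
    nullW <- .williamsW(draws, sigmaG, specs)$W
    bestSpec <- specs[[obs$best]]
    betaOpt <- constrainedEstimate(betaHat, sigmaG, bestSpec)
    list(W = obs$W, p = mean(nullW > obs$W), bestPattern = bestSpec$name,
         betaOpt = betaOpt, B = B)
}
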