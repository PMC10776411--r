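#' Global test across experimental groups
#'
#' Chi-square test of whether any group coefficient differs from the
#' reference, per taxon: the identity contrast on the group-coefficient
#' subvector with the corresponding covariance submatrix.
#'
#' @param betaHat taxa x p bias-corrected coefficient matrix.
#' @param sigma p x p x taxa covariance array.
#' @param groupCols integer indices of the g group-indicator columns.
#' @param s0 per-column regularization constants (length p or length g), or
#'   NULL for no regularization.
#' @return data.frame with columns taxon, W, p.
#' @export
globalTest <- function(betaHat, sigma, groupCols, s0 = NULL) {
    g <- length(groupCols)
    if (g < 1L) stop("at least one group coefficient is required")
    d <- nrow(betaHat)
    s0g <- if (is.null(s0)) rep(0, g) else
        if (length(s0) == ncol(betaHat)) s0[groupCols] else rep(s0, length.out = g)
    W <- p <- rep(NA_real_, d)
    A <- diag(g)
    for (j in seq_len(d)) {
        Sg <- sigma[groupCols, groupCols, j, drop = TRUE]
        Sg <- matrix(Sg, g, g)
        if (any(s0g > 0)) {
            se <- sqrt(pmax(diag(Sg), 0))
            Sg <- Sg + diag((se + s0g)^2 - se^2, g)
        }
        wt <- waldTest(betaHat[j, groupCols], Sg, A, beta0 = rep(0, g))
        W[j] <- wt$W; p[j] <- wt$p
    }
    data.frame(taxon = rownames(betaHat), W = W, p = p,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' All pairwise group comparison statistics
#'
#' Two-sided z-statistics for every unordered pair of groups, including each
#' group against the reference (whose coefficient and variance are zero by
#' construction). The denominator uses the two coefficients' variances only
#' (no covariance term), each standard error regularized additively when
#' \code{s0} is supplied.
#'
#' @param betaHat taxa x p coefficient matrix.
#' @param sigma p x p x taxa covariance array.
#' @param groupCols indices of the g group columns; the reference group is
#'   implicit (index 0).
#' @param groupLevels optional character vector of length g + 1 naming the
#'   reference and the g groups (for labeling).
#' @param s0 per-column regularization (as in \code{\link{globalTest}}).
#' @param referenceOnly logical; if TRUE only the g reference comparisons are
#'   returned (Dunnett-type layout), otherwise all g(g+1)/2 pairs.
#' @return data.frame with columns taxon, k, kprime (group labels, kprime is
#'   the lower-ordered group), lfc, se, W, p.
#' @export
pairwiseStats <- function(betaHat, sigma, groupCols, groupLevels = NULL,
                          s0 = NULL, referenceOnly = FALSE) {
    g <- length(groupCols)
    d <- nrow(betaHat)
    if (is.null(groupLevels)) groupLevels <- as.character(0:g)
    s0g <- if (is.null(s0)) rep(0, g) else
        if (length(s0) == ncol(betaHat)) s0[groupCols] else rep(s0, length.out = g)
    B <- betaHat[, groupCols, drop = FALSE]
    V <- matrix(0, d, g)
    for (k in seq_len(g)) V[, k] <- sigma[groupCols[k], groupCols[k], ]
    if (any(V <= 0)) stop("non-positive variance in pairwise comparison")
    seReg <- sweep(sqrt(V), 2L, s0g, "+")

    pairs <- cbind(k = seq_len(g), kprime = 0L)
    if (!referenceOnly && g >= 2L) {
        extra <- t(utils::combn(seq_len(g), 2L))[, 2:1, drop = FALSE]
        colnames(extra) <- c("k", "kprime")
        pairs <- rbind(pairs, extra)
    }
    out <- vector("list", nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
        k <- pairs[r, 1L]; kp <- pairs[r, 2L]
        if (kp == 0L) {
            lfc <- B[, k]
            se <- sqrt(seReg[, k]^2)
        } else {
            lfc <- B[, k] - B[, kp]
            se <- sqrt(seReg[, k]^2 + seReg[, kp]^2)
        }
        W <- lfc / se
        out[[r]] <- data.frame(
            taxon = rownames(betaHat),
            k = groupLevels[k + 1L],
            kprime = groupLevels[kp + 1L],
            lfc = lfc, se = se, W = W,
            p = 2 * stats::pnorm(-abs(W)),
            row.names = NULL, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}

#' Mixed directional FDR controlling procedure
#'
#' The three-step screen-then-test-then-sign procedure: (1) Benjamini-
#' Hochberg on the per-taxon screening p-values at level alpha, giving R
#' discovered taxa; (2) within each discovered taxon, a familywise
#' error-controlling procedure (Holm by default) on its pairwise p-values at
#' level R * alpha / d; (3) directions assigned by the sign of the pairwise
#' statistic for each rejected pairwise hypothesis.
#'
#' @param screeningP named per-taxon screening p-values (length d).
#' @param pairwise data.frame from \code{\link{pairwiseStats}} with columns
#'   taxon, k, kprime, W, p.
#' @param alpha nominal mdFDR level (default 0.05).
#' @param fwerMethod "holm" (default) or "hochberg" for step 2.
#' @return list with \code{screened} (named logical), \code{R}, and
#'   \code{pairwise}: the input with added columns rejected (logical) and
#'   direction ("up", "down" or "none", relative to k vs kprime).
#' @export
mdfdrProcedure <- function(screeningP, pairwise, alpha = 0.05,
                           fwerMethod = c("holm", "hochberg")) {
    fwerMethod <- match.arg(fwerMethod)
    d <- length(screeningP)
    qScreen <- stats::p.adjust(screeningP, method = "BH")
    screened <- qScreen <= alpha
    R <- sum(screened, na.rm = TRUE)
    pairwise$rejected <- FALSE
    pairwise$direction <- "none"
    if (R > 0L) {
        level <- R * alpha / d
        for (tx in names(screeningP)[which(screened)]) {
            idx <- which(pairwise$taxon == tx)
            if (!length(idx)) next
            padj <- stats::p.adjust(pairwise$p[idx], method = fwerMethod)
            rej <- padj <= level
            pairwise$rejected[idx] <- rej
            pairwise$direction[idx][rej] <-
                ifelse(pairwise$W[idx][rej] > 0, "up", "down")
        }
    }
    list(screened = setNames(as.logical(screened), names(screeningP)), R = R,
         pairwise = pairwise, alpha = alpha)
}

#' Dunnett-type screening p-values
#'
#' Monte-Carlo p-value for the maximum absolute reference-comparison
#' z-statistic against the null distribution of the maximum of g independent
#' standard normal absolute values. One shared set of null draws serves all
#' taxa (the null distribution does not depend on the taxon).
#'
#' @param Wmat taxa x g matrix of reference-comparison z-statistics (or a
#'   vector for a single taxon).
#' @param B number of null draws (default 1000, minimum 100).
#' @param seed optional integer seed for the draws.
#' @return named numeric vector of screening p-values.
#' @export
dunnettScreen <- function(Wmat, B = 1000L, seed = NULL) {
    if (is.null(dim(Wmat))) Wmat <- matrix(Wmat, nrow = 1L)
    if (B < 100L) stop("B must be at least 100")
    g <- ncol(Wmat)
    if (!is.null(seed)) set.seed(seed)
    Wb <- matrix(abs(stats::rnorm(B * g)), B, g)
    nullMax <- if (g == 1L) Wb[, 1L] else do.call(pmax, as.data.frame(Wb))
    obs <- apply(abs(Wmat), 1L, max)
    p <- vapply(obs, function(w) mean(nullMax > w), numeric(1))
    setNames(p, rownames(Wmat))
}
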