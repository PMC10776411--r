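#' Detect structural zeros across experimental groups
#'
#' A taxon is structurally zero in a group when it is absent from that entire
#' ecosystem. By default absence means every count in the group is zero; with
#' \code{useAsymptoticBound} a taxon is declared absent when the lower
#' normal-approximation confidence bound on its within-group presence
#' proportion is at or below zero, which additionally catches taxa observed
#' in a vanishing fraction of a group. Taxa that are structurally zero in
#' some groups but present in others are differentially abundant by
#' presence/absence alone and are excluded from model-based analysis.
#'
#' @param counts taxa-by-samples count matrix.
#' @param groups per-sample group labels (length = number of samples).
#' @param useAsymptoticBound logical; use the presence-proportion lower
#'   confidence bound rule instead of the all-zero rule.
#' @param coverage nominal coverage of the bound (default 0.95).
#' @return \linkS4class{ZeroReport} with the structural part filled in;
#'   \code{retained} is \code{TRUE} for taxa not declared structural-zero DA
#'   and not absent everywhere (no prevalence filter applied here).
#' @export
detectStructuralZeros <- function(counts, groups, useAsymptoticBound = FALSE,
                                  coverage = 0.95) {
    groups <- as.factor(groups)
    if (length(groups) != ncol(counts))
        stop("groups must have one label per sample")
    if (nlevels(groups) < 2L)
        stop("at least two groups are required")
    if (any(table(groups) == 0L))
        stop("every group must contain at least one sample")
    present <- counts > 0
    d <- nrow(counts)
    sz <- matrix(FALSE, d, nlevels(groups),
                 dimnames = list(rownames(counts), levels(groups)))
    z <- stats::qnorm(1 - (1 - coverage) / 2)
    for (g in levels(groups)) {
        idx <- groups == g
        nr <- sum(idx)
        phat <- rowMeans(present[, idx, drop = FALSE])
        if (useAsymptoticBound) {
            lower <- phat - z * sqrt(phat * (1 - phat) / nr)
            sz[, g] <- lower <= 0
        } else {
            sz[, g] <- phat == 0
        }
    }
    nz <- rowSums(sz)
    structuralDA <- nz > 0L & nz < ncol(sz)
    prevalence <- rowMeans(present)
    retained <- !structuralDA & prevalence > 0
    new("ZeroReport", structuralZero = sz, structuralDA = structuralDA,
        prevalence = prevalence, retained = retained, threshold = 0)
}

#' Prevalence filter
#'
#' Retains taxa present (count > 0) in at least \code{threshold} of all
#' samples; the boundary is inclusive.
#'
#' @param counts taxa-by-samples count matrix.
#' @param threshold fraction in [0, 1]; default 0.10.
#' @return named logical vector of retained taxa.
#' @export
prevalenceFilter <- function(counts, threshold = 0.10) {
    if (threshold < 0 || threshold > 1)
        stop("threshold must lie in [0, 1]")
    prevalence <- rowMeans(counts > 0)
    setNames(prevalence >= threshold, rownames(counts))
}

#' Combined zero-handling assessment
#'
#' Runs structural-zero detection (when groups are given) followed by the
#' prevalence filter, assembling the full \linkS4class{ZeroReport}. Taxa
#' declared structural-zero DA bypass the prevalence filter (they are
#' reported, not modeled); taxa absent everywhere are dropped.
#'
#' @inheritParams detectStructuralZeros
#' @inheritParams prevalenceFilter
#' @return \linkS4class{ZeroReport}.
#' @export
assessZeros <- function(counts, groups = NULL, threshold = 0.10,
                        useAsymptoticBound = FALSE, coverage = 0.95) {
    prevalence <- rowMeans(counts > 0)
    if (!is.null(groups)) {
        zr <- detectStructuralZeros(counts, groups, useAsymptoticBound,
                                    coverage)
        sz <- zr@structuralZero
        structuralDA <- zr@structuralDA
    } else {
        sz <- matrix(FALSE, nrow(counts), 0L,
                     dimnames = list(rownames(counts), NULL))
        structuralDA <- setNames(rep(FALSE, nrow(counts)), rownames(counts))
    }
    retained <- !structuralDA & prevalence >= threshold & prevalence > 0
    new("ZeroReport", structuralZero = sz, structuralDA = structuralDA,
        prevalence = setNames(prevalence, rownames(counts)),
        retained = retained, threshold = threshold)
}

#' Pseudo-count sensitivity analysis
#'
#' Assesses how sensitive each taxon's significance verdict is to the
#' pseudo-count used for zeros. For every value c in the grid, all zero
#' counts are replaced by c, the supplied fit callback re-runs the full
#' analysis on the modified table, and the per-taxon p-values are recorded.
#' The sensitivity score is the fraction of grid runs in which the p-value
#' exceeds \code{alpha}. A taxon is insensitive only when the grid verdict is
#' unanimous (score exactly 0 or 1) and agrees with the complete-data
#' verdict; otherwise it is sensitive, and under the SS-filter variant
#' sensitive taxa are declared non-significant.
#'
#' @param fitFun callback taking a modified count matrix and returning a
#'   named numeric vector of per-taxon p-values (taxa matching
#'   \code{rownames(counts)}).
#' @param counts taxa-by-samples count matrix (the complete data).
#' @param completeP named numeric vector of p-values from the complete-data
#'   fit.
#' @param alpha significance level (default 0.05).
#' @param pseudoGrid strictly positive pseudo-counts; default
#'   \code{seq(0.01, 0.50, by = 0.01)}.
#' @return data.frame with columns taxon, score, complete_sig, sensitive.
#' @export
sensitivityAnalysis <- function(fitFun, counts, completeP, alpha = 0.05,
                                pseudoGrid = seq(0.01, 0.50, by = 0.01)) {
    if (any(pseudoGrid <= 0))
        stop("pseudo-counts must be strictly positive")
    taxa <- rownames(counts)
    exceed <- matrix(NA, length(taxa), length(pseudoGrid),
                     dimnames = list(taxa, NULL))
    for (ci in seq_along(pseudoGrid)) {
        cc <- pseudoGrid[ci]
        modified <- counts
        modified[modified == 0] <- cc
        p <- tryCatch(fitFun(modified), error = function(e)
            stop("sensitivity fit failed at pseudo-count ", cc, ": ",
                 conditionMessage(e)))
        exceed[, ci] <- p[taxa] > alpha
    }
    score <- rowMeans(exceed)
    completeSig <- completeP[taxa] <= alpha
    unanimous <- score %in% c(0, 1)
    agrees <- (score == 0 & completeSig) | (score == 1 & !completeSig)
    sensitive <- !(unanimous & agrees)
    sensitive[is.na(score) | is.na(completeSig)] <- TRUE
    data.frame(taxon = taxa, score = score, complete_sig = completeSig,
               sensitive = sensitive, row.names = NULL,
               stringsAsFactors = FALSE)
}
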