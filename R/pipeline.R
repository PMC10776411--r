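## Parse a random-effects specification: NULL, a formula ~ 1 | subject or
## ~ 1 + var | subject, or the string form "(1|subject)" / "(1+var|subject)".
.parseRandom <- function(random) {
    if (is.null(random)) return(NULL)
    txt <- if (inherits(random, "formula"))
        paste(deparse(random[[2L]]), collapse = "") else as.character(random)
    txt <- gsub("[()[:space:]]", "", txt)
    parts <- strsplit(txt, "|", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
        stop("random term must have the form (1|subject) or (1+var|subject)")
    lhs <- strsplit(parts[1L], "+", fixed = TRUE)[[1L]]
    lhs <- setdiff(lhs, c("1", ""))
    if (length(lhs) > 1L)
        stop("at most one random slope variable is supported")
    list(subject = parts[2L], slope = if (length(lhs)) lhs else NULL)
}

## Core estimation on a retained count table: centering, iterative
## estimation (ML or ReML), sandwich/GLS covariance, EM bias correction and
## final estimates. `emColumns` restricts the EM to selected design columns
## (NULL = all non-intercept columns). For mixed fits `lambdaFixed` skips
## ReML (sensitivity-analysis path).
.coreFit <- function(counts, X, randomInfo = NULL, subject = NULL,
                     slopeZ = NULL, tol = 1e-5, maxIter = 100L,
                     emColumns = NULL, lambdaFixed = NULL) {
    cl <- centerLogCounts(counts)
    y <- cl$y
    keep <- rowSums(cl$mask) > ncol(X)
    ## the design must stay full rank on each taxon's observed rows,
    ## otherwise its contrasts are not estimable from the complete data
    for (j in which(keep)) {
        obs <- cl$mask[rownames(y)[j], ]
        if (!all(obs) && qr(X[obs, , drop = FALSE])$rank < ncol(X))
            keep[j] <- FALSE
    }
    if (!all(keep)) {
        warning("excluding taxa whose observed samples cannot support the ",
                "design: ", paste(rownames(y)[!keep], collapse = ", "))
        y <- y[keep, , drop = FALSE]
    }
    mixed <- !is.null(randomInfo)
    if (mixed) {
        it <- iterativeReml(y, X, subject = subject, z = slopeZ, tol = tol,
                            maxIter = maxIter, lambdaFixed = lambdaFixed)
        sigma <- it$sigma
        random <- list(sigma2 = it$sigma2, D = it$D, lambda = it$lambda,
                       logLik = it$logLik, remlConverged = it$remlConverged)
    } else {
        it <- iterativeEstimation(y, X, tol = tol, maxIter = maxIter)
        sigma <- estimateSigma(y, X, it$thetaStar, it$betaStar)
        random <- list()
    }
    em <- .emAllColumns(it$betaStar, sigma, columns = emColumns, tol = tol,
                        maxIter = maxIter)
    fin <- finalizeEstimates(it$betaStar, em$delta, y, X)
    p <- ncol(X)
    d <- nrow(y)
    se <- matrix(NA_real_, d, p, dimnames = dimnames(it$betaStar))
    for (k in seq_len(p)) se[, k] <- sqrt(pmax(sigma[k, k, ], 0))
    list(y = y, mask = !is.na(y), betaStar = it$betaStar,
         betaHat = fin$betaHat, thetaStar = it$thetaStar,
         thetaHat = fin$thetaHat, sigma = sigma, se = se,
         s0 = .regularizationS0(se), delta = em$delta, mixtures = em$fits,
         converged = it$converged, random = random,
         dropped = c(cl$dropped, rownames(cl$y)[!keep]))
}

## p-values used for significance calls and the sensitivity score, given a
## fitted core. mode: "covariate" (matrix of per-column z-test p-values),
## "global", "dunnett" or "trend" (per-taxon screening p).
.targetPvalues <- function(core, ctx) {
    s0 <- if (ctx$regularize) core$s0 else rep(0, ncol(core$betaHat))
    if (ctx$mode == "covariate") {
        cols <- ctx$testCols
        z <- core$betaHat[, cols, drop = FALSE] /
            sweep(core$se[, cols, drop = FALSE], 2L, s0[cols], "+")
        return(2 * stats::pnorm(-abs(z)))
    }
    if (ctx$mode == "global") {
        gt <- globalTest(core$betaHat, core$sigma, ctx$groupCols)
        return(setNames(gt$p, gt$taxon))
    }
    if (ctx$mode == "dunnett") {
        pw <- pairwiseStats(core$betaHat, core$sigma, ctx$groupCols,
                            groupLevels = ctx$groupLevels,
                            s0 = if (ctx$regularize) core$s0 else NULL,
                            referenceOnly = TRUE)
        Wmat <- matrix(pw$W, nrow = nrow(core$betaHat),
                       dimnames = list(rownames(core$betaHat), NULL))
        return(dunnettScreen(Wmat, B = ctx$B, seed = ctx$seed))
    }
    ## trend: Williams-type pattern p per taxon
    pr <- .patternAll(core, ctx)
    setNames(pr$p, pr$taxon)
}

## regularized group-coefficient covariance for one taxon: each SE becomes
## se + s0 while correlations are preserved
.regularizedSigmaG <- function(sigma, groupCols, j, s0g) {
    g <- length(groupCols)
    Sg <- matrix(sigma[groupCols, groupCols, j], g, g)
    if (any(s0g > 0)) {
        se <- sqrt(pmax(diag(Sg), 0))
        Sg <- Sg + diag((se + s0g)^2 - se^2, g)
    }
    Sg
}

## pattern analysis over all taxa
.patternAll <- function(core, ctx) {
    g <- length(ctx$groupCols)
    specs <- ctx$patternSpecs
    d <- nrow(core$betaHat)
    W <- p <- lfc <- rep(NA_real_, d)
    best <- character(d)
    if (!is.null(ctx$seed)) set.seed(ctx$seed)
    for (j in seq_len(d)) {
        Sg <- .regularizedSigmaG(core$sigma, ctx$groupCols, j, 0)
        pt <- patternTest(core$betaHat[j, ctx$groupCols], Sg, specs,
                          B = ctx$B, seed = NULL)
        W[j] <- pt$W; p[j] <- pt$p; best[j] <- pt$bestPattern
        lfc[j] <- pt$betaOpt[g]
    }
    data.frame(taxon = rownames(core$betaHat), W = W, p = p,
               best_pattern = best, lfc_end = lfc,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Bias-corrected differential abundance analysis
#'
#' The full analysis pipeline for a taxa-by-samples count table: structural
#' zero detection (optional), prevalence filtering, per-taxon centering of
#' log counts, iterative estimation of sampling fractions (ML for fixed
#' effects, ReML with a subject random intercept or intercept + slope for
#' repeated measures), EM Gaussian-mixture bias correction of every
#' covariate's coefficients, regularized Wald tests with Holm (default)
#' adjustment, and optionally: a chi-square global test, all-pairwise or
#' reference-only (Dunnett-type) comparisons under mdFDR control, pattern
#' (trend) analysis over ordered groups, and the pseudo-count sensitivity
#' filter that demotes taxa whose verdicts depend on the pseudo-count.
#'
#' @param counts taxa-by-samples integer matrix (or a SummarizedExperiment,
#'   first assay used).
#' @param metadata data.frame of sample covariates, row names matching the
#'   count table's sample names (taken from colData when \code{counts} is a
#'   SummarizedExperiment and \code{metadata} is NULL).
#' @param fixed one-sided formula or character vector of fixed-effect
#'   variables.
#' @param group optional name of the (categorical) group variable among the
#'   fixed effects; required for global/pairwise/Dunnett/trend analyses.
#' @param random optional random-effects term, e.g. \code{~ 1 | subject} or
#'   \code{"(1 + time | subject)"}.
#' @param reference named list of reference levels for categorical
#'   variables (default: first level in lexicographic order).
#' @param prvCut prevalence cutoff (default 0.10).
#' @param alpha nominal significance level (default 0.05).
#' @param pAdjMethod "holm" (default) or "bh".
#' @param structZero detect structural zeros across groups (default FALSE).
#' @param structZeroAsymptotic use the asymptotic lower-bound rule for
#'   structural zeros.
#' @param ssFilter run the pseudo-count sensitivity analysis and declare
#'   sensitive taxa non-significant (default TRUE).
#' @param pseudoGrid pseudo-count grid (default 0.01 to 0.50 by 0.01).
#' @param global compute the chi-square global screening test (default TRUE
#'   when a group is given).
#' @param pairwise run all pairwise comparisons under mdFDR control.
#' @param dunnett run reference-only comparisons with the Dunnett-type
#'   bootstrap screen under mdFDR control.
#' @param trend run the order-restricted pattern analysis.
#' @param patterns character vector of candidate patterns for \code{trend}
#'   ("simple_inc", "simple_dec", "tree", "umbrella:k" with peak k).
#' @param B bootstrap size for Dunnett screening and pattern nulls
#'   (default 1000).
#' @param seed integer seed for all Monte-Carlo components.
#' @param regularize apply the SAM-style additive standard-error
#'   regularization (5th percentile of each fixed effect's standard errors;
#'   default TRUE).
#' @param fwerMethod within-taxon familywise procedure for mdFDR step 2.
#' @param tol,maxIter convergence controls for the iterative estimation and
#'   the EM.
#' @return a \linkS4class{BCDAResults}.
#' @export
bcda <- function(counts, metadata = NULL, fixed, group = NULL, random = NULL,
                 reference = NULL, prvCut = 0.10, alpha = 0.05,
                 pAdjMethod = c("holm", "bh"), structZero = FALSE,
                 structZeroAsymptotic = FALSE, ssFilter = TRUE,
                 pseudoGrid = seq(0.01, 0.50, by = 0.01),
                 global = !is.null(group), pairwise = FALSE,
                 dunnett = FALSE, trend = FALSE,
                 patterns = c("simple_inc", "simple_dec"), B = 1000L,
                 seed = NULL, regularize = TRUE,
                 fwerMethod = c("holm", "hochberg"), tol = 1e-5,
                 maxIter = 100L) {
    theCall <- match.call()
    pAdjMethod <- match.arg(pAdjMethod)
    fwerMethod <- match.arg(fwerMethod)
    if (methods::is(counts, "SummarizedExperiment")) {
        se_ <- counts
        counts <- SummarizedExperiment::assay(se_, 1L)
        if (is.null(metadata))
            metadata <- as.data.frame(SummarizedExperiment::colData(se_))
    }
    validateCountTable(counts)
    al <- alignSamples(counts, metadata)
    counts <- al$counts; metadata <- al$meta

    randomInfo <- .parseRandom(random)
    fixedTerms <- if (inherits(fixed, "formula")) all.vars(fixed) else fixed
    if (!is.null(group) && !group %in% fixedTerms)
        stop("group variable must be among the fixed effects")

    ## zero handling
    zr <- assessZeros(counts,
                      groups = if (structZero && !is.null(group))
                          metadata[[group]] else NULL,
                      threshold = prvCut,
                      useAsymptoticBound = structZeroAsymptotic)
    retained <- names(which(zr@retained))
    if (length(retained) < 2L)
        stop("fewer than 2 taxa retained after zero handling")
    countsRet <- counts[retained, , drop = FALSE]

    ## design
    des <- buildDesign(metadata, fixedTerms, reference)
    X <- des$matrix
    groupCols <- if (!is.null(group))
        which(unname(des$columnToVariable) == group) else integer(0)
    groupLevels <- if (!is.null(group)) levels(des$data[[group]]) else NULL
    subject <- if (!is.null(randomInfo)) {
        if (!randomInfo$subject %in% names(metadata))
            stop("random-effects subject variable not in metadata")
        as.character(metadata[[randomInfo$subject]])
    } else NULL
    slopeZ <- if (!is.null(randomInfo) && !is.null(randomInfo$slope)) {
        if (!randomInfo$slope %in% names(metadata))
            stop("random-slope variable not in metadata")
        as.numeric(metadata[[randomInfo$slope]])
    } else NULL

    ## analysis mode (drives the p-value fed to the sensitivity score)
    mode <- if (trend) "trend"
            else if (dunnett) "dunnett"
            else if (pairwise || (global && !is.null(group))) "global"
            else "covariate"
    if (mode != "covariate" && is.null(group))
        stop("group is required for global/pairwise/dunnett/trend analyses")

    patternSpecs <- NULL
    if (trend) {
        g <- length(groupCols)
        patternSpecs <- lapply(patterns, function(nm) {
            if (grepl("^umbrella:", nm)) {
                buildPattern("umbrella", g,
                             peak = as.integer(sub("^umbrella:", "", nm)))
            } else buildPattern(nm, g)
        })
    }

    core <- .coreFit(countsRet, X, randomInfo = randomInfo,
                     subject = subject, slopeZ = slopeZ, tol = tol,
                     maxIter = maxIter)
    taxa <- rownames(core$betaHat)
    testCols <- setdiff(seq_len(ncol(X)), 1L)
    ctx <- list(mode = mode, testCols = testCols, groupCols = groupCols,
                groupLevels = groupLevels, regularize = regularize, B = B,
                seed = seed, patternSpecs = patternSpecs)

    ## mode-specific analyses on the complete-data fit
    s0use <- if (regularize) core$s0 else NULL
    globalDf <- pairwiseDf <- patternsDf <- NULL
    screenP <- NULL
    if (mode == "global" ||
        (!is.null(group) && global && mode != "trend")) {
        globalDf <- globalTest(core$betaHat, core$sigma, groupCols)
        if (mode == "global")
            screenP <- setNames(globalDf$p, globalDf$taxon)
    }
    if (mode == "dunnett") {
        screenP <- .targetPvalues(core, ctx)
        globalDf <- data.frame(taxon = taxa, W = NA_real_,
                               p = unname(screenP),
                               stringsAsFactors = FALSE)
    }
    mdres <- NULL
    if (pairwise || dunnett) {
        pw <- pairwiseStats(core$betaHat, core$sigma, groupCols,
                            groupLevels = groupLevels, s0 = s0use,
                            referenceOnly = dunnett && !pairwise)
        mdres <- mdfdrProcedure(screenP, pw, alpha = alpha,
                                fwerMethod = fwerMethod)
        pairwiseDf <- mdres$pairwise
    }
    if (trend) {
        patternsDf <- .patternAll(core, ctx)
        screenP <- setNames(patternsDf$p, patternsDf$taxon)
        patternsDf$q <- adjustPvalues(patternsDf$p, pAdjMethod)
    }

    ## per-covariate primary results
    z <- core$betaHat[, testCols, drop = FALSE] /
        sweep(core$se[, testCols, drop = FALSE], 2L,
              if (regularize) core$s0[testCols] else rep(0, length(testCols)),
              "+")
    pMat <- 2 * stats::pnorm(-abs(z))
    qMat <- apply(pMat, 2L, adjustPvalues, method = pAdjMethod)
    if (is.null(dim(qMat))) qMat <- matrix(qMat, ncol = length(testCols))

    ## sensitivity analysis
    sensDf <- NULL
    passed <- matrix(TRUE, length(taxa), length(testCols),
                     dimnames = list(taxa, colnames(X)[testCols]))
    if (ssFilter) {
        completeP <- if (mode == "covariate") pMat else screenP
        fitFun <- function(modCounts) {
            coreMod <- .coreFit(modCounts, X, randomInfo = randomInfo,
                                subject = subject, slopeZ = slopeZ,
                                tol = tol, maxIter = maxIter,
                                emColumns = if (mode == "covariate")
                                    testCols else groupCols,
                                lambdaFixed = if (!is.null(randomInfo))
                                    core$random$lambda else NULL)
            .targetPvalues(coreMod, ctx)
        }
        if (mode == "covariate") {
            scores <- matrix(NA_real_, length(taxa), length(testCols),
                             dimnames = dimnames(passed))
            sens <- matrix(FALSE, length(taxa), length(testCols),
                           dimnames = dimnames(passed))
            exceed <- array(NA, dim = c(length(taxa), length(testCols),
                                        length(pseudoGrid)))
            for (ci in seq_along(pseudoGrid)) {
                modCounts <- countsRet[taxa, , drop = FALSE]
                modCounts[modCounts == 0] <- pseudoGrid[ci]
                exceed[, , ci] <- fitFun(modCounts)[taxa, ] > alpha
            }
            for (k in seq_along(testCols)) {
                sc <- rowMeans(exceed[, k, , drop = FALSE], dims = 1L)
                scores[, k] <- sc
                compSig <- pMat[, k] <= alpha
                unan <- sc %in% c(0, 1)
                agree <- (sc == 0 & compSig) | (sc == 1 & !compSig)
                sens[, k] <- !(unan & agree)
            }
            passed <- !sens
            sensDf <- data.frame(taxon = rep(taxa, length(testCols)),
                                 contrast = rep(colnames(X)[testCols],
                                                each = length(taxa)),
                                 score = as.vector(scores),
                                 sensitive = as.vector(sens),
                                 row.names = NULL, stringsAsFactors = FALSE)
        } else {
            sensDf <- sensitivityAnalysis(
                function(m) fitFun(m), countsRet[taxa, , drop = FALSE],
                completeP = completeP, alpha = alpha,
                pseudoGrid = pseudoGrid)
            sensitive <- setNames(sensDf$sensitive, sensDf$taxon)[taxa]
            passed[, ] <- !sensitive
            ## demote sensitive taxa in the mode-specific results
            if (!is.null(mdres)) {
                bad <- pairwiseDf$taxon %in% taxa[sensitive]
                pairwiseDf$rejected[bad] <- FALSE
                pairwiseDf$direction[bad] <- "none"
                mdres$pairwise <- pairwiseDf
                mdres$screened[taxa[sensitive]] <- FALSE
            }
            if (!is.null(patternsDf))
                patternsDf$passed_ss <- !sensitive
        }
    } else if (!is.null(patternsDf)) {
        patternsDf$passed_ss <- TRUE
    }

    if (!is.null(mdres) && !is.null(globalDf))
        globalDf$screened <- unname(mdres$screened[globalDf$taxon])

    ## assemble the primary results table
    rows <- list()
    for (k in seq_along(testCols)) {
        cn <- colnames(X)[testCols[k]]
        sig <- qMat[, k] <= alpha & passed[, k]
        rows[[k]] <- data.frame(
            taxon = taxa, contrast = cn,
            lfc = core$betaHat[, testCols[k]],
            se = core$se[, testCols[k]],
            W = z[, k], p = pMat[, k], q = qMat[, k],
            passed_ss = passed[, k], structural_zero = FALSE,
            direction = ifelse(sig, ifelse(core$betaHat[, testCols[k]] > 0,
                                           "up", "down"), "none"),
            row.names = NULL, stringsAsFactors = FALSE)
    }
    results <- do.call(rbind, rows)

    ## structural-zero taxa: cataloged, not modeled
    szTaxa <- names(which(zr@structuralDA))
    if (length(szTaxa) && !is.null(group)) {
        sz <- zr@structuralZero
        refLab <- groupLevels[1L]
        for (k in seq_along(groupCols)) {
            lab <- groupLevels[k + 1L]
            dirn <- ifelse(sz[szTaxa, refLab] & !sz[szTaxa, lab], "up",
                    ifelse(!sz[szTaxa, refLab] & sz[szTaxa, lab], "down",
                           "none"))
            results <- rbind(results, data.frame(
                taxon = szTaxa, contrast = colnames(X)[groupCols[k]],
                lfc = NA_real_, se = NA_real_, W = NA_real_, p = NA_real_,
                q = NA_real_, passed_ss = TRUE, structural_zero = TRUE,
                direction = dirn, row.names = NULL, stringsAsFactors = FALSE))
        }
    }

    fit <- new("BCDAFit", betaStar = core$betaStar, betaHat = core$betaHat,
               se = core$se, sigma = core$sigma,
               thetaStar = unname(core$thetaStar),
               thetaHat = unname(core$thetaHat), delta = core$delta,
               mixtures = core$mixtures, s0 = core$s0, X = X,
               mask = core$mask,
               method = if (is.null(randomInfo)) "ml" else "reml",
               converged = core$converged, random = core$random)
    new("BCDAResults", call = theCall, fit = fit, results = results,
        zeroReport = zr, sensitivity = sensDf, global = globalDf,
        pairwise = pairwiseDf, patterns = patternsDf, alpha = alpha,
        variant = if (ssFilter) "ss_filter" else "no_filter")
}
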