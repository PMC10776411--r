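#' Simulation configuration for the Poisson log-normal generator
#'
#' Collects the design of a synthetic microbiome experiment: the log-scale
#' mean vector and covariance of the absolute abundances, the exposure
#' design, the differential-abundance (DA) injection, nuisance variation
#' (per-sample sampling fractions, per-taxon sequencing efficiencies), an
#' optional continuous covariate affecting a subset of taxa, and optional
#' subject-level random effects for repeated measures.
#'
#' Defaults: the log-abundance means form an evenly spaced ladder on
#' [-2, 7.5] (covering rare to dominant taxa); the covariance is a rank-2
#' factor structure plus a diagonal, giving correlated taxa with log-scale
#' variances below ~1.5; log sampling fractions are uniform on [-1, 1]; log
#' sequencing efficiencies are normal with SD 0.5.
#'
#' @param d number of taxa (default 200).
#' @param n number of samples, or samples per group for group designs
#'   (default 30); for repeated measures, subjects (per group).
#' @param exposure "continuous", "binary", or "groups".
#' @param nGroups total number of groups for \code{exposure = "groups"}
#'   (default 3, i.e. reference plus 2).
#' @param propDA fraction of DA taxa in [0, 0.9] (default 0.10).
#' @param effectRange magnitude range of injected log fold-changes
#'   (default c(0.5, 2)); signs are split randomly unless
#'   \code{orderedEffect} is set.
#' @param orderedEffect logical; for 3-group designs, give DA taxa effect
#'   delta for group 2 and delta + 1 for group 3 (all increasing).
#' @param confounder logical; add a continuous covariate affecting a random
#'   10\% of taxa with effects in \code{effectRange}.
#' @param mu optional length-d log-abundance mean vector.
#' @param Sigma optional d x d positive-semidefinite log-scale covariance.
#' @param logSamplingFractionRange range of log sampling fractions
#'   (default c(-1, 1)).
#' @param efficiencySD SD of log taxon efficiencies (default 0.5).
#' @param randomEffects NULL, or list(interceptSD=, slopeSD=, corr=,
#'   obsPerSubject=) for repeated measures (slopeSD may be 0/absent for a
#'   random intercept only; the slope is in the continuous covariate).
#' @param seed integer seed making the whole run reproducible.
#' @return object of class \code{simConfig} (a validated list).
#' @export
simConfig <- function(d = 200L, n = 30L,
                      exposure = c("continuous", "binary", "groups"),
                      nGroups = 3L, propDA = 0.10,
                      effectRange = c(0.5, 2), orderedEffect = FALSE,
                      confounder = FALSE, mu = NULL, Sigma = NULL,
                      logSamplingFractionRange = c(-1, 1),
                      efficiencySD = 0.5, randomEffects = NULL,
                      seed = 1L) {
    exposure <- match.arg(exposure)
    if (propDA < 0 || propDA > 0.9)
        stop("propDA must lie in [0, 0.9]")
    if (!is.null(Sigma)) {
        if (!isSymmetric(unname(Sigma)))
            stop("Sigma must be symmetric")
        ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < -1e-8 * max(abs(ev)))
            stop("Sigma must be positive semidefinite")
    }
    structure(list(d = as.integer(d), n = as.integer(n), exposure = exposure,
                   nGroups = as.integer(nGroups), propDA = propDA,
                   effectRange = effectRange, orderedEffect = orderedEffect,
                   confounder = confounder, mu = mu, Sigma = Sigma,
                   logSamplingFractionRange = logSamplingFractionRange,
                   efficiencySD = efficiencySD,
                   randomEffects = randomEffects, seed = as.integer(seed)),
              class = "simConfig")
}

## default synthetic log-scale parameters
.defaultMu <- function(d) seq(-2, 7.5, length.out = d)

.defaultSigma <- function(d) {
    L <- matrix(stats::rnorm(d * 2L, sd = sqrt(0.2)), d, 2L)
    tcrossprod(L) + diag(stats::runif(d, 0.3, 1))
}

#' Simulate a Poisson log-normal microbiome dataset
#'
#' Draws per-sample log absolute abundances from a multivariate normal (the
#' configured mean plus injected covariate effects, plus subject random
#' effects when configured), then observed counts as Poisson with mean
#' S_i * C_j * A_ij: sampling fraction times sequencing efficiency times
#' absolute abundance, the two bias sources the analysis must remove.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{counts} (taxa x samples integer matrix),
#'   \code{metadata} (data.frame; columns among exposure, group, covariate,
#'   subject), and \code{truth}: list with \code{daTaxa}, \code{beta}
#'   (taxa x effect-columns true log fold-changes), \code{logS},
#'   \code{logC}, \code{mu}, \code{Sigma}.
#' @export
simulatePLN <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    set.seed(config$seed)
    d <- config$d
    mu <- if (is.null(config$mu)) .defaultMu(d) else config$mu
    Sigma <- if (is.null(config$Sigma)) .defaultSigma(d) else config$Sigma
    if (length(mu) != d || nrow(Sigma) != d)
        stop("mu/Sigma dimensions must match d")

    re <- config$randomEffects
    obsPerSubject <- if (is.null(re)) 1L else
        as.integer(re$obsPerSubject %||% 2L)

    ## exposure design (per subject; each subject contributes obsPerSubject
    ## observations)
    if (config$exposure == "continuous") {
        nSubj <- config$n
        groupOf <- NULL
    } else {
        ng <- if (config$exposure == "binary") 2L else config$nGroups
        nSubj <- config$n * ng
        groupOf <- factor(rep(paste0("G", seq_len(ng) - 1L),
                              each = config$n))
    }
    nObs <- nSubj * obsPerSubject
    subject <- rep(seq_len(nSubj), each = obsPerSubject)

    ## covariates
    xCont <- if (config$exposure == "continuous")
        stats::rnorm(nObs) else NULL
    covariate <- if (config$confounder) stats::rnorm(nObs) else NULL

    ## DA taxa and true effects
    nDA <- round(config$propDA * d)
    daTaxa <- sort(sample.int(d, nDA))
    taxaNames <- sprintf("taxon%03d", seq_len(d))

    effectCols <- switch(config$exposure,
        continuous = "exposure",
        binary = "groupG1",
        groups = paste0("groupG", seq_len(config$nGroups - 1L)))
    beta <- matrix(0, d, length(effectCols),
                   dimnames = list(taxaNames, effectCols))
    if (nDA > 0L) {
        mag <- stats::runif(nDA, config$effectRange[1], config$effectRange[2])
        if (config$orderedEffect) {
            if (config$exposure != "groups" || config$nGroups != 3L)
                stop("orderedEffect requires a 3-group design")
            beta[daTaxa, 1L] <- mag
            beta[daTaxa, 2L] <- mag + 1
        } else {
            sgn <- rep(c(1, -1), length.out = nDA)[sample.int(nDA)]
            for (k in seq_along(effectCols))
                beta[daTaxa, k] <- if (k == 1L) mag * sgn else
                    stats::runif(nDA, config$effectRange[1],
                                 config$effectRange[2]) *
                        rep(c(1, -1), length.out = nDA)[sample.int(nDA)]
        }
    }
    betaCov <- NULL
    if (config$confounder) {
        nCov <- max(round(0.10 * d), 1L)
        covTaxa <- sort(sample.int(d, nCov))
        betaCov <- rep(0, d)
        betaCov[covTaxa] <- stats::runif(nCov, config$effectRange[1],
                                         config$effectRange[2]) *
            rep(c(1, -1), length.out = nCov)[sample.int(nCov)]
    }

    ## linear predictor of log absolute abundance
    eta <- matrix(mu, d, nObs)
    if (config$exposure == "continuous") {
        eta <- eta + beta[, 1L] %o% xCont
    } else {
        Gobs <- groupOf[subject]
        for (k in seq_along(effectCols)) {
            ind <- as.numeric(Gobs == paste0("G", k))
            eta <- eta + beta[, k] %o% ind
        }
    }
    if (config$confounder)
        eta <- eta + betaCov %o% covariate

    ## subject random effects on the log scale (per taxon, independent
    ## across taxa)
    if (!is.null(re)) {
        intSD <- re$interceptSD %||% 1
        slpSD <- re$slopeSD %||% 0
        corr <- re$corr %||% 0
        if (slpSD > 0 && is.null(covariate))
            stop("a random slope requires the continuous covariate")
        for (s in seq_len(nSubj)) {
            idx <- which(subject == s)
            a0 <- stats::rnorm(d, sd = intSD)
            if (slpSD > 0) {
                a1 <- corr * (slpSD / intSD) * a0 +
                    stats::rnorm(d, sd = slpSD * sqrt(1 - corr^2))
                eta[, idx] <- eta[, idx] + a0 +
                    a1 %o% covariate[idx]
            } else {
                eta[, idx] <- eta[, idx] + a0
            }
        }
    }

    ## multivariate normal noise across taxa, independent across samples
    ch <- chol(Sigma + diag(1e-10, d))
    eps <- t(ch) %*% matrix(stats::rnorm(d * nObs), d, nObs)
    logA <- eta + eps

    logS <- stats::runif(nObs, config$logSamplingFractionRange[1],
                         config$logSamplingFractionRange[2])
    logC <- stats::rnorm(d, sd = config$efficiencySD)
    lambda <- exp(sweep(logA + logC, 2L, logS, "+"))
    counts <- matrix(stats::rpois(d * nObs, lambda), d, nObs)

    sampleNames <- sprintf("sample%04d", seq_len(nObs))
    dimnames(counts) <- list(taxaNames, sampleNames)
    metadata <- data.frame(row.names = sampleNames)
    if (!is.null(xCont)) metadata$exposure <- xCont
    if (!is.null(groupOf)) metadata$group <- as.character(groupOf[subject])
    if (!is.null(covariate)) metadata$covariate <- covariate
    if (!is.null(re)) metadata$subject <- paste0("S", subject)

    truth <- list(daTaxa = taxaNames[daTaxa], beta = beta,
                  betaCovariate = betaCov, logS = logS, logC = logC,
                  mu = mu, Sigma = Sigma)
    list(counts = counts, metadata = metadata, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate log-scale PLN parameters from a count table
#'
#' Produces a (mu, Sigma) pair usable as \code{\link{simConfig}} inputs from
#' an existing count table: taxa below the prevalence cut are dropped, log
#' counts (zeros excluded) give the per-taxon means, and the covariance is
#' a linearly shrunk sample covariance with a diagonal floor so the result
#' is always positive definite.
#'
#' @param counts taxa-by-samples count matrix.
#' @param minPrevalence prevalence cut (default 0.05).
#' @param shrink shrinkage weight toward the diagonal in [0, 1]
#'   (default 0.2).
#' @return list with \code{mu}, \code{Sigma} and \code{taxa} (names kept).
#' @export
empiricalParams <- function(counts, minPrevalence = 0.05, shrink = 0.2) {
    if (ncol(counts) < 2L)
        stop("at least two samples are required")
    keep <- prevalenceFilter(counts, minPrevalence)
    counts <- counts[keep, , drop = FALSE]
    y <- log(counts)
    y[counts == 0] <- NA_real_
    mu <- rowMeans(y, na.rm = TRUE)
    yc <- y - mu
    yc[is.na(yc)] <- 0
    S <- tcrossprod(yc) / max(ncol(counts) - 1L, 1L)
    Sigma <- (1 - shrink) * S + shrink * diag(pmax(diag(S), 1e-6))
    Sigma <- Sigma + diag(1e-6, nrow(Sigma))
    list(mu = mu, Sigma = Sigma, taxa = rownames(counts))
}
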