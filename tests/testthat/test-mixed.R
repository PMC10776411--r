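# simulated repeated-measures response for a single taxon
mixedToy <- function(nSubj = 40L, obsPer = 2L, intSD = 1, slopeSD = 0,
                     corr = 0, seed = 61) {
    set.seed(seed)
    n <- nSubj * obsPer
    subject <- rep(paste0("S", seq_len(nSubj)), each = obsPer)
    grp <- rep(rep(c("G0", "G1", "G2"), length.out = nSubj), each = obsPer)
    z <- rnorm(n)
    X <- cbind(`(Intercept)` = 1, groupG1 = as.numeric(grp == "G1"),
               groupG2 = as.numeric(grp == "G2"), covariate = z)
    beta <- c(0.3, 1, -0.5, 0.4)
    a0 <- rnorm(nSubj, sd = intSD)
    a1 <- if (slopeSD > 0)
        corr * (slopeSD / intSD) * a0 +
            rnorm(nSubj, sd = slopeSD * sqrt(1 - corr^2)) else rep(0, nSubj)
    idx <- rep(seq_len(nSubj), each = obsPer)
    y <- drop(X %*% beta) + a0[idx] + a1[idx] * z + rnorm(n, sd = 0.6)
    list(y = y, X = X, subject = subject, z = z, grp = grp)
}

test_that("profiled ReML matches lme4 for a random intercept", {
    skip_if_not_installed("lme4")
    toy <- mixedToy()
    ours <- remlFit(toy$y, toy$X, toy$subject)
    df <- data.frame(y = toy$y, grp = toy$grp, z = toy$z,
                     subject = toy$subject)
    lm4 <- lme4::lmer(y ~ grp + z + (1 | subject), data = df, REML = TRUE)
    expect_equal(unname(ours$beta), unname(lme4::fixef(lm4)),
                 tolerance = 1e-5)
    expect_equal(ours$sigma2, lme4::getME(lm4, "sigma")^2, tolerance = 1e-4)
    expect_equal(ours$D[1, 1],
                 as.numeric(lme4::VarCorr(lm4)$subject), tolerance = 1e-3)
    expect_equal(unname(diag(ours$covBeta)),
                 unname(diag(as.matrix(vcov(lm4)))), tolerance = 1e-4)
})

test_that("profiled ReML matches lme4 for intercept plus slope", {
    skip_if_not_installed("lme4")
    toy <- mixedToy(nSubj = 60L, obsPer = 3L, intSD = 1, slopeSD = 1.5,
                    corr = 0.5, seed = 62)
    ours <- remlFit(toy$y, toy$X, toy$subject, z = toy$z)
    df <- data.frame(y = toy$y, grp = toy$grp, z = toy$z,
                     subject = toy$subject)
    lm4 <- suppressWarnings(
        lme4::lmer(y ~ grp + z + (1 + z | subject), data = df, REML = TRUE))
    expect_equal(unname(ours$beta), unname(lme4::fixef(lm4)),
                 tolerance = 1e-3)
    vc <- as.matrix(Matrix::bdiag(lme4::VarCorr(lm4)$subject))
    expect_equal(unname(ours$D), unname(vc), tolerance = 0.05)
})

test_that("without subject effects the ReML fit collapses to least squares", {
    set.seed(63)
    d <- 25L; nSubj <- 30L
    subject <- rep(paste0("S", 1:nSubj), each = 2L)
    x <- rnorm(60)
    X <- cbind(`(Intercept)` = 1, x = x)
    Y <- matrix(rnorm(d * 60, sd = 0.5), d, 60) +
        outer(rnorm(d), x)
    dimnames(Y) <- list(paste0("t", 1:d), paste0("s", 1:60))
    mlFit <- iterativeEstimation(Y, X)
    remlRes <- iterativeReml(Y, X, subject = subject)
    expect_equal(remlRes$betaStar, mlFit$betaStar, tolerance = 0.02)
    ## most taxa should sit at (or near) the zero-variance boundary
    expect_lt(median(unlist(remlRes$lambda)), 0.2)
})

test_that("the random-intercept variance is recovered across taxa", {
    set.seed(64)
    d <- 40L; nSubj <- 50L; obsPer <- 2L
    n <- nSubj * obsPer
    subject <- rep(paste0("S", 1:nSubj), each = obsPer)
    idx <- rep(seq_len(nSubj), each = obsPer)
    x <- rnorm(n)
    X <- cbind(`(Intercept)` = 1, x = x)
    Y <- matrix(0, d, n, dimnames = list(paste0("t", 1:d),
                                         paste0("s", 1:n)))
    for (j in seq_len(d)) {
        a0 <- rnorm(nSubj, sd = 1)
        Y[j, ] <- 0.2 * x + a0[idx] + rnorm(n, sd = 0.8)
    }
    res <- iterativeReml(Y, X, subject = subject)
    Dhat <- vapply(res$D, function(D) D[1, 1], numeric(1))
    ## intercept variance 1, averaged over taxa, within Monte-Carlo error
    expect_lt(abs(mean(Dhat) - 1), 3 * sd(Dhat) / sqrt(d) + 0.1)
    expect_lt(abs(mean(res$sigma2) - 0.64), 0.15)
})

test_that("balanced compound symmetry gives GLS equal to OLS", {
    ## every subject sees the same within-subject design, so GLS and OLS
    ## coefficients coincide classically
    set.seed(65)
    nSubj <- 20L
    subject <- rep(paste0("S", 1:nSubj), each = 2L)
    xw <- rep(c(0, 1), nSubj)        # identical within-subject covariate
    X <- cbind(`(Intercept)` = 1, xw = xw)
    y <- rnorm(2 * nSubj) + rep(rnorm(nSubj, sd = 1.2), each = 2L)
    f <- remlFit(y, X, subject)
    ols <- drop(solve(crossprod(X), crossprod(X, y)))
    expect_equal(unname(f$beta), unname(ols), tolerance = 1e-6)
})

test_that("mixed and fixed pipelines agree when subject variance is absent", {
    set.seed(66)
    sim <- simulatePLN(simConfig(d = 50L, n = 12L, exposure = "groups",
                                 nGroups = 3L, propDA = 0.1,
                                 randomEffects = list(interceptSD = 0.01,
                                                      obsPerSubject = 2L),
                                 seed = 67L))
    resM <- suppressWarnings(
        bcda(sim$counts, sim$metadata, fixed = "group", group = "group",
             random = ~ 1 | subject, pairwise = TRUE, ssFilter = FALSE,
             seed = 5))
    resF <- suppressWarnings(
        bcda(sim$counts, sim$metadata, fixed = "group", group = "group",
             pairwise = TRUE, ssFilter = FALSE, seed = 5))
    pm <- testResults(resM); pf <- testResults(resF)
    shared <- intersect(paste(pm$taxon, pm$contrast),
                        paste(pf$taxon, pf$contrast))
    pm <- pm[match(shared, paste(pm$taxon, pm$contrast)), ]
    pf <- pf[match(shared, paste(pf$taxon, pf$contrast)), ]
    expect_equal(pm$lfc, pf$lfc, tolerance = 0.05)
    expect_lt(median(abs(pm$p - pf$p), na.rm = TRUE), 0.03)
})
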