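# shared toy fit: 4 taxa, intercept + two group indicators
toyGroupFit <- function() {
    beta <- rbind(c(0.1, 0.0, 0.0),
                  c(0.2, 1.0, -1.0),
                  c(0.0, 2.0, 2.5),
                  c(-0.1, -0.8, 0.3))
    dimnames(beta) <- list(paste0("t", 1:4),
                           c("(Intercept)", "groupG1", "groupG2"))
    sigma <- array(0, dim = c(3, 3, 4),
                   dimnames = list(colnames(beta), colnames(beta),
                                   rownames(beta)))
    for (j in 1:4) sigma[, , j] <- diag(c(0.02, 0.5, 0.5))
    list(beta = beta, sigma = sigma)
}

test_that("the global test is the identity-contrast Wald test", {
    fit <- toyGroupFit()
    gt <- globalTest(fit$beta, fit$sigma, groupCols = 2:3)
    ## zero group effects give W = 0, p = 1
    expect_equal(gt$W[1], 0)
    expect_equal(gt$p[1], 1)
    ## three groups: A = I2 on (beta1, beta2)
    for (j in 2:4) {
        wt <- waldTest(fit$beta[j, 2:3], fit$sigma[2:3, 2:3, j],
                       A = diag(2), beta0 = c(0, 0))
        expect_equal(gt$W[j], wt$W)
        expect_equal(gt$p[j], wt$p)
    }
    expect_equal(gt$W[2], (1^2 + 1^2) / 0.5)
})

test_that("pairwise statistics use diagonal variances and the reference", {
    fit <- toyGroupFit()
    pw <- pairwiseStats(fit$beta, fit$sigma, groupCols = 2:3,
                        groupLevels = c("G0", "G1", "G2"))
    ## g = 2 gives g(g+1)/2 = 3 contrasts per taxon
    expect_equal(nrow(pw), 3L * 4L)

    ## reference comparison: W_10 = beta1 / se(beta1)
    r <- pw[pw$taxon == "t2" & pw$k == "G1" & pw$kprime == "G0", ]
    expect_equal(r$W, 1 / sqrt(0.5))

    ## beta = (1, -1), both variances 0.5: W_21 = -2, p = 2(1 - Phi(2))
    r2 <- pw[pw$taxon == "t2" & pw$k == "G2" & pw$kprime == "G1", ]
    expect_equal(r2$W, -2)
    expect_equal(r2$p, 2 * (1 - pnorm(2)), tolerance = 1e-12)

    ## equal coefficients give W = 0, p = 1
    r0 <- pw[pw$taxon == "t1" & pw$kprime == "G1", ]
    expect_equal(r0$W, 0)
    expect_equal(r0$p, 1)

    ## reference-only mode returns g contrasts per taxon
    pwRef <- pairwiseStats(fit$beta, fit$sigma, groupCols = 2:3,
                           referenceOnly = TRUE)
    expect_equal(nrow(pwRef), 2L * 4L)

    ## regularization adds to each standard error before combining
    pwReg <- pairwiseStats(fit$beta, fit$sigma, groupCols = 2:3,
                           groupLevels = c("G0", "G1", "G2"), s0 = 0.1)
    rr <- pwReg[pwReg$taxon == "t2" & pwReg$k == "G2" &
                pwReg$kprime == "G1", ]
    expect_equal(rr$se, sqrt(2 * (sqrt(0.5) + 0.1)^2))

    badSigma <- fit$sigma; badSigma[2, 2, 1] <- 0
    expect_error(pairwiseStats(fit$beta, badSigma, groupCols = 2:3),
                 "non-positive variance")
})

test_that("the three-step mdFDR procedure screens, tests and signs", {
    ## hand-traced d = 2 example: screening p (0.001, 0.9) at alpha 0.05
    ## gives R = 1, so the discovered taxon's pairwise tests run at
    ## level 1 * 0.05 / 2 = 0.025
    screenP <- c(t1 = 0.001, t2 = 0.9)
    pw <- data.frame(
        taxon = rep(c("t1", "t2"), each = 3),
        k = rep(c("G1", "G2", "G2"), 2),
        kprime = rep(c("G0", "G0", "G1"), 2),
        W = c(3.5, -0.5, -3.1, 4, 4, 4),
        p = c(0.0004, 0.6, 0.002, 1e-6, 1e-6, 1e-6))
    md <- mdfdrProcedure(screenP, pw, alpha = 0.05)
    expect_equal(md$R, 1L)
    expect_equal(unname(md$screened), c(TRUE, FALSE))
    ## Holm within t1: sorted p (0.0004, 0.002, 0.6) -> adjusted
    ## (0.0012, 0.004, 0.6); the first two pass 0.025
    expect_equal(md$pairwise$rejected[1:3], c(TRUE, FALSE, TRUE))
    expect_equal(md$pairwise$direction[1:3], c("up", "none", "down"))
    ## taxon t2 was not screened: no rejections despite tiny p
    expect_false(any(md$pairwise$rejected[4:6]))

    ## all screening p = 1: nothing anywhere
    md0 <- mdfdrProcedure(c(t1 = 1, t2 = 1), pw, alpha = 0.05)
    expect_equal(md0$R, 0L)
    expect_false(any(md0$pairwise$rejected))
})

test_that("mdFDR rejections are monotone in the pairwise p-values", {
    screenP <- c(t1 = 0.001, t2 = 0.002, t3 = 0.8)
    pw <- data.frame(taxon = rep(c("t1", "t2", "t3"), each = 1),
                     k = "G1", kprime = "G0",
                     W = c(3, 3, 3), p = c(0.01, 0.02, 0.5))
    md1 <- mdfdrProcedure(screenP, pw, alpha = 0.1)
    pw2 <- pw; pw2$p[2] <- 0.001
    md2 <- mdfdrProcedure(screenP, pw2, alpha = 0.1)
    expect_true(all(md2$pairwise$rejected >= md1$pairwise$rejected))
})

test_that("the Dunnett screen matches closed forms for max |N(0,1)|", {
    ## g = 1 reduces to the two-sided normal tail
    W1 <- matrix(c(1.96, 0), ncol = 1)
    p <- dunnettScreen(W1, B = 1e5, seed = 5)
    expect_lt(abs(p[1] - 2 * (1 - pnorm(1.96))),
              3 * sqrt(0.05 * 0.95 / 1e5))
    expect_gt(p[2], 0.99)

    ## g = 2: P(max |Z| > w) = 1 - (2 Phi(w) - 1)^2
    W2 <- matrix(c(2.5, 0.2), ncol = 2)
    p2 <- dunnettScreen(W2, B = 1e5, seed = 6)
    target <- 1 - (2 * pnorm(2.5) - 1)^2
    expect_lt(abs(p2[1] - target), 3 * sqrt(target * (1 - target) / 1e5))

    ## deterministic given the seed
    expect_identical(dunnettScreen(W2, B = 1000, seed = 7),
                     dunnettScreen(W2, B = 1000, seed = 7))
})

test_that("mdFDR is controlled under a global null (statistic-level simulation)", {
    ## simulate the testing layer directly: d taxa, g = 2 group effects,
    ## true beta = 0, independent normal estimates with known SEs
    set.seed(303)
    nRep <- 100L; d <- 50L; alpha <- 0.05
    errs <- numeric(nRep)
    for (r in seq_len(nRep)) {
        se <- matrix(runif(d * 2, 0.2, 0.5), d, 2)
        betaHat <- cbind(0, matrix(rnorm(d * 2), d, 2) * se)
        colnames(betaHat) <- c("(Intercept)", "groupG1", "groupG2")
        rownames(betaHat) <- paste0("t", seq_len(d))
        sigma <- array(0, dim = c(3, 3, d))
        for (j in seq_len(d))
            sigma[, , j] <- diag(c(0.01, se[j, ]^2))
        gt <- globalTest(betaHat, sigma, 2:3)
        pw <- pairwiseStats(betaHat, sigma, 2:3,
                            groupLevels = c("G0", "G1", "G2"))
        md <- mdfdrProcedure(setNames(gt$p, gt$taxon), pw, alpha = alpha)
        errTaxa <- unique(md$pairwise$taxon[md$pairwise$rejected])
        errs[r] <- length(errTaxa) / max(md$R, 1L)
    }
    mcse <- sd(errs) / sqrt(nRep)
    expect_lte(mean(errs), alpha + 3 * mcse)
})
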