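test_that("log-count centering masks zeros and centers observed entries", {
    e <- exp(1)
    counts <- rbind(c(e, e, e), c(1, e^2, e), c(2, 0, 8))
    dimnames(counts) <- list(paste0("t", 1:3), paste0("s", 1:3))
    cl <- centerLogCounts(counts)
    expect_equal(unname(cl$y["t1", ]), c(0, 0, 0))
    expect_equal(unname(cl$y["t2", ]), c(-1, 1, 0))
    expect_equal(unname(cl$y["t3", ]), c(-log(2), NA, log(2)))
    expect_true(all(abs(rowMeans(cl$y, na.rm = TRUE)) < 1e-10))

    ## fewer than two positive samples: excluded with a warning
    sparse <- makeCounts(rbind(c(1, 0, 0), c(2, 3, 4)))
    expect_warning(cl2 <- centerLogCounts(sparse), "fewer than 2")
    expect_equal(rownames(cl2$y), "t2")
})

test_that("noise-free data recovers coefficients exactly", {
    set.seed(11)
    X <- cbind(1, rnorm(6), rep(c(0, 1), 3))
    colnames(X) <- c("(Intercept)", "x", "g")
    Bcoef <- matrix(rnorm(10), 5, 2) %*% rbind(c(1, 0, 0), c(0, 1, 1))
    Bcoef <- cbind(rnorm(5), matrix(rnorm(10), 5, 2))
    Y <- noiseFreeY(X, Bcoef)
    fit <- iterativeEstimation(Y, X, tol = 1e-12)
    expect_true(fit$converged)
    expect_equal(max(abs(fit$thetaStar)), 0, tolerance = 1e-10)
    expect_equal(unname(fit$betaStar), unname(Bcoef), tolerance = 1e-10)
})

test_that("a design-space sampling fraction becomes a shared coefficient bias", {
    set.seed(12)
    X <- cbind(1, rnorm(6), runif(6))
    delta <- c(0, 1.3, -0.7)          # bias direction within the design space
    s <- drop(X %*% delta)
    Bcoef <- cbind(rnorm(5), matrix(rnorm(10), 5, 2))
    Y <- noiseFreeY(X, Bcoef, theta = s)
    fit <- iterativeEstimation(Y, X, tol = 1e-12)
    shift <- fit$betaStar - Bcoef
    ## the same additive bias for every taxon
    expect_lt(max(apply(shift, 2, function(col) diff(range(col)))), 1e-8)
})

test_that("the converged solution satisfies the fixed-point equations", {
    sim <- smallSim()
    keep <- prevalenceFilter(sim$counts, 0.10)
    cl <- centerLogCounts(sim$counts[keep, ])
    X <- cbind(`(Intercept)` = 1, exposure = sim$metadata$exposure)
    fit <- iterativeEstimation(cl$y, X, tol = 1e-10)
    ## theta equation: per-sample mean residual over observed taxa
    resid <- cl$y - fit$betaStar %*% t(X)
    expect_equal(unname(fit$thetaStar),
                 unname(colMeans(resid, na.rm = TRUE)), tolerance = 1e-8)
    ## beta equation: per-taxon least squares on the corrected responses
    for (j in c(1L, 7L, nrow(cl$y))) {
        obs <- which(!is.na(cl$y[j, ]))
        Xo <- X[obs, , drop = FALSE]
        bj <- solve(crossprod(Xo),
                    crossprod(Xo, cl$y[j, obs] - fit$thetaStar[obs]))
        expect_equal(unname(fit$betaStar[j, ]), unname(drop(bj)),
                     tolerance = 1e-8)
    }
})

test_that("scaling one taxon's counts changes nothing downstream", {
    ## multiplying a taxon's counts by a constant is a sequencing-efficiency
    ## change; per-taxon centering removes it exactly
    sim <- smallSim()
    keep <- prevalenceFilter(sim$counts, 0.10)
    counts <- sim$counts[keep, ]
    scaled <- counts
    scaled[4L, ] <- scaled[4L, ] * 16L
    X <- cbind(`(Intercept)` = 1, exposure = sim$metadata$exposure)
    cl1 <- centerLogCounts(counts)
    cl2 <- centerLogCounts(scaled)
    expect_equal(cl1$y, cl2$y, tolerance = 1e-12)
    f1 <- iterativeEstimation(cl1$y, X)
    f2 <- iterativeEstimation(cl2$y, X)
    expect_equal(f1$betaStar, f2$betaStar, tolerance = 1e-12)
})

test_that("sandwich covariance matches OLS covariance under homoskedasticity", {
    set.seed(13)
    n <- 400L; d <- 60L
    X <- cbind(1, rnorm(n))
    sigma <- 0.7
    Y <- matrix(rnorm(d * n, sd = sigma), d, n)
    dimnames(Y) <- list(paste0("t", 1:d), paste0("s", 1:n))
    theta0 <- rep(0, n)
    B0 <- matrix(0, d, 2)
    sig <- estimateSigma(Y, X, theta0, B0)
    ols <- sigma^2 * solve(crossprod(X))
    avg <- apply(sig, c(1, 2), mean)
    expect_equal(unname(avg), unname(ols), tolerance = 0.1)

    ## zero residuals give a zero matrix
    B3 <- cbind(rnorm(3), rnorm(3))
    Yfit <- noiseFreeY(X, B3)
    sig0 <- estimateSigma(Yfit, X, rep(0, n), B3)
    expect_equal(max(abs(sig0)), 0, tolerance = 1e-12)
})

test_that("EM recovers a pure null component and a planted bias", {
    ## all coefficients equal with tiny spread: the null component takes all
    x <- rep(2.5, 60)
    fit <- emBiasCorrection(x, rep(1e-6, 60))
    expect_equal(fit@delta, 2.5, tolerance = 1e-3)
    expect_gt(fit@pi[1], 0.99)

    ## planted bias delta = 1.5 under the three-component generative model
    set.seed(21)
    d <- 500L
    comp <- sample(0:2, d, replace = TRUE, prob = c(0.7, 0.15, 0.15))
    nu0 <- runif(d, 0.05, 0.15)
    x <- 1.5 + ifelse(comp == 1, -2, ifelse(comp == 2, 2, 0)) +
        rnorm(d, sd = nu0 + ifelse(comp == 0, 0, 0.3))
    fit2 <- emBiasCorrection(x, nu0^2)
    ## Monte-Carlo SE of a location estimate at this d is below 0.03
    expect_lt(abs(fit2@delta - 1.5), 3 * 0.03)
    expect_true(validObject(fit2))
})

test_that("EM bias estimation is sign-symmetric", {
    set.seed(22)
    d <- 300L
    comp <- sample(0:2, d, replace = TRUE, prob = c(0.8, 0.1, 0.1))
    nu0 <- runif(d, 0.05, 0.2)
    x <- 0.4 + ifelse(comp == 1, -1.5, ifelse(comp == 2, 1.5, 0)) +
        rnorm(d, sd = nu0)
    f1 <- emBiasCorrection(x, nu0^2)
    f2 <- emBiasCorrection(-x, nu0^2)
    expect_equal(f2@delta, -f1@delta, tolerance = 1e-6)
    expect_equal(f2@l1, -f1@l2, tolerance = 1e-6)
    expect_equal(f2@l2, -f1@l1, tolerance = 1e-6)
    expect_equal(f2@pi[2], f1@pi[3], tolerance = 1e-6)
    expect_equal(f2@kappa1, f1@kappa2, tolerance = 1e-5)
})

test_that("final estimates subtract the bias and satisfy the theta identity", {
    sim <- smallSim()
    keep <- prevalenceFilter(sim$counts, 0.10)
    cl <- centerLogCounts(sim$counts[keep, ])
    X <- cbind(`(Intercept)` = 1, exposure = sim$metadata$exposure)
    fit <- iterativeEstimation(cl$y, X)

    fin0 <- finalizeEstimates(fit$betaStar, c(0, 0), cl$y, X)
    expect_identical(fin0$betaHat, fit$betaStar)

    fin <- finalizeEstimates(fit$betaStar, c(99, 0.37), cl$y, X)
    ## the intercept is never bias-corrected
    expect_equal(fin$betaHat[, 1], fit$betaStar[, 1])
    expect_equal(fin$betaHat[, 2], fit$betaStar[, 2] - 0.37)
    resid <- cl$y - fin$betaHat %*% t(X)
    expect_equal(unname(fin$thetaHat),
                 unname(colMeans(resid, na.rm = TRUE)), tolerance = 1e-8)
})

test_that("Wald tests match chi-square and regularized z forms", {
    beta <- c(0.5, 1.2, -0.4)
    sigma <- diag(c(0.04, 0.09, 0.01))
    ## null contrast value gives W = 0, p = 1
    wt0 <- waldTest(beta, sigma, A = c(0, 1, 0), beta0 = 1.2)
    expect_equal(wt0$W, 0)
    expect_equal(wt0$p, 1)

    ## chi-square with W = 3.84, q = 1 sits at p ~ 0.05
    expect_equal(stats::pchisq(3.84, 1, lower.tail = FALSE), 0.05,
                 tolerance = 1e-3)
    z <- waldTest(beta, sigma, A = c(0, 1, 0))
    expect_equal(z$W, 1.2 / 0.3)
    expect_equal(z$p, 2 * pnorm(-4))

    ## regularization adds to the denominator
    zr <- waldTest(beta, sigma, A = c(0, 1, 0), s0 = 0.1)
    expect_equal(zr$W, 1.2 / 0.4)

    ## vector contrast: identity on two coefficients
    w2 <- waldTest(beta, sigma, A = rbind(c(0, 1, 0), c(0, 0, 1)))
    expect_equal(w2$df, 2L)
    expect_equal(w2$W, 1.2^2 / 0.09 + 0.4^2 / 0.01)
})

test_that("p-value adjustment implements step-down Holm and BH", {
    expect_equal(adjustPvalues(0.03), 0.03)
    expect_equal(adjustPvalues(c(0.01, 0.04)), c(0.02, 0.04))
    expect_equal(adjustPvalues(rep(1, 5)), rep(1, 5))
    expect_equal(adjustPvalues(c(0.01, 0.04), method = "bh"),
                 p.adjust(c(0.01, 0.04), "BH"))
})
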