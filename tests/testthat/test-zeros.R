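test_that("structural zeros follow the two-group truth table", {
    groups <- c("A", "A", "B", "B")
    ## enumerate the all-zero patterns for two groups
    counts <- makeCounts(rbind(
        c(0L, 0L, 3L, 5L),   # absent in A only -> structural DA
        c(2L, 1L, 0L, 0L),   # absent in B only -> structural DA
        c(0L, 0L, 0L, 0L),   # absent everywhere -> flagged, not DA
        c(4L, 0L, 2L, 7L)))  # present in both -> nothing
    zr <- detectStructuralZeros(counts, groups)
    expect_equal(unname(zr@structuralZero[, "A"]), c(TRUE, FALSE, TRUE, FALSE))
    expect_equal(unname(zr@structuralZero[, "B"]), c(FALSE, TRUE, TRUE, FALSE))
    expect_equal(unname(zr@structuralDA), c(TRUE, TRUE, FALSE, FALSE))
    expect_false(zr@retained["t3"])  # absent everywhere is dropped

    expect_error(detectStructuralZeros(counts, factor(groups,
                                                      levels = c("A", "B", "C"))),
                 "at least one sample")
})

test_that("the asymptotic bound also flags vanishing presence proportions", {
    n <- 40L
    counts <- makeCounts(matrix(c(rep(0L, n), 1L, rep(0L, n - 1L)),
                                nrow = 2L, byrow = TRUE),
                         samples = paste0("s", 1:n))
    groups <- rep(c("A", "B"), each = n / 2L)
    ## taxon 2 present once in group A: default rule keeps it non-structural,
    ## the lower-bound rule declares it absent
    strict <- detectStructuralZeros(counts, groups)
    expect_false(strict@structuralZero["t2", "A"])
    loose <- detectStructuralZeros(counts, groups, useAsymptoticBound = TRUE)
    expect_true(loose@structuralZero["t2", "A"])
})

test_that("prevalence filtering is boundary-inclusive", {
    n <- 20L
    counts <- makeCounts(rbind(
        c(5L, rep(0L, n - 1L)),          # 1/20 = 0.05
        c(3L, 2L, rep(0L, n - 2L)),      # 2/20 = 0.10 exactly
        rep(1L, n)), samples = paste0("s", 1:n))
    keep <- prevalenceFilter(counts, 0.10)
    expect_equal(unname(keep), c(FALSE, TRUE, TRUE))
    expect_true(all(prevalenceFilter(counts, 0)))
})

test_that("zero reports respond to presence/absence only", {
    sim <- smallSim()
    groups <- rep(c("A", "B"), length.out = ncol(sim$counts))
    zr1 <- assessZeros(sim$counts, groups)
    zr2 <- assessZeros(sim$counts * 2L, groups)
    expect_identical(zr1@structuralZero, zr2@structuralZero)
    expect_identical(zr1@prevalence, zr2@prevalence)
    expect_identical(zr1@retained, zr2@retained)

    ## within-group sample permutation leaves the structural calls unchanged
    idxA <- which(groups == "A"); idxB <- which(groups == "B")
    perm <- seq_along(groups)
    perm[idxA] <- sample(idxA); perm[idxB] <- sample(idxB)
    zr3 <- detectStructuralZeros(sim$counts[, perm], groups[perm])
    expect_identical(zr3@structuralZero,
                     detectStructuralZeros(sim$counts, groups)@structuralZero)
})

test_that("sensitivity scores follow the unanimity-and-agreement rule", {
    counts <- makeCounts(rbind(
        c(5L, 8L, 7L, 6L),    # zero-free: pseudo-counts are a no-op
        c(0L, 9L, 4L, 0L)))
    pCalls <- list(
        always = function(m) setNames(c(0.5, 0.5), rownames(counts)))
    res <- sensitivityAnalysis(pCalls$always, counts,
                               completeP = setNames(c(0.5, 0.5),
                                                    rownames(counts)),
                               alpha = 0.05,
                               pseudoGrid = seq(0.01, 0.05, by = 0.01))
    expect_equal(res$score, c(1, 1))
    expect_equal(res$sensitive, c(FALSE, FALSE))

    ## a non-unanimous verdict is sensitive regardless of the complete fit
    flip <- local({
        i <- 0
        function(m) {
            i <<- i + 1
            setNames(c(0.5, if (i %% 2) 0.001 else 0.9), rownames(counts))
        }
    })
    res2 <- sensitivityAnalysis(flip, counts,
                                completeP = setNames(c(0.5, 0.01),
                                                     rownames(counts)),
                                alpha = 0.05,
                                pseudoGrid = seq(0.01, 0.05, by = 0.01))
    expect_true(res2$sensitive[2])
    expect_true(res2$score[2] > 0 && res2$score[2] < 1)

    ## unanimous but contradicting the complete-data verdict is sensitive
    res3 <- sensitivityAnalysis(pCalls$always, counts,
                                completeP = setNames(c(0.01, 0.5),
                                                     rownames(counts)),
                                alpha = 0.05,
                                pseudoGrid = seq(0.01, 0.05, by = 0.01))
    expect_true(res3$sensitive[1])

    expect_error(sensitivityAnalysis(pCalls$always, counts,
                                     completeP = setNames(c(0.5, 0.5),
                                                          rownames(counts)),
                                     pseudoGrid = c(0, 0.1)),
                 "strictly positive")
})

test_that("the default pseudo-count grid spans 0.01 to 0.50 in 50 steps", {
    grid <- eval(formals(sensitivityAnalysis)$pseudoGrid)
    expect_equal(length(grid), 50L)
    expect_equal(min(grid), 0.01)
    expect_equal(max(grid), 0.50)
    expect_equal(grid, eval(formals(bcda)$pseudoGrid))
})
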