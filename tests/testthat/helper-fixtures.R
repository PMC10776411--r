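# Shared fixtures built in code: tiny count tables and a small PLN dataset
# reused across test files.

makeCounts <- function(mat, taxa = NULL, samples = NULL) {
    m <- as.matrix(mat)
    rownames(m) <- taxa %||% paste0("t", seq_len(nrow(m)))
    colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
    storage.mode(m) <- "integer"
    m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small deterministic PLN dataset shared by pipeline-level tests
smallSim <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- simulatePLN(simConfig(d = 60L, n = 20L,
                                            exposure = "continuous",
                                            propDA = 0.1, seed = 101L))
        cache
    }
})

# noise-free response matrix y = theta + X b per taxon (no masking)
noiseFreeY <- function(X, Bcoef, theta = rep(0, nrow(X))) {
    Y <- Bcoef %*% t(X) + rep(theta, each = nrow(Bcoef))
    rownames(Y) <- paste0("t", seq_len(nrow(Y)))
    colnames(Y) <- paste0("s", seq_len(ncol(Y)))
    Y
}
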