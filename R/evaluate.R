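#' FDR and power of a set of differential-abundance calls
#'
#' @param discovered logical vector (or character vector of taxon names)
#'   of discoveries.
#' @param daTaxa character vector of truly differential taxa.
#' @param taxa character vector of all tested taxa (required when
#'   \code{discovered} is logical and unnamed).
#' @return list with \code{fdr} (false discoveries over max(discoveries, 1))
#'   and \code{power} (true discoveries over the number of DA taxa; NA when
#'   there are none).
#' @export
fdrPower <- function(discovered, daTaxa, taxa = NULL) {
    if (is.logical(discovered)) {
        if (is.null(names(discovered))) {
            if (is.null(taxa)) stop("taxa required for unnamed logical calls")
            names(discovered) <- taxa
        }
        discovered <- names(discovered)[discovered]
    }
    nDisc <- length(discovered)
    fd <- sum(!discovered %in% daTaxa)
    list(fdr = fd / max(nDisc, 1L),
         power = if (length(daTaxa)) mean(daTaxa %in% discovered) else
             NA_real_)
}

#' Mixed directional FDR and power of a pairwise-comparison result
#'
#' Scores the output of \code{\link{mdfdrProcedure}} against simulation
#' truth. A screened taxon commits an error (V(j) = 1) when any of its
#' rejected pairwise hypotheses is a type-I error (the true difference is
#' zero) or a directional error (the declared sign contradicts the true
#' difference); the mdFDR estimate is the number of erring taxa over
#' max(R, 1). Discovery is the step-1 screening event (that is what R
#' counts), so power is the fraction of truly DA taxa discovered in the
#' screen; when the screening indicator is absent, a taxon counts as
#' discovered if it has at least one correct pairwise rejection.
#'
#' @param mdres result of \code{\link{mdfdrProcedure}} (a list with
#'   \code{pairwise}, \code{R} and optionally \code{screened}).
#' @param trueBetaGroups matrix taxa x g of true group effects relative to
#'   the reference; column names must match the group labels used in the
#'   pairwise table (the reference label maps to 0).
#' @param daTaxa character vector of truly DA taxa.
#' @param referenceLabel label of the reference group (default the unique
#'   \code{kprime} label absent from \code{colnames(trueBetaGroups)}).
#' @return list with \code{mdfdr}, \code{power}, \code{R}.
#' @export
mdfdrEval <- function(mdres, trueBetaGroups, daTaxa,
                      referenceLabel = NULL) {
    pw <- mdres$pairwise
    labs <- unique(c(pw$k, pw$kprime))
    if (is.null(referenceLabel))
        referenceLabel <- setdiff(labs, colnames(trueBetaGroups))[1L]
    trueEff <- function(taxon, lab) {
        if (lab == referenceLabel) 0 else trueBetaGroups[taxon, lab]
    }
    rej <- pw[pw$rejected, , drop = FALSE]
    err <- correct <- character(0)
    if (nrow(rej)) {
        diffTrue <- vapply(seq_len(nrow(rej)), function(r)
            trueEff(rej$taxon[r], rej$k[r]) -
                trueEff(rej$taxon[r], rej$kprime[r]), numeric(1))
        isErr <- diffTrue == 0 |
            (diffTrue > 0 & rej$direction != "up") |
            (diffTrue < 0 & rej$direction != "down")
        err <- unique(rej$taxon[isErr])
        correct <- unique(rej$taxon[!isErr])
    }
    discovered <- if (!is.null(mdres$screened))
        names(which(mdres$screened)) else correct
    list(mdfdr = length(err) / max(mdres$R, 1L),
         power = if (length(daTaxa)) mean(daTaxa %in% discovered) else
             NA_real_,
         R = mdres$R)
}

#' Run seeded simulation replicates and aggregate metrics
#'
#' @param configFactory function(seed) returning a \code{\link{simConfig}}.
#' @param methodFun function(sim, seed) returning a named numeric vector of
#'   replicate-level metrics.
#' @param nReps number of replicates (at least 2).
#' @param seed master seed; replicate r uses \code{seed + stride * (r - 1)}.
#' @param stride seed stride between replicates (default 1000).
#' @return list with \code{summary} (data.frame metric/mean/se/nReps) and
#'   \code{replicates} (matrix of per-replicate metrics), plus
#'   \code{nFailed}.
#' @export
replicateRunner <- function(configFactory, methodFun, nReps, seed,
                            stride = 1000L) {
    if (nReps < 2L) stop("nReps must be at least 2")
    rows <- vector("list", nReps)
    nFailed <- 0L
    for (r in seq_len(nReps)) {
        repSeed <- as.integer(seed + stride * (r - 1L))
        res <- tryCatch({
            sim <- simulatePLN(configFactory(repSeed))
            methodFun(sim, repSeed)
        }, error = function(e) {
            warning("replicate ", r, " failed: ", conditionMessage(e))
            NULL
        })
        if (is.null(res)) nFailed <- nFailed + 1L else rows[[r]] <- res
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) stop("all replicates failed")
    mat <- do.call(rbind, rows)
    mean_ <- colMeans(mat, na.rm = TRUE)
    se_ <- apply(mat, 2L, function(x)
        stats::sd(x, na.rm = TRUE) / sqrt(sum(is.finite(x))))
    list(summary = data.frame(metric = colnames(mat), mean = mean_,
                              se = se_, nReps = nrow(mat),
                              row.names = NULL, stringsAsFactors = FALSE),
         replicates = mat, nFailed = nFailed)
}
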