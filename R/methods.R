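#' Extract the per-taxon per-contrast test table
#'
#' @param object a \linkS4class{BCDAResults}.
#' @param ... unused.
#' @return A data.frame with one row per taxon per contrast.
#' @rdname testResults
#' @export
setMethod("testResults", "BCDAResults", function(object, ...) object@results)

#' Estimated log sampling fractions
#'
#' Per-sample estimates of the (centered) log sampling fraction, the nuisance
#' that links observed counts to ecosystem abundances.
#'
#' @param object a \linkS4class{BCDAFit} or \linkS4class{BCDAResults}.
#' @param ... unused.
#' @return Named numeric vector, one value per sample.
#' @rdname sampleFractions
#' @export
setMethod("sampleFractions", "BCDAFit", function(object, ...) {
    setNames(object@thetaHat, colnames(object@mask))
})

#' @rdname sampleFractions
#' @export
setMethod("sampleFractions", "BCDAResults", function(object, ...)
    sampleFractions(object@fit))

#' Per-covariate bias (mixture) estimates
#'
#' @param object a \linkS4class{BCDAFit} or \linkS4class{BCDAResults}.
#' @param ... unused.
#' @return Named list of \linkS4class{MixtureFit} objects, one per
#'   bias-corrected design column.
#' @rdname biasEstimates
#' @export
setMethod("biasEstimates", "BCDAFit", function(object, ...) object@mixtures)

#' @rdname biasEstimates
#' @export
setMethod("biasEstimates", "BCDAResults", function(object, ...)
    biasEstimates(object@fit))

#' Zero-handling report accessor
#'
#' @param object a \linkS4class{BCDAResults}.
#' @param ... unused.
#' @return The \linkS4class{ZeroReport} computed during the analysis.
#' @rdname zeroReport
#' @export
setMethod("zeroReport", "BCDAResults", function(object, ...) object@zeroReport)

#' Taxa retained for model-based analysis
#'
#' @param object a \linkS4class{ZeroReport} or \linkS4class{BCDAResults}.
#' @param ... unused.
#' @return Character vector of retained taxon names.
#' @rdname retainedTaxa
#' @export
setMethod("retainedTaxa", "ZeroReport", function(object, ...) {
    names(which(object@retained))
})

#' @rdname retainedTaxa
#' @export
setMethod("retainedTaxa", "BCDAResults", function(object, ...)
    retainedTaxa(object@zeroReport))

#' @describeIn BCDAFit bias-corrected coefficient matrix (taxa x
#'   coefficients).
#' @param object a \linkS4class{BCDAFit}.
#' @export
setMethod("coef", "BCDAFit", function(object) object@betaHat)

setMethod("show", "ZeroReport", function(object) {
    cat("ZeroReport\n")
    cat("  taxa:", length(object@prevalence), "\n")
    if (ncol(object@structuralZero) > 0L) {
        cat("  groups:", ncol(object@structuralZero), "\n")
        cat("  structural-zero DA taxa:", sum(object@structuralDA), "\n")
    } else {
        cat("  groups: none (structural zeros not assessed)\n")
    }
    cat("  prevalence threshold:", object@threshold, "\n")
    cat("  retained for modeling:", sum(object@retained), "\n")
    invisible(NULL)
})

setMethod("show", "MixtureFit", function(object) {
    cat("MixtureFit (3-component Gaussian mixture)\n")
    cat(sprintf("  delta: %.4g\n", object@delta))
    cat(sprintf("  pi: %.3f / %.3f / %.3f (null / down / up)\n",
                object@pi[1], object@pi[2], object@pi[3]))
    cat(sprintf("  l1: %.4g  l2: %.4g  kappa1: %.4g  kappa2: %.4g\n",
                object@l1, object@l2, object@kappa1, object@kappa2))
    cat(sprintf("  converged: %s (%d iterations)\n",
                object@converged, object@nIter))
    invisible(NULL)
})

setMethod("show", "BCDAFit", function(object) {
    cat(sprintf("BCDAFit (%s)\n",
                if (object@method == "ml") "fixed effects" else
                    "mixed effects, ReML"))
    cat("  taxa:", nrow(object@betaStar), " samples:", ncol(object@mask), "\n")
    cat("  coefficients:", paste(colnames(object@betaStar), collapse = ", "),
        "\n")
    dk <- object@delta[object@delta != 0]
    if (length(dk))
        cat("  bias corrections:",
            paste(sprintf("%s=%.3g", names(dk), dk), collapse = ", "), "\n")
    cat("  sampling-fraction iteration converged:", object@converged, "\n")
    invisible(NULL)
})

setMethod("show", "BCDAResults", function(object) {
    cat("BCDAResults\n")
    cat("  variant:", object@variant, " alpha:", object@alpha, "\n")
    res <- object@results
    if (nrow(res)) {
        cat("  contrasts:", paste(unique(res$contrast), collapse = ", "), "\n")
        cat("  significant rows (q <= alpha, passing filters):",
            sum(res$q <= object@alpha & res$passed_ss, na.rm = TRUE), "\n")
    }
    if (!is.null(object@global))
        cat("  global screening tests:", nrow(object@global), "\n")
    if (!is.null(object@pairwise))
        cat("  pairwise records:", nrow(object@pairwise), "\n")
    if (!is.null(object@patterns))
        cat("  pattern tests:", nrow(object@patterns), "\n")
    invisible(NULL)
})
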