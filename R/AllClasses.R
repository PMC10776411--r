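#' @import methods
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

#' Zero-handling report
#'
#' Summarises the three zero-handling stages applied to a count table:
#' structural-zero detection across experimental groups, overall prevalence,
#' and the retention mask used for downstream modeling.
#'
#' @slot structuralZero logical matrix (taxa x groups); \code{TRUE} where a
#'   taxon is declared structurally absent from a group. Zero columns when no
#'   grouping variable was supplied.
#' @slot structuralDA logical; \code{TRUE} for taxa declared differentially
#'   abundant purely through structural zeros (absent from some groups,
#'   present in at least one).
#' @slot prevalence numeric; per-taxon fraction of samples with a positive
#'   count.
#' @slot retained logical; taxa kept for model-based analysis (prevalence at
#'   or above the threshold, not structural-zero DA, not absent everywhere).
#' @slot threshold numeric(1); the prevalence cutoff used.
#' @export
setClass("ZeroReport",
    representation(
        structuralZero = "matrix",
        structuralDA = "logical",
        prevalence = "numeric",
        retained = "logical",
        threshold = "numeric"
    )
)

setValidity("ZeroReport", function(object) {
    msg <- NULL
    d <- length(object@prevalence)
    if (length(object@structuralDA) != d || length(object@retained) != d)
        msg <- c(msg, "per-taxon slots must have equal length")
    if (ncol(object@structuralZero) > 0L && nrow(object@structuralZero) != d)
        msg <- c(msg, "structuralZero must have one row per taxon")
    if (any(object@prevalence < 0 | object@prevalence > 1, na.rm = TRUE))
        msg <- c(msg, "prevalence must lie in [0, 1]")
    bad <- object@structuralDA &
        (rowSums(object@structuralZero) == 0L |
         rowSums(object@structuralZero) == ncol(object@structuralZero))
    if (ncol(object@structuralZero) > 0L && any(bad))
        msg <- c(msg, "structuralDA requires structural zeros in some but not all groups")
    if (any(object@retained & object@structuralDA))
        msg <- c(msg, "structural-zero DA taxa cannot be retained for modeling")
    if (is.null(msg)) TRUE else msg
})

#' Three-component Gaussian mixture fit for one covariate
#'
#' Holds the EM estimate of the shared coefficient bias for a single design
#' column: the null-component location (the bias), the mixing proportions of
#' the null / decreased / increased components, the component offsets and the
#' shared spread inflations of the two differential components.
#'
#' @slot delta numeric(1); estimated shared bias of the preliminary
#'   coefficients for this covariate.
#' @slot pi numeric(3); mixing proportions (null, decreased, increased).
#' @slot l1,l2 numeric(1); component mean offsets, \code{l1 < 0 < l2}.
#' @slot kappa1,kappa2 numeric(1); positive additive inflations of the
#'   per-taxon component standard deviations.
#' @slot converged logical(1).
#' @slot nIter integer(1); EM iterations used.
#' @slot logLik numeric(1); final observed-data log-likelihood.
#' @export
setClass("MixtureFit",
    representation(
        delta = "numeric",
        pi = "numeric",
        l1 = "numeric",
        l2 = "numeric",
        kappa1 = "numeric",
        kappa2 = "numeric",
        converged = "logical",
        nIter = "integer",
        logLik = "numeric"
    )
)

setValidity("MixtureFit", function(object) {
    msg <- NULL
    if (length(object@pi) != 3L || abs(sum(object@pi) - 1) > 1e-8)
        msg <- c(msg, "pi must be a 3-vector summing to 1")
    if (!(object@l1 < 0))
        msg <- c(msg, "l1 must be negative")
    if (!(object@l2 > 0))
        msg <- c(msg, "l2 must be positive")
    if (object@kappa1 < 0 || object@kappa2 < 0)
        msg <- c(msg, "kappa1 and kappa2 must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' Bias-corrected model fit
#'
#' Per-taxon estimates from the offset-based log-linear model: preliminary
#' coefficients from the iterative sampling-fraction algorithm, the EM bias
#' correction per covariate, sandwich (or GLS) covariances, and the final
#' sampling-fraction estimates.
#'
#' @slot betaStar numeric matrix (taxa x coefficients); preliminary estimates.
#' @slot betaHat numeric matrix; bias-corrected estimates (intercept column is
#'   never bias-corrected).
#' @slot se numeric matrix; unregularized standard errors.
#' @slot sigma array (p x p x taxa); per-taxon coefficient covariance.
#' @slot thetaStar,thetaHat numeric; per-sample log sampling-fraction
#'   estimates (preliminary / final, centered scale).
#' @slot delta numeric(p); assembled EM bias vector (0 for the intercept).
#' @slot mixtures list of \linkS4class{MixtureFit}, one per bias-corrected
#'   column.
#' @slot s0 numeric(p); SAM-style regularization constants (5th percentile of
#'   each column's standard errors).
#' @slot X numeric design matrix (samples x p).
#' @slot mask logical matrix (taxa x samples); observed (positive count)
#'   entries used in the complete-data fit.
#' @slot method character(1); \code{"ml"} (fixed effects) or \code{"reml"}
#'   (mixed effects).
#' @slot converged logical(1); convergence of the sampling-fraction iteration.
#' @slot random list; mixed-effects extras (variance components, residual
#'   variances, ReML log-likelihoods), empty for fixed-effects fits.
#' @export
setClass("BCDAFit",
    representation(
        betaStar = "matrix",
        betaHat = "matrix",
        se = "matrix",
        sigma = "array",
        thetaStar = "numeric",
        thetaHat = "numeric",
        delta = "numeric",
        mixtures = "list",
        s0 = "numeric",
        X = "matrix",
        mask = "matrix",
        method = "character",
        converged = "logical",
        random = "list"
    )
)

setValidity("BCDAFit", function(object) {
    msg <- NULL
    d <- nrow(object@betaStar); p <- ncol(object@betaStar)
    if (!all(dim(object@betaHat) == c(d, p)) || !all(dim(object@se) == c(d, p)))
        msg <- c(msg, "betaHat and se must match betaStar dimensions")
    if (!all(dim(object@sigma) == c(p, p, d)))
        msg <- c(msg, "sigma must be a p x p x d array")
    if (length(object@delta) != p)
        msg <- c(msg, "delta must have one entry per coefficient")
    if (any(object@se < 0, na.rm = TRUE))
        msg <- c(msg, "standard errors must be non-negative")
    if (!object@method %in% c("ml", "reml"))
        msg <- c(msg, "method must be 'ml' or 'reml'")
    if (is.null(msg)) TRUE else msg
})

#' Differential-abundance analysis results
#'
#' Container returned by \code{\link{bcda}}: the underlying
#' \linkS4class{BCDAFit}, the per-taxon per-contrast test table, the
#' zero-handling report, sensitivity scores, and any multigroup or pattern
#' analysis results.
#'
#' @slot call the matched call.
#' @slot fit a \linkS4class{BCDAFit}.
#' @slot results data.frame with columns taxon, contrast, lfc, se, W, p, q,
#'   passed_ss, structural_zero, direction.
#' @slot zeroReport a \linkS4class{ZeroReport}.
#' @slot sensitivity data.frame of sensitivity scores, or NULL when the
#'   pseudo-count sensitivity analysis was not run.
#' @slot global data.frame of per-taxon global (chi-square or Dunnett-type)
#'   screening tests, or NULL.
#' @slot pairwise data.frame of pairwise comparisons under mdFDR control, or
#'   NULL.
#' @slot patterns data.frame of order-restricted pattern tests, or NULL.
#' @slot alpha numeric(1); nominal significance level.
#' @slot variant character(1); \code{"ss_filter"} or \code{"no_filter"}.
#' @export
setClass("BCDAResults",
    representation(
        call = "call",
        fit = "BCDAFit",
        results = "data.frame",
        zeroReport = "ZeroReport",
        sensitivity = "data.frameOrNULL",
        global = "data.frameOrNULL",
        pairwise = "data.frameOrNULL",
        patterns = "data.frameOrNULL",
        alpha = "numeric",
        variant = "character"
    )
)

setValidity("BCDAResults", function(object) {
    msg <- NULL
    need <- c("taxon", "contrast", "lfc", "se", "W", "p", "q",
              "passed_ss", "structural_zero", "direction")
    if (nrow(object@results) > 0L && !all(need %in% names(object@results)))
        msg <- c(msg, "results is missing required columns")
    if (!object@variant %in% c("ss_filter", "no_filter"))
        msg <- c(msg, "variant must be 'ss_filter' or 'no_filter'")
    if (is.null(msg)) TRUE else msg
})
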