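## Replicate-level metric functions for the four built-in benchmark
## scenarios. Each takes the simulated dataset and the replicate seed and
## returns named metrics computed against the simulator's ground truth.

.metricsContinuous <- function(sim, repSeed, ssFilter = TRUE,
                               alpha = 0.05, contrast = "exposure") {
    fixedVar <- if (contrast == "exposure") "exposure" else "group"
    res <- bcda(sim$counts, sim$metadata, fixed = fixedVar,
                structZero = TRUE, ssFilter = ssFilter, alpha = alpha,
                seed = repSeed)
    tab <- testResults(res)
    tab <- tab[tab$contrast == contrast, ]
    disc <- tab$taxon[!is.na(tab$q) & tab$q <= alpha & tab$passed_ss]
    fp <- fdrPower(disc, sim$truth$daTaxa)
    c(fdr = fp$fdr, power = fp$power)
}

.metricsPairwise <- function(sim, repSeed, ssFilter = TRUE, alpha = 0.05,
                             random = NULL) {
    res <- bcda(sim$counts, sim$metadata, fixed = c("group", "covariate"),
                group = "group", random = random, pairwise = TRUE,
                ssFilter = ssFilter, alpha = alpha, seed = repSeed)
    md <- list(pairwise = res@pairwise,
               R = sum(res@global$screened, na.rm = TRUE),
               screened = setNames(res@global$screened, res@global$taxon))
    truthB <- sim$truth$beta
    colnames(truthB) <- sub("^group", "", colnames(truthB))
    ev <- mdfdrEval(md, truthB, sim$truth$daTaxa, referenceLabel = "G0")
    c(mdfdr = ev$mdfdr, power = ev$power, R = ev$R)
}

.metricsTrend <- function(sim, repSeed, alpha = 0.05, B = 500L) {
    res <- bcda(sim$counts, sim$metadata, fixed = "group", group = "group",
                trend = TRUE, ssFilter = FALSE, B = B, seed = repSeed)
    pat <- res@patterns
    sig <- !is.na(pat$q) & pat$q <= alpha
    discInc <- pat$taxon[sig & pat$best_pattern == "simple_inc"]
    disc <- pat$taxon[sig]
    da <- sim$truth$daTaxa
    ## a discovery is an error if the taxon is null, or its declared best
    ## pattern contradicts the (increasing) truth
    err <- sum(!disc %in% da) +
        sum(pat$taxon[sig & pat$best_pattern != "simple_inc"] %in% da)
    c(fdr = err / max(length(disc), 1L),
      power = if (length(da)) mean(da %in% discInc) else NA_real_)
}

#' Built-in simulation benchmarks
#'
#' Reproduces the package's reference simulation studies with the built-in
#' Poisson log-normal generator and scores the analysis against the
#' simulator's ground truth, aggregating replicate-level metrics.
#'
#' Scenarios:
#' \describe{
#'   \item{continuous_fdr}{continuous exposure, d = 200, n = 30, 10\% DA,
#'     SS-filter variant; reports FDR and power of the Holm-adjusted calls.}
#'   \item{binary_fdr}{as continuous_fdr but with a binary exposure,
#'     n = 30 per group.}
#'   \item{pairwise_mdfdr}{3 ordered groups plus a continuous covariate,
#'     n per group = 30, 10\% DA, all pairwise comparisons under mdFDR
#'     control, SS-filter variant; reports mdFDR and power.}
#'   \item{trend_power}{3 ordered groups with monotone effects (delta and
#'     delta + 1), 20\% DA, n per group = 50, pattern analysis with B = 500;
#'     reports FDR and the fraction of DA taxa detected with the increasing
#'     pattern.}
#'   \item{mixed_mdfdr}{3 groups, subject random intercept (SD 1), two
#'     observations per subject, continuous covariate, n = 30 subjects per
#'     group, ReML fit, all pairwise comparisons, SS-filter variant;
#'     reports mdFDR and power.}
#' }
#'
#' @param scenario one of the scenario names above.
#' @param nReps number of simulation replicates.
#' @param seed master seed.
#' @param ssFilter override the scenario's default variant.
#' @return list as from \code{\link{replicateRunner}}.
#' @export
runBenchmark <- function(scenario = c("continuous_fdr", "binary_fdr",
                                      "pairwise_mdfdr", "trend_power",
                                      "mixed_mdfdr"),
                         nReps = 50L, seed = 1L, ssFilter = TRUE) {
    scenario <- match.arg(scenario)
    switch(scenario,
        continuous_fdr = replicateRunner(
            function(s) simConfig(d = 200L, n = 30L,
                                  exposure = "continuous", propDA = 0.10,
                                  seed = s),
            function(sim, s) .metricsContinuous(sim, s,
                                                ssFilter = ssFilter),
            nReps = nReps, seed = seed),
        binary_fdr = replicateRunner(
            function(s) simConfig(d = 200L, n = 30L, exposure = "binary",
                                  propDA = 0.10, seed = s),
            function(sim, s) .metricsContinuous(sim, s,
                                                ssFilter = ssFilter,
                                                contrast = "groupG1"),
            nReps = nReps, seed = seed),
        pairwise_mdfdr = replicateRunner(
            function(s) simConfig(d = 200L, n = 30L, exposure = "groups",
                                  nGroups = 3L, propDA = 0.10,
                                  confounder = TRUE, seed = s),
            function(sim, s) .metricsPairwise(sim, s, ssFilter = ssFilter),
            nReps = nReps, seed = seed),
        trend_power = replicateRunner(
            function(s) simConfig(d = 200L, n = 50L, exposure = "groups",
                                  nGroups = 3L, propDA = 0.20,
                                  orderedEffect = TRUE, seed = s),
            function(sim, s) .metricsTrend(sim, s),
            nReps = nReps, seed = seed),
        mixed_mdfdr = replicateRunner(
            function(s) simConfig(d = 200L, n = 30L, exposure = "groups",
                                  nGroups = 3L, propDA = 0.10,
                                  confounder = TRUE,
                                  randomEffects = list(interceptSD = 1,
                                                       obsPerSubject = 2L),
                                  seed = s),
            function(sim, s) .metricsPairwise(sim, s, ssFilter = ssFilter,
                                              random = ~ 1 | subject),
            nReps = nReps, seed = seed))
}
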