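#' @include pipeline.R
NULL

#' Replicated simulation experiments
#'
#' Ready-made Monte-Carlo experiments that exercise the package's two
#' statistical engines under known truth.  Expensive shared inputs (the
#' genotype panel and partitioned LD scores, or the peak universe) are
#' built once per experiment; each replicate then redraws only the random
#' layer appropriate to the question (chi-square statistics, or lead
#' variant placement).  All experiments are deterministic given `seed`.
#'
#' \describe{
#'   \item{`sldscRecoveryExperiment()`}{analytic-mode summary statistics
#'     with one planted annotation coefficient `tauStar`; per replicate,
#'     the stratified LD-score regression is refit and the estimate,
#'     jackknife SE and one-sided p recorded.  With `tauStar = 0` this is
#'     the null-calibration experiment.}
#'   \item{`conditioningExperiment()`}{a non-causal "shadow" annotation is
#'     constructed to overlap the causal one (half of its intervals are
#'     shared, half are background), so its marginal coefficient is
#'     inflated by the planted signal; per replicate the shadow
#'     coefficient is estimated alone and conditional on the causal
#'     annotation.}
#'   \item{`cheersCalibrationExperiment()`}{lead variants placed uniformly
#'     on the genome (no planted enrichment); per replicate the per-state
#'     specificity-rank p-values are recorded.}
#'   \item{`cheersRecoveryExperiment()`}{lead variants planted into peaks
#'     specific to a target state with probability `pi`; per replicate,
#'     whether the target state attains the largest enrichment Z.}
#' }
#'
#' @param seed master seed.
#' @param nReplicates number of Monte-Carlo replicates.
#' @param tauStar planted per-SNP heritability coefficient.
#' @param nVariants,nIndividuals,gwasN,windowBp,nBlocks problem sizes for
#'   the regression experiments.
#' @param weights weighting mode passed to [fitSldsc()].
#' @param nPeaks,nCellStates,nLeads,pi,targetState problem sizes for the
#'   specificity-rank experiments.
#' @return A data.frame of per-replicate results (see each description),
#'   with the shared inputs attached as attributes where useful.
#' @name experiments
NULL

# Shared inputs for the regression experiments: panel, active annotation,
# LD scores (active + total).
sldscExperimentInputs <- function(seed, nVariants, nIndividuals,
                                  windowBp) {
  cfg <- simulationConfig(seed = seed, nIndividuals = nIndividuals,
                          nVariants = nVariants)
  panel <- simulateGenotypePanel(cfg)
  seg <- simulateSegmentation(cfg)
  active <- mergeActiveStates(seg)
  total <- annotationSet("total",
    GRanges("chr1", IRanges(1, genomeLength(cfg))))
  lds <- partitionedLdScores(panel, list(active = active, total = total),
                             windowBp = windowBp)
  list(cfg = cfg, panel = panel, active = active, lds = lds)
}

#' @rdname experiments
#' @export
sldscRecoveryExperiment <- function(seed = 1L, nReplicates = 100L,
                                    tauStar = 5e-6, nVariants = 20000L,
                                    nIndividuals = 1000L, gwasN = 50000L,
                                    windowBp = 100000L, nBlocks = 200L,
                                    weights = "ldsc") {
  inp <- sldscExperimentInputs(seed, nVariants, nIndividuals, windowBp)
  out <- lapply(seq_len(nReplicates), function(r) {
    cfgR <- inp$cfg
    cfgR$seed <- stageSeed(seed, paste0("replicate", r))
    cfgR$gwasN <- gwasN
    cfgR$plantedTau <- c(active = tauStar)
    stats <- simulateSummaryStats(inp$panel, list(active = inp$active),
                                  cfgR, mode = "analytic",
                                  ldscores = inp$lds)
    fit <- fitSldsc(stats, inp$lds, modelAnnotations = "active",
                    nBlocks = nBlocks, weights = weights)
    cf <- coefficientTable(fit)
    data.frame(replicate = r, tauHat = cf$tau, se = cf$se, z = cf$z,
               p = cf$p, covered = abs(cf$tau - tauStar) <= 3 * cf$se,
               intercept = fit@intercept)
  })
  res <- do.call(rbind, out)
  attr(res, "tauStar") <- tauStar
  res
}

# A non-causal annotation correlated with the causal one: half of the
# causal intervals plus an equal amount of background.
shadowAnnotation <- function(active, genomeBp, seed) {
  r <- annotationRanges(active)
  withSeed(stageSeed(seed, "shadow"), {
    half <- sort(sample(length(r), ceiling(length(r) / 2)))
    shared <- r[half]
    w <- width(shared)
    bgStart <- sample.int(genomeBp - max(w) - 1L, length(shared))
    bg <- GRanges("chr1", IRanges(bgStart, width = w))
    annotationSet("shadow", c(shared, bg),
                  provenance = "half causal, half background")
  })
}

#' @rdname experiments
#' @export
conditioningExperiment <- function(seed = 1L, nReplicates = 100L,
                                   tauStar = 5e-6, nVariants = 20000L,
                                   nIndividuals = 1000L, gwasN = 50000L,
                                   windowBp = 100000L, nBlocks = 200L) {
  inp <- sldscExperimentInputs(seed, nVariants, nIndividuals, windowBp)
  shadow <- shadowAnnotation(inp$active, genomeLength(inp$cfg), seed)
  lds <- partitionedLdScores(inp$panel,
    list(active = inp$active, shadow = shadow), windowBp = windowBp)
  out <- lapply(seq_len(nReplicates), function(r) {
    cfgR <- inp$cfg
    cfgR$seed <- stageSeed(seed, paste0("cond", r))
    cfgR$gwasN <- gwasN
    cfgR$plantedTau <- c(active = tauStar)
    stats <- simulateSummaryStats(inp$panel, list(active = inp$active),
                                  cfgR, mode = "analytic", ldscores = lds)
    un <- fitSldsc(stats, lds, modelAnnotations = "shadow",
                   nBlocks = nBlocks)
    co <- fitConditional(stats, lds, "shadow", "active",
                         nBlocks = nBlocks)
    data.frame(replicate = r,
               tauUncond = coefficientTable(un)$tau[1],
               tauCond = coefficientTable(co)$tau[
                 match("shadow", coefficientTable(co)$annotation)])
  })
  do.call(rbind, out)
}

#' @rdname experiments
#' @export
cheersCalibrationExperiment <- function(seed = 1L, nReplicates = 200L,
                                        nPeaks = 5000L, nCellStates = 6L,
                                        nLeads = 50L, nVariants = 10000L,
                                        targetState = "state1") {
  cfg <- simulationConfig(seed = seed, nVariants = nVariants,
                          nPeaks = nPeaks, nCellStates = nCellStates,
                          nLeads = nLeads, plantedEnrichmentPi = 0)
  psm <- simulatePeakMatrix(cfg)
  out <- lapply(seq_len(nReplicates), function(r) {
    cfgR <- cfg
    cfgR$seed <- stageSeed(seed, paste0("calib", r))
    leads <- plantRiskVariants(psm, targetState, cfgR)
    ov <- overlapVariants(psm, leads)
    if (!nrow(ov)) return(NULL)
    tab <- enrichmentTable(cheersTest(psm, ov))
    data.frame(replicate = r, state = tab$state, n = tab$n_peaks,
               p = tab$p)
  })
  do.call(rbind, out)
}

#' @rdname experiments
#' @export
cheersRecoveryExperiment <- function(seed = 1L, nReplicates = 100L,
                                     pi = 0.8, nPeaks = 5000L,
                                     nCellStates = 6L, nLeads = 50L,
                                     nVariants = 10000L,
                                     targetState = "state3") {
  cfg <- simulationConfig(seed = seed, nVariants = nVariants,
                          nPeaks = nPeaks, nCellStates = nCellStates,
                          nLeads = nLeads, plantedEnrichmentPi = pi)
  psm <- simulatePeakMatrix(cfg)
  out <- vapply(seq_len(nReplicates), function(r) {
    cfgR <- cfg
    cfgR$seed <- stageSeed(seed, paste0("recov", r))
    leads <- plantRiskVariants(psm, targetState, cfgR)
    ov <- overlapVariants(psm, leads)
    if (!nrow(ov)) return(NA)
    tab <- enrichmentTable(cheersTest(psm, ov))
    tab$z[match(targetState, tab$state)] >= max(tab$z)
  }, logical(1))
  data.frame(replicate = seq_len(nReplicates), targetTop = out)
}
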