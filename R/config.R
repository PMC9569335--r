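#' @include utils.R
NULL

#' Simulation configuration
#'
#' Collects every parameter of the synthetic-data generator in one
#' validated object.  The defaults define the study conditions under which
#' the package's statistical engines are exercised; see the methods
#' vignette for the rationale behind each value.
#'
#' @param seed master integer seed; per-stage seeds are derived from it so
#'   each generator stage is independently reproducible.
#' @param nIndividuals reference-panel size (rows of the genotype matrix).
#' @param nVariants number of biallelic variants on the synthetic genome.
#' @param blockSize variants per LD block; LD is AR-1 within blocks and
#'   zero across blocks.
#' @param rhoLD within-block AR-1 correlation of the latent Gaussian,
#'   in `[0, 1)`.
#' @param mafRange length-2 numeric; per-variant minor allele frequencies
#'   are drawn uniformly from this interval.
#' @param gwasN GWAS sample size N entering the chi-square model.
#' @param plantedTau named numeric vector mapping annotation name to the
#'   per-SNP heritability coefficient tau planted for that annotation
#'   (all >= 0).
#' @param variantSpacing base pairs between consecutive variants; the
#'   synthetic genome length is `nVariants * variantSpacing`.
#' @param nPeaks,nCellStates dimensions of the simulated peak-by-cell-state
#'   signal matrix.
#' @param specificityFraction fraction of peaks planted as specific to each
#'   cell state (`specificityFraction * nCellStates` must be <= 1 so planted
#'   sets are disjoint).
#' @param specificityBoost multiplicative signal boost a planted peak
#'   receives in its own state.
#' @param peakWidth width of each simulated peak in bp.
#' @param plantedEnrichmentPi probability that a simulated lead risk
#'   variant is placed inside a peak specific to the target state (the rest
#'   land uniformly on the genome).
#' @param nLeads number of lead risk variants to plant.
#' @return A validated list of class `"SimulationConfig"`.
#' @examples
#' cfg <- simulationConfig(seed = 1, nVariants = 500, nIndividuals = 100)
#' cfg$nVariants
#' @export
simulationConfig <- function(seed = 1L,
                             nIndividuals = 1000L,
                             nVariants = 20000L,
                             blockSize = 50L,
                             rhoLD = 0.9,
                             mafRange = c(0.05, 0.5),
                             gwasN = 50000L,
                             plantedTau = c(active = 0),
                             variantSpacing = 1000L,
                             nPeaks = 5000L,
                             nCellStates = 6L,
                             specificityFraction = 0.05,
                             specificityBoost = 8,
                             peakWidth = 300L,
                             plantedEnrichmentPi = 0,
                             nLeads = 50L) {
  cfg <- list(seed = as.integer(seed),
              nIndividuals = as.integer(nIndividuals),
              nVariants = as.integer(nVariants),
              blockSize = as.integer(blockSize),
              rhoLD = rhoLD,
              mafRange = as.numeric(mafRange),
              gwasN = as.numeric(gwasN),
              plantedTau = plantedTau,
              variantSpacing = as.integer(variantSpacing),
              nPeaks = as.integer(nPeaks),
              nCellStates = as.integer(nCellStates),
              specificityFraction = specificityFraction,
              specificityBoost = specificityBoost,
              peakWidth = as.integer(peakWidth),
              plantedEnrichmentPi = plantedEnrichmentPi,
              nLeads = as.integer(nLeads))
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}

validateSimulationConfig <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  counts <- c("nIndividuals", "nVariants", "blockSize", "variantSpacing",
              "nPeaks", "nCellStates", "peakWidth", "nLeads")
  for (f in counts)
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 1L)
      stop("configuration error: '", f, "' must be a positive count")
  if (cfg$blockSize > cfg$nVariants)
    stop("configuration error: blockSize exceeds nVariants")
  if (cfg$rhoLD < 0 || cfg$rhoLD >= 1)
    stop("configuration error: rhoLD must lie in [0, 1)")
  if (length(cfg$mafRange) != 2L || cfg$mafRange[1] <= 0 ||
      cfg$mafRange[2] > 0.5 || cfg$mafRange[1] > cfg$mafRange[2])
    stop("configuration error: mafRange must be within (0, 0.5]")
  if (cfg$plantedEnrichmentPi < 0 || cfg$plantedEnrichmentPi > 1)
    stop("configuration error: plantedEnrichmentPi must lie in [0, 1]")
  if (cfg$specificityFraction < 0 || cfg$specificityFraction > 1)
    stop("configuration error: specificityFraction must lie in [0, 1]")
  if (cfg$specificityFraction * cfg$nCellStates > 1 + 1e-9)
    stop("configuration error: specificityFraction * nCellStates exceeds 1 ",
         "(planted sets must be disjoint)")
  if (any(cfg$plantedTau < 0))
    stop("configuration error: plantedTau coefficients must be >= 0")
  if (cfg$nPeaks < cfg$nCellStates)
    stop("configuration error: nPeaks must be >= nCellStates")
  if (cfg$gwasN < 0)
    stop("configuration error: gwasN must be non-negative")
  invisible(cfg)
}

# Synthetic genome length in bp implied by the configuration.
genomeLength <- function(cfg) as.numeric(cfg$nVariants) * cfg$variantSpacing
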