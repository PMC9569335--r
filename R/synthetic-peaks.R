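#' @include config.R cheers.R
NULL

#' Simulate a peak-by-cell-state signal matrix with planted specificity
#'
#' Generates `nPeaks` non-overlapping peak intervals on the synthetic
#' genome and a log-normal background signal for each peak in each of
#' `nCellStates` cell states; for each state, a disjoint random subset of
#' `specificityFraction * nPeaks` peaks receives a `specificityBoost`-fold
#' multiplicative signal boost in that state only.  The raw matrix is then
#' processed by [specificityScores()] (quantile normalization, bottom
#' decile removal, Euclidean-norm scaling, within-state ranking), with the
#' planted truth carried in `rowData()$plantedState`.
#'
#' @param config a [simulationConfig()].
#' @param ... processing switches passed on to [specificityScores()].
#' @return A [PeakSpecificityMatrix-class]; `metadata()` records
#'   `genomeBp` and `seed`.  Deterministic given `config$seed`.
#' @export
simulatePeakMatrix <- function(config, ...) {
  validateSimulationConfig(config)
  nP <- config$nPeaks; nS <- config$nCellStates
  L <- genomeLength(config)
  w <- config$peakWidth
  if (nP * w > L)
    stop("configuration error: peaks cannot be placed without overlap ",
         "(nPeaks * peakWidth exceeds genome length)")
  withSeed(stageSeed(config$seed, "peaks"), {
    # non-overlapping placement: random gaps scaled to fill the genome
    gaps <- rexp(nP + 1L)
    gaps <- gaps / sum(gaps) * (L - nP * w)
    starts <- round(cumsum(gaps)[seq_len(nP)] + (seq_len(nP) - 1L) * w) + 1L
    peaks <- GRanges("chr1", IRanges(as.integer(starts), width = w))
    states <- paste0("state", seq_len(nS))
    baseline <- rnorm(nP, 0, 0.5)
    signal <- exp(baseline + matrix(rnorm(nP * nS, 0, 0.3), nP, nS))
    colnames(signal) <- states
    planted <- rep(NA_character_, nP)
    nSpec <- floor(config$specificityFraction * nP)
    if (nSpec > 0) {
      pool <- sample.int(nP, nSpec * nS)
      for (k in seq_len(nS)) {
        idx <- pool[seq.int((k - 1L) * nSpec + 1L, k * nSpec)]
        signal[idx, k] <- signal[idx, k] * config$specificityBoost
        planted[idx] <- states[k]
      }
    }
    psm <- specificityScores(signal, peaks = peaks,
                             rowData = DataFrame(plantedState = planted), ...)
    metadata(psm)$genomeBp <- L
    metadata(psm)$seed <- config$seed
    psm
  })
}

#' Plant lead risk variants with known cell-state enrichment
#'
#' Creates ground truth for specificity-rank recovery experiments: each of
#' `config$nLeads` lead variants is, with probability
#' `config$plantedEnrichmentPi`, placed uniformly inside a peak planted as
#' specific to `targetState`; otherwise it is placed uniformly on the
#' synthetic genome.
#'
#' @param peaks a [PeakSpecificityMatrix-class] from [simulatePeakMatrix()]
#'   (must carry `rowData()$plantedState` and `metadata()$genomeBp`).
#' @param targetState the cell state whose specific peaks receive planted
#'   variants.
#' @param config a [simulationConfig()].
#' @return A width-1 `GRanges` of lead positions with `variant` and `lead`
#'   metadata columns; deterministic given `config$seed`.
#' @export
plantRiskVariants <- function(peaks, targetState, config) {
  validateSimulationConfig(config)
  stopifnot(is(peaks, "PeakSpecificityMatrix"))
  planted <- rowData(peaks)$plantedState
  if (is.null(planted))
    stop("peaks carry no planted truth (rowData()$plantedState)")
  if (!targetState %in% colnames(specificityScore(peaks)))
    stop("unknown target state: ", targetState)
  spec <- which(!is.na(planted) & planted == targetState)
  if (config$plantedEnrichmentPi > 0 && !length(spec))
    stop("degenerate configuration: no peaks specific to ", targetState)
  L <- metadata(peaks)$genomeBp
  if (is.null(L)) L <- max(end(rowRanges(peaks)))
  withSeed(stageSeed(config$seed, paste0("leads-", targetState)), {
    nL <- config$nLeads
    inPeak <- runif(nL) < config$plantedEnrichmentPi
    pos <- numeric(nL)
    for (i in seq_len(nL)) {
      if (inPeak[i]) {
        pk <- rowRanges(peaks)[sample(spec, 1L)]
        pos[i] <- sample.int(width(pk), 1L) + start(pk) - 1L
      } else {
        pos[i] <- sample.int(L, 1L)
      }
    }
    ids <- sprintf("lead%03d", seq_len(nL))
    GRanges("chr1", IRanges(as.integer(pos), width = 1L),
            variant = ids, lead = ids)
  })
}

#' Simulate a gene model on the synthetic genome
#'
#' Places `nGenes` non-overlapping gene bodies with random strands on the
#' synthetic genome; the TSS is the gene-body start on the + strand and
#' the end on the - strand.
#'
#' @param config a [simulationConfig()].
#' @param nGenes number of genes.
#' @param geneWidth gene-body width in bp.
#' @return A `GRanges` with strand, `gene_id` and `tss` metadata columns.
#' @export
simulateGeneModel <- function(config, nGenes = 200L, geneWidth = 20000L) {
  validateSimulationConfig(config)
  L <- genomeLength(config)
  if (nGenes * geneWidth > L)
    stop("configuration error: genes cannot be placed without overlap")
  withSeed(stageSeed(config$seed, "genes"), {
    gaps <- rexp(nGenes + 1L)
    gaps <- gaps / sum(gaps) * (L - nGenes * geneWidth)
    starts <- round(cumsum(gaps)[seq_len(nGenes)] +
                      (seq_len(nGenes) - 1L) * geneWidth) + 1L
    strand <- sample(c("+", "-"), nGenes, replace = TRUE)
    g <- GRanges("chr1", IRanges(as.integer(starts), width = geneWidth),
                 strand = strand,
                 gene_id = sprintf("gene%04d", seq_len(nGenes)))
    mcols(g)$tss <- ifelse(strand == "+", start(g), end(g))
    g
  })
}

#' Simulate GMT-style gene sets
#'
#' Draws `nSets` gene sets of random sizes from a gene model's ids, for
#' exercising over-representation analysis.
#'
#' @param config a [simulationConfig()].
#' @param genes a gene model `GRanges` from [simulateGeneModel()].
#' @param nSets number of sets.
#' @param sizeRange integer range of set sizes.
#' @return Named list of character vectors (gene ids).
#' @export
simulateGeneSets <- function(config, genes, nSets = 25L,
                             sizeRange = c(5L, 40L)) {
  validateSimulationConfig(config)
  ids <- mcols(genes)$gene_id
  withSeed(stageSeed(config$seed, "genesets"), {
    sizes <- sample(seq(sizeRange[1], min(sizeRange[2], length(ids))),
                    nSets, replace = TRUE)
    sets <- lapply(sizes, function(s) sample(ids, s))
    names(sets) <- sprintf("SET_%03d", seq_len(nSets))
    sets
  })
}
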