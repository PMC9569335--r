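#' @include epienrich-package.R
NULL

#' Binary genomic annotation
#'
#' A named, maximally merged set of genomic intervals acting as a binary
#' per-base (and hence per-variant) annotation, e.g. the union of all
#' "active" chromatin-state segments of one tissue, or one regulatory
#' element class (promoter / enhancer / genic enhancer).
#'
#' Intervals are held as a [GenomicRanges::GRanges] in the usual 1-based,
#' closed convention; conversion to/from BED (0-based, half-open) happens
#' only at I/O through \pkg{rtracklayer}.  The validity method enforces the
#' binary-annotation semantics: intervals are sorted, non-overlapping and
#' non-adjacent (adjacent intervals are merged).
#'
#' @slot name single character, the annotation's name.
#' @slot ranges a `GRanges` of disjoint, merged intervals.
#' @slot provenance character vector recording e.g. which chromatin-state
#'   labels were merged to produce the annotation.
#'
#' @seealso [mergeActiveStates()], [classAnnotations()], [annotateVariants()]
#' @export
setClass("AnnotationSet",
  representation(name = "character", ranges = "GRanges",
                 provenance = "character"))

setValidity("AnnotationSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name))
    msg <- c(msg, "'name' must be a single non-NA string")
  r <- object@ranges
  if (length(r)) {
    red <- reduce(r, min.gapwidth = 1L)
    if (length(red) != length(r) || sum(width(red)) != sum(width(r)))
      msg <- c(msg, "ranges must be disjoint and maximally merged")
    if (any(start(r) < 1))
      msg <- c(msg, "coordinates must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Reference genotype panel
#'
#' Allele counts for a set of individuals at biallelic variants, together
#' with the variant map and the LD block structure used to simulate the
#' panel (when synthetic).  Stands in for an external reference panel such
#' as 1000 Genomes when computing r^2 LD, partitioned LD scores and LD
#' expansion of lead variants.
#'
#' @slot genotypes integer-valued matrix, individuals x variants, entries in
#'   \{0, 1, 2\}; columns named by variant id.
#' @slot variants `GRanges` of width-1 variant positions (1-based), with
#'   metadata columns `variant` (id) and `maf` (target minor allele
#'   frequency, for synthetic panels).
#' @slot blockSize integer, number of variants per LD block (0 if unknown).
#' @slot rho numeric, AR-1 within-block correlation parameter of the latent
#'   Gaussian used to simulate the panel (NA if unknown).
#'
#' @seealso [simulateGenotypePanel()], [pairwiseR2()], [partitionedLdScores()]
#' @export
setClass("GenotypePanel",
  representation(genotypes = "matrix", variants = "GRanges",
                 blockSize = "integer", rho = "numeric"))

setValidity("GenotypePanel", function(object) {
  msg <- character()
  g <- object@genotypes
  if (ncol(g) != length(object@variants))
    msg <- c(msg, "ncol(genotypes) must equal length(variants)")
  if (!all(g %in% 0:2))
    msg <- c(msg, "genotype values must be in {0, 1, 2}")
  if (is.null(mcols(object@variants)$variant))
    msg <- c(msg, "variants must carry a 'variant' id column")
  pos <- split(start(object@variants), as.character(seqnames(object@variants)))
  if (any(vapply(pos, is.unsorted, logical(1), strictly = TRUE)))
    msg <- c(msg, "positions must be strictly increasing within a chromosome")
  f <- colMeans(g) / 2
  if (any(pmin(f, 1 - f) <= 0))
    msg <- c(msg, "every variant must be polymorphic (MAF > 0)")
  if (length(msg)) msg else TRUE
})

#' Partitioned LD-score table
#'
#' For every retained variant j and every annotation C, the LD score
#' l(j, C) = sum over k in C within the window of r^2(j, k), computed from
#' a reference panel.  One column per annotation; the self term (r^2 = 1)
#' is included when j is itself a member of C.
#'
#' @slot scores numeric matrix, variants x annotations, non-negative.
#' @slot variants `GRanges` of the scored variants, with `variant` id column.
#' @slot window integer, window half-width in base pairs.
#' @slot panelId single character identifying the panel used.
#'
#' @seealso [partitionedLdScores()], [fitSldsc()]
#' @export
setClass("PartitionedLdScoreTable",
  representation(scores = "matrix", variants = "GRanges",
                 window = "integer", panelId = "character"))

setValidity("PartitionedLdScoreTable", function(object) {
  msg <- character()
  if (nrow(object@scores) != length(object@variants))
    msg <- c(msg, "nrow(scores) must equal length(variants)")
  if (is.null(colnames(object@scores)))
    msg <- c(msg, "scores must have annotation column names")
  if (any(object@scores < -1e-9))
    msg <- c(msg, "LD scores must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Peak-by-cell-state specificity matrix
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] holding a peak x
#' cell-state signal matrix together with the derived specificity scores
#' and within-state specificity ranks.  Assays:
#' \describe{
#'   \item{signal}{raw input signal.}
#'   \item{normalized}{column-quantile-normalized signal.}
#'   \item{score}{specificity score: each peak's normalized row divided by
#'     its Euclidean norm, so per peak the squared scores sum to 1.}
#'   \item{rank}{within-state rank of the score (1 = least specific,
#'     N = most specific).}
#'   \item{normRank}{rank / N, in (0, 1]; values near 1 mark peaks most
#'     selective for that state.}
#' }
#' `rowRanges` are the peak intervals; `metadata(x)$genomeBp` records the
#' synthetic genome length when the object was simulated.
#'
#' @seealso [specificityScores()], [simulatePeakMatrix()], [cheersTest()]
#' @export
setClass("PeakSpecificityMatrix", contains = "RangedSummarizedExperiment")

setValidity("PeakSpecificityMatrix", function(object) {
  need <- c("signal", "score", "rank", "normRank")
  miss <- setdiff(need, assayNames(object))
  if (length(miss))
    return(paste("missing assays:", paste(miss, collapse = ", ")))
  rk <- assay(object, "rank")
  n <- nrow(rk)
  if (n && !all(apply(rk, 2, function(col) all(sort(col) == seq_len(n)))))
    return("per state, ranks must be a permutation of 1..N")
  TRUE
})

#' Stratified LD-score regression result
#'
#' Per-annotation coefficient estimates from regressing per-variant GWAS
#' chi-square statistics on N * l(j, C) with a free intercept; standard
#' errors by delete-one-block jackknife over contiguous variant blocks.
#'
#' @slot coefficients data.frame with columns `annotation`, `tau`, `se`,
#'   `z`, `p` (one-sided, upper tail) and `p_adjusted` (Benjamini-Hochberg
#'   across the model annotations).
#' @slot intercept,interceptSE numeric, the free regression intercept and
#'   its jackknife SE.
#' @slot jackknife numeric matrix of delete-one-block estimates (blocks x
#'   coefficients, intercept first) used downstream for heritability SEs.
#' @slot nVariants,nBlocks integers.
#' @slot target character, the annotation of interest in a conditional
#'   model (NA for ordinary fits).
#' @slot weighted logical, whether heteroskedasticity weights were applied.
#'
#' @seealso [fitSldsc()], [fitConditional()], [coefficientDifferenceTest()],
#'   [heritabilitySummary()]
#' @export
setClass("RegressionResult",
  representation(coefficients = "data.frame", intercept = "numeric",
                 interceptSE = "numeric", jackknife = "matrix",
                 nVariants = "integer", nBlocks = "integer",
                 target = "character", weighted = "logical"))

setValidity("RegressionResult", function(object) {
  msg <- character()
  cf <- object@coefficients
  need <- c("annotation", "tau", "se", "z", "p")
  if (!all(need %in% names(cf)))
    msg <- c(msg, "coefficients must have annotation/tau/se/z/p columns")
  else {
    if (any(cf$se <= 0)) msg <- c(msg, "standard errors must be positive")
    if (any(cf$p <= 0 | cf$p >= 1)) msg <- c(msg, "p-values must lie in (0,1)")
  }
  if (length(msg)) msg else TRUE
})

#' Specificity-rank enrichment result
#'
#' Per cell state: the number of unique peaks overlapped by risk variants
#' (or their LD proxies), the mean normalized specificity rank of those
#' peaks, and a one-sided p-value against the null that overlapped peaks
#' are a random draw from the discrete-uniform rank distribution.
#'
#' @slot table data.frame with columns `state`, `n_peaks`, `mean_rank`,
#'   `z`, `p`, `p_bonferroni` (and `p_exact` when an exact null was also
#'   evaluated).
#' @slot nPeaksTotal integer N, the size of the peak universe after
#'   filtering.
#' @slot overlaps data.frame of variant-peak overlaps (`peak`, `variant`,
#'   `lead`), deduplicated rows; a peak may appear with several supporting
#'   variants but is counted once in `n_peaks`.
#' @slot method character, "normal", "exact" or "montecarlo".
#'
#' @seealso [cheersTest()], [overlapVariants()], [stimulationContrast()]
#' @export
setClass("CheersResult",
  representation(table = "data.frame", nPeaksTotal = "integer",
                 overlaps = "data.frame", method = "character"))

setValidity("CheersResult", function(object) {
  tab <- object@table
  msg <- character()
  need <- c("state", "n_peaks", "mean_rank", "z", "p", "p_bonferroni")
  if (!all(need %in% names(tab)))
    msg <- c(msg, "table must have state/n_peaks/mean_rank/z/p/p_bonferroni")
  else {
    ok <- is.na(tab$mean_rank) | (tab$mean_rank > 0 & tab$mean_rank <= 1)
    if (!all(ok)) msg <- c(msg, "mean normalized ranks must lie in (0,1]")
    if (any(tab$n_peaks > object@nPeaksTotal))
      msg <- c(msg, "n_peaks cannot exceed the peak universe size")
  }
  if (length(msg)) msg else TRUE
})
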