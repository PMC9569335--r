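#' @include cheers.R
NULL

#' Select cell-selective, variant-overlapped peaks for pathway analysis
#'
#' Returns the peaks that are both highly specific to at least one
#' designated cell state (normalized specificity rank strictly above
#' `specificityThreshold`) and overlapped by risk variants.
#'
#' @param peaks a [PeakSpecificityMatrix-class].
#' @param overlaps overlap table from [overlapVariants()] or a character
#'   vector of overlapped peak ids.
#' @param specificityThreshold strict rank threshold (default 0.9).
#' @param states designated states (default: all).
#' @return Character vector of peak ids (possibly empty; downstream ORA is
#'   then skipped with a notice).
#' @export
selectTestPeaks <- function(peaks, overlaps, specificityThreshold = 0.9,
                            states = NULL) {
  nr <- specificityRank(peaks, normalized = TRUE)
  if (is.null(states)) states <- colnames(nr)
  selective <- rownames(nr)[
    apply(nr[, states, drop = FALSE], 1L, max) > specificityThreshold]
  overlapped <- if (is.data.frame(overlaps)) unique(overlaps$peak)
                else unique(as.character(overlaps))
  out <- intersect(selective, overlapped)
  if (!length(out))
    message("selectTestPeaks: no peak passes both conditions")
  out
}

#' Assign peaks to genes
#'
#' For each peak, takes the union of genes whose body overlaps the peak
#' and genes whose promoter (TSS +/- `promoterWindow`) overlaps the peak;
#' when that union is empty, falls back to the single gene with the
#' nearest TSS, up to `maxTssDistance` bp away (further peaks map to no
#' gene).  The final gene list is deduplicated across peaks.
#'
#' @param peaks `GRanges` of peak intervals (or a
#'   [PeakSpecificityMatrix-class], optionally subset by peak ids via
#'   `peakIds`).
#' @param genes gene model `GRanges` with strand and `gene_id`/`tss`
#'   metadata (e.g. [simulateGeneModel()] or [readGeneModel()]).
#' @param maxTssDistance maximum TSS fallback distance in bp (default
#'   10000; a TSS exactly at the cap is accepted).  Distance is the gap —
#'   the number of bases strictly between the peak and the TSS, 0 for
#'   overlap or adjacency — as computed by
#'   [GenomicRanges::distanceToNearest()].
#' @param promoterWindow promoter half-width around the TSS in bp
#'   (default 3000).
#' @param peakIds optional peak names to restrict to.
#' @return Character vector of unique gene ids.
#' @export
peaksToGenes <- function(peaks, genes, maxTssDistance = 10000,
                         promoterWindow = 3000, peakIds = NULL) {
  if (is(peaks, "PeakSpecificityMatrix")) peaks <- rowRanges(peaks)
  if (!is.null(peakIds)) peaks <- peaks[peakIds]
  ids <- mcols(genes)$gene_id
  if (is.null(ids)) stop("gene model lacks a gene_id column")
  tssPos <- mcols(genes)$tss
  if (is.null(tssPos))
    tssPos <- ifelse(as.character(strand(genes)) == "-",
                     end(genes), start(genes))
  tss <- GRanges(seqnames(genes), IRanges(tssPos, width = 1L),
                 gene_id = ids)
  prom <- GRanges(seqnames(genes),
                  IRanges(pmax(1L, tssPos - promoterWindow),
                          tssPos + promoterWindow),
                  gene_id = ids)
  hitsBody <- findOverlaps(peaks, genes, ignore.strand = TRUE)
  hitsProm <- findOverlaps(peaks, prom, ignore.strand = TRUE)
  out <- character()
  covered <- unique(c(queryHits(hitsBody), queryHits(hitsProm)))
  out <- c(ids[subjectHits(hitsBody)], ids[subjectHits(hitsProm)])
  orphan <- setdiff(seq_along(peaks), covered)
  if (length(orphan)) {
    nn <- distanceToNearest(peaks[orphan], tss, ignore.strand = TRUE)
    ok <- mcols(nn)$distance <= maxTssDistance
    out <- c(out, ids[subjectHits(nn)[ok]])
  }
  unique(out)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the test list overlaps the set more
#' than expected under random draws from the universe: with universe size
#' M, set size K (after intersecting the set with the universe), list size
#' n and overlap k, the one-sided p-value is the upper hypergeometric tail
#' `P(X >= k)`.  Benjamini-Hochberg adjustment across sets; results are
#' sorted by p.
#'
#' @param geneList character vector of test genes (intersected with the
#'   universe; a message reports any dropped).
#' @param geneSets named list of character vectors (e.g. from
#'   [readGmt()]).
#' @param universe character vector of background genes.
#' @return data.frame with columns `set, k, K, n, M, p, p_adjusted,
#'   gene_ratio, genes`, sorted by p.  Sets with empty universe
#'   intersection are skipped with a message.
#' @examples
#' oraTest(c("g1", "g2"), list(s = paste0("g", 1:5)), paste0("g", 1:10))
#' @export
oraTest <- function(geneList, geneSets, universe) {
  universe <- unique(universe)
  M <- length(universe)
  drop <- setdiff(geneList, universe)
  if (length(drop))
    message("oraTest: ", length(drop), " test gene(s) outside universe dropped")
  geneList <- unique(intersect(geneList, universe))
  n <- length(geneList)
  rows <- lapply(names(geneSets), function(s) {
    set <- intersect(unique(geneSets[[s]]), universe)
    if (!length(set)) {
      message("oraTest: set '", s, "' has empty universe intersection; skipped")
      return(NULL)
    }
    K <- length(set)
    hit <- intersect(geneList, set)
    k <- length(hit)
    p <- phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(set = s, k = k, K = K, n = n, M = M, p = p,
               gene_ratio = if (n > 0) k / n else NA_real_,
               genes = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), M = integer(), p = numeric(),
                      p_adjusted = numeric(), gene_ratio = numeric(),
                      genes = character()))
  out$p_adjusted <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set),
             c("set", "k", "K", "n", "M", "p", "p_adjusted",
               "gene_ratio", "genes")]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1 (delegates to [stats::p.adjust()]).
#'
#' @param pvalues numeric p-values.
#' @return Adjusted p-values.
#' @export
bhAdjust <- function(pvalues) p.adjust(pvalues, method = "BH")
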