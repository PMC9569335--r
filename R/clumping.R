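#' @include utils.R
NULL

#' Filter summary statistics on minor allele count
#'
#' Removes variants with minor allele count below `minMac` (strictly; a
#' variant at exactly `minMac` is retained).  When a `MAC` column is
#' absent the count is derived as `round(2 * N * min(FRQ, 1 - FRQ))`.
#'
#' @param stats summary-statistic data.frame.
#' @param minMac minimum minor allele count (default 10).
#' @return Filtered data.frame with attribute `nRemoved`.
#' @export
filterMac <- function(stats, minMac = 10) {
  checkSumstats(stats, require = "SNP")
  mac <- if ("MAC" %in% names(stats)) stats$MAC
         else if (all(c("FRQ", "N") %in% names(stats)))
           round(2 * stats$N * pmin(stats$FRQ, 1 - stats$FRQ))
         else stop("unusable record set: neither MAC nor FRQ+N present")
  keep <- mac >= minMac
  message("filterMac: removed ", sum(!keep), " of ", length(keep),
          " variants with MAC < ", minMac)
  out <- stats[keep, , drop = FALSE]
  attr(out, "nRemoved") <- sum(!keep)
  out
}

#' Filter summary statistics on reference-panel allele frequency
#'
#' Keeps only variants present in the reference panel with panel minor
#' allele frequency strictly greater than `minMaf`, mirroring the
#' convention of restricting to variants well represented in an external
#' reference panel.
#'
#' @param stats summary-statistic data.frame.
#' @param panel a [GenotypePanel-class].
#' @param minMaf strict lower MAF bound (default 0.01).
#' @return Filtered data.frame with attribute `nRemoved`.
#' @export
filterMafPanel <- function(stats, panel, minMaf = 0.01) {
  checkSumstats(stats, require = "SNP")
  f <- colMeans(genotypes(panel)) / 2
  maf <- setNames(pmin(f, 1 - f), variantIds(panel))
  pm <- maf[stats$SNP]
  keep <- !is.na(pm) & pm > minMaf
  message("filterMafPanel: removed ", sum(!keep), " of ", length(keep),
          " variants (absent from panel or MAF <= ", minMaf, ")")
  out <- stats[keep, , drop = FALSE]
  attr(out, "nRemoved") <- sum(!keep)
  out
}

#' Distance-based clumping to independent lead variants
#'
#' Restricts to genome-wide-significant variants (`P < pThreshold`,
#' strictly) outside the excluded region, then greedily selects the
#' smallest-p remaining variant as a lead and discards all remaining
#' significant variants within `distanceBp` on the same chromosome,
#' repeating until none remain.  A variant exactly `distanceBp` away is
#' clumped (leads must be separated by strictly more than `distanceBp`).
#' Ties on p are broken by (chromosome, position) order, so the selection
#' never depends on input row order.
#'
#' @param stats summary-statistic data.frame (needs `SNP, CHR, BP, P`).
#' @param pThreshold genome-wide significance threshold (default 5e-8).
#' @param distanceBp clumping distance in bp (default 500000, i.e.
#'   +/- 500 kb).
#' @param mhc `GRanges` region to exclude before clumping (default the
#'   GRCh38 MHC, [mhcRegion()]); `NULL` to skip.
#' @param disorder optional label stored with the result.
#' @return A data.frame of lead variants (`disorder, SNP, CHR, BP, P`),
#'   ordered by (CHR, BP), with a `provenance` attribute recording the
#'   thresholds and per-filter counts.  Zero significant variants yield a
#'   valid empty set.
#' @examples
#' stats <- data.frame(SNP = c("a", "b", "c"), CHR = "chr1",
#'   BP = c(1000000, 1400000, 2100000), P = c(1e-10, 1e-9, 1e-9))
#' clumpVariants(stats, mhc = NULL)$SNP   # "a", "c"
#' @export
clumpVariants <- function(stats, pThreshold = 5e-8, distanceBp = 500000,
                          mhc = mhcRegion("GRCh38"), disorder = NA_character_) {
  checkSumstats(stats)
  n0 <- nrow(stats)
  sig <- stats[stats$P < pThreshold, , drop = FALSE]
  nSig <- nrow(sig)
  nMhc <- 0L
  if (!is.null(mhc) && nrow(sig)) {
    sig <- excludeRegion(sig, mhc)
    nMhc <- attr(sig, "nRemoved")
  }
  sig$CHR <- normChr(as.character(sig$CHR))
  ord <- order(sig$P, sig$CHR, sig$BP)
  sig <- sig[ord, , drop = FALSE]
  leads <- integer()
  alive <- rep(TRUE, nrow(sig))
  for (i in seq_len(nrow(sig))) {
    if (!alive[i]) next
    leads <- c(leads, i)
    alive[alive & sig$CHR == sig$CHR[i] &
            abs(sig$BP - sig$BP[i]) <= distanceBp] <- FALSE
  }
  out <- sig[leads, c("SNP", "CHR", "BP", "P"), drop = FALSE]
  out <- out[order(out$CHR, out$BP), , drop = FALSE]
  out <- data.frame(disorder = rep(disorder, nrow(out)), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!nrow(out)) message("clumpVariants: no genome-wide-significant variants")
  attr(out, "provenance") <- list(
    pThreshold = pThreshold, distanceBp = distanceBp,
    mhc = if (is.null(mhc)) NULL else as.character(mhc),
    nInput = n0, nSignificant = nSig, nRemovedMhc = nMhc,
    nLeads = nrow(out))
  out
}

#' Minimum-locus eligibility check
#'
#' Specificity-rank enrichment on a handful of loci is underpowered and
#' unstable; disorders with fewer than `minLoci` independent
#' genome-wide-significant loci are flagged ineligible for downstream
#' analysis (default 3, so a disorder with only two loci is excluded).
#'
#' @param leads data.frame of lead variants (as from [clumpVariants()]).
#' @param minLoci minimum lead count (default 3).
#' @return Logical flag: `TRUE` when eligible.
#' @export
checkMinLoci <- function(leads, minLoci = 3) {
  eligible <- nrow(leads) >= minLoci
  if (!eligible)
    message("only ", nrow(leads), " lead variant(s) (< ", minLoci,
            "): ineligible for specificity-rank analysis")
  eligible
}
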