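#' @include AllGenerics.R
NULL

#' Peak specificity scores and within-state ranks
#'
#' Processes a raw peak-by-cell-state signal matrix into specificity
#' scores and normalized specificity ranks:
#' \enumerate{
#'   \item quantile-normalize columns (via \pkg{limma}), so cell states are
#'     comparable;
#'   \item drop the bottom `dropBottom` fraction of peaks by mean
#'     normalized signal (weak peaks carry no specificity information);
#'   \item divide each peak's row by its Euclidean norm, giving
#'     specificity scores that sum-of-squares to 1 per peak;
#'   \item rank scores within each state (1 = least specific,
#'     N = most specific) and normalize ranks to (0, 1].
#' }
#' Each step can be switched off to match alternative processing chains.
#'
#' @param signal numeric matrix, peaks x cell states (>= 2 of each), with
#'   column names; or a [PeakSpecificityMatrix-class] to reprocess.
#' @param peaks optional `GRanges` of peak intervals (one per row).
#' @param quantileNormalize,euclideanScale logical switches.
#' @param dropBottom fraction of lowest-mean peaks to drop (default 0.1;
#'   0 disables).
#' @param rowData optional `DataFrame` of per-peak metadata (e.g. planted
#'   truth) carried through filtering.
#' @return A [PeakSpecificityMatrix-class].
#' @export
specificityScores <- function(signal, peaks = NULL, quantileNormalize = TRUE,
                              dropBottom = 0.1, euclideanScale = TRUE,
                              rowData = NULL) {
  if (is(signal, "PeakSpecificityMatrix")) {
    peaks <- rowRanges(signal)
    rowData <- rowData(signal)
    signal <- assay(signal, "signal")
  }
  stopifnot(is.matrix(signal), nrow(signal) >= 2L, ncol(signal) >= 2L)
  if (is.null(colnames(signal)))
    colnames(signal) <- paste0("state", seq_len(ncol(signal)))
  if (is.null(peaks))
    peaks <- GRanges("unplaced",
                     IRanges(seq_len(nrow(signal)) * 1000L, width = 1L))
  stopifnot(length(peaks) == nrow(signal))
  zero <- rowSums(signal != 0) == 0L
  if (any(zero)) {
    warning("dropping ", sum(zero), " all-zero peak row(s)")
    signal <- signal[!zero, , drop = FALSE]
    peaks <- peaks[!zero]
    if (!is.null(rowData)) rowData <- rowData[!zero, , drop = FALSE]
  }
  norm <- if (quantileNormalize) limma::normalizeQuantiles(signal)
          else signal
  if (dropBottom > 0) {
    mu <- rowMeans(norm)
    keep <- mu > quantile(mu, dropBottom)
    signal <- signal[keep, , drop = FALSE]
    norm <- norm[keep, , drop = FALSE]
    peaks <- peaks[keep]
    if (!is.null(rowData)) rowData <- rowData[keep, , drop = FALSE]
  }
  score <- if (euclideanScale) norm / sqrt(rowSums(norm^2)) else norm
  N <- nrow(score)
  rk <- apply(score, 2L, rank, ties.method = "first")
  dimnames(rk) <- dimnames(score)
  rownames(signal) <- rownames(norm) <- rownames(score) <- rownames(rk) <-
    sprintf("peak%05d", seq_len(N))
  names(peaks) <- rownames(score)
  se <- SummarizedExperiment(
    assays = list(signal = signal, normalized = norm, score = score,
                  rank = rk, normRank = rk / N),
    rowRanges = peaks)
  if (!is.null(rowData)) rowData(se) <- cbind(rowData(se), rowData)
  new("PeakSpecificityMatrix", se)
}

#' Overlap risk variants with peaks
#'
#' A peak is overlapped iff at least one variant from at least one LD
#' neighborhood lies within it; the returned set is deduplicated so each
#' peak counts once even when several variants support it.
#'
#' @param peaks a [PeakSpecificityMatrix-class].
#' @param variants a width-1 `GRanges` of variant positions with optional
#'   `variant` and `lead` metadata columns (e.g. from
#'   [neighborhoodRanges()] or [plantRiskVariants()]).
#' @return data.frame with one row per (peak, variant) pair: `peak`,
#'   `variant`, `lead`; attribute `peaks` holds the unique overlapped peak
#'   ids.
#' @export
overlapVariants <- function(peaks, variants) {
  stopifnot(is(peaks, "PeakSpecificityMatrix"), is(variants, "GRanges"))
  hits <- findOverlaps(rowRanges(peaks), variants, ignore.strand = TRUE)
  vid <- mcols(variants)$variant
  if (is.null(vid)) vid <- paste0("v", seq_along(variants))
  lid <- mcols(variants)$lead
  if (is.null(lid)) lid <- vid
  out <- unique(data.frame(
    peak = names(rowRanges(peaks))[queryHits(hits)],
    variant = vid[subjectHits(hits)],
    lead = lid[subjectHits(hits)],
    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "peaks") <- unique(out$peak)
  out
}

# Exact upper-tail probability P(sum of n iid uniform{1..N} ranks >= s).
# Iterative convolution with a sliding cumulative-sum window, O(n^2 * N).
exactRankSumTail <- function(n, N, s) {
  dist <- rep(1 / N, N)           # support of partial sum i: i .. i*N
  if (n > 1) for (i in 2:n) {
    len <- length(dist)
    cs <- c(0, cumsum(dist))
    j <- seq_len(len + N - 1L)    # new support has len + N - 1 cells
    hi <- pmin(j, len)            # window over the previous distribution:
    lo <- pmax(j - N, 0L)         # stored cells (j - N + 1) .. j
    dist <- (cs[hi + 1L] - cs[lo + 1L]) / N
  }
  support <- seq.int(n, n * N)
  sum(dist[support >= s - 1e-9])
}

#' Specificity-rank enrichment test
#'
#' For each cell state, takes the unique peaks overlapped by risk variants
#' and compares their mean normalized specificity rank x-bar in that state
#' against the null that overlapped peaks are a random draw of n i.i.d.
#' discrete-uniform ranks: null mean `mu = (N + 1) / (2N)`, SE
#' `sigma_n = sqrt((N^2 - 1) / (12 N^2 n))`, one-sided
#' `p = 1 - Phi((x-bar - mu) / sigma_n)`.  Because the null is discrete, a
#' standard continuity correction (half a rank unit on the rank-sum scale,
#' i.e. `1/(2nN)` on the mean scale) is applied by default, as in other
#' normal approximations to rank statistics; it is negligible whenever
#' `n * N` is large and can be switched off.  Bonferroni adjustment across
#' the tested states (family size `mBonferroni`).  An exact enumerated
#' null (rank-sum convolution) or a Monte-Carlo null is available for
#' validating the normal approximation at small `n * N` (recommended for
#' overlaps of only one or two peaks, where no normal approximation is
#' accurate).
#'
#' @param peaks a [PeakSpecificityMatrix-class].
#' @param overlaps overlap table from [overlapVariants()] (or a character
#'   vector of overlapped peak ids).
#' @param states states to test (default: all columns).
#' @param method `"normal"` (default), `"exact"`, or `"montecarlo"`.
#' @param continuityCorrection apply the half-rank continuity correction
#'   to the normal approximation (default `TRUE`).
#' @param mBonferroni Bonferroni family size (default: number of tested
#'   states; must be >= that).
#' @param nMc Monte-Carlo draws for `method = "montecarlo"`.
#' @param seed seed for the Monte-Carlo null.
#' @return A [CheersResult-class].  With zero overlapped peaks the result
#'   is marked untestable (NA statistics) with a message.
#' @export
cheersTest <- function(peaks, overlaps, states = NULL,
                       method = c("normal", "exact", "montecarlo"),
                       mBonferroni = NULL, nMc = 100000L, seed = 1L,
                       continuityCorrection = TRUE) {
  method <- match.arg(method)
  stopifnot(is(peaks, "PeakSpecificityMatrix"))
  nr <- specificityRank(peaks, normalized = TRUE)
  if (is.null(states)) states <- colnames(nr)
  if (is.null(mBonferroni)) mBonferroni <- length(states)
  if (mBonferroni < length(states))
    stop("Bonferroni family size smaller than the number of tests")
  peakIds <- if (is.data.frame(overlaps)) unique(overlaps$peak)
             else unique(as.character(overlaps))
  peakIds <- intersect(peakIds, rownames(nr))
  N <- nrow(nr)
  n <- length(peakIds)
  mu <- (N + 1) / (2 * N)
  if (n == 0L) {
    message("cheersTest: no overlapped peaks; result untestable")
    tab <- data.frame(state = states, n_peaks = 0L, mean_rank = NA_real_,
                      z = NA_real_, p = NA_real_, p_bonferroni = NA_real_)
    return(new("CheersResult", table = tab, nPeaksTotal = N,
               overlaps = if (is.data.frame(overlaps)) overlaps else
                 data.frame(peak = character(), variant = character(),
                            lead = character()),
               method = method))
  }
  sigma <- sqrt((N^2 - 1) / (12 * N^2 * n))
  xbar <- colMeans(nr[peakIds, states, drop = FALSE])
  z <- (xbar - mu) / sigma
  cc <- if (continuityCorrection) 1 / (2 * n * N) else 0
  p <- switch(method,
    normal = pnorm((xbar - cc - mu) / sigma, lower.tail = FALSE),
    exact = vapply(states, function(s) {
      sObs <- sum(assay(peaks, "rank")[peakIds, s])
      exactRankSumTail(n, N, sObs)
    }, numeric(1)),
    montecarlo = withSeed(seed, {
      null <- matrix(sample.int(N, nMc * n, replace = TRUE) / N, nMc, n)
      nullMeans <- rowMeans(null)
      vapply(states, function(s)
        (sum(nullMeans >= xbar[s] - 1e-12) + 1) / (nMc + 1), numeric(1))
    }))
  tab <- data.frame(state = states, n_peaks = n, mean_rank = as.numeric(xbar),
                    z = as.numeric(z), p = as.numeric(p),
                    p_bonferroni = pmin(1, as.numeric(p) * mBonferroni),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new("CheersResult", table = tab, nPeaksTotal = N,
      overlaps = if (is.data.frame(overlaps)) overlaps else
        data.frame(peak = peakIds, variant = NA_character_,
                   lead = NA_character_),
      method = method)
}

#' Contrast enrichment between two conditions
#'
#' One-sided two-sample Z-test comparing the mean specificity rank of a
#' cell state between two runs on the same peak universe (e.g. stimulated
#' vs unstimulated cells for the same disorder):
#' `Z = (xbar1 - xbar2) / sqrt(2 * SE^2)` with `SE = sigma_n`, which is
#' identical across conditions because peaks are called on the dataset as
#' a whole; `p = 1 - Phi(Z)`.
#'
#' @param result1,result2 [CheersResult-class] objects with identical peak
#'   universe size N and overlap count n.
#' @param state1 state name in `result1`; `state2` (default the same) in
#'   `result2`.
#' @return Named numeric vector `c(z, p)`.
#' @export
stimulationContrast <- function(result1, result2, state1, state2 = state1) {
  t1 <- enrichmentTable(result1); t2 <- enrichmentTable(result2)
  i1 <- match(state1, t1$state); i2 <- match(state2, t2$state)
  if (is.na(i1) || is.na(i2)) stop("state not present in results")
  if (result1@nPeaksTotal != result2@nPeaksTotal ||
      t1$n_peaks[i1] != t2$n_peaks[i2])
    stop("incomparable results: peak universe N or overlap count n differ")
  N <- result1@nPeaksTotal; n <- t1$n_peaks[i1]
  se <- sqrt((N^2 - 1) / (12 * N^2 * n))
  z <- (t1$mean_rank[i1] - t2$mean_rank[i2]) / sqrt(2 * se^2)
  c(z = z, p = pnorm(z, lower.tail = FALSE))
}

#' Bonferroni adjustment
#'
#' Family-wise error correction `min(1, p * m)` across a declared family
#' of `m` tests (e.g. the cell states tested per disorder per dataset).
#'
#' @param pvalues numeric p-values.
#' @param m family size (default `length(pvalues)`; must be >= that).
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroniAdjust <- function(pvalues, m = length(pvalues)) {
  if (m < length(pvalues)) stop("family size m smaller than number of tests")
  pmin(1, pvalues * m)
}
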