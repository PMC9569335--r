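#' @include AllGenerics.R
NULL

#' Squared-correlation LD between two panel variants
#'
#' Plain squared Pearson correlation of the two allele-count columns.  An
#' optional finite-sample bias adjustment (`r2 - (1 - r2)/(n - 2)`) mirrors
#' the estimator used by the standard LD-score software; it is off by
#' default so the statistic is the textbook r^2.
#'
#' @param panel a [GenotypePanel-class].
#' @param i,j variant ids (character) or column indices.
#' @param biasAdjust apply the finite-sample adjustment.
#' @return r^2 in `[0, 1]` (the adjusted estimator may be slightly
#'   negative).
#' @export
pairwiseR2 <- function(panel, i, j, biasAdjust = FALSE) {
  g <- genotypes(panel)
  gi <- g[, i]; gj <- g[, j]
  if (sd(gi) == 0 || sd(gj) == 0)
    stop("undefined correlation: monomorphic variant")
  r2 <- cor(gi, gj)^2
  if (biasAdjust) r2 <- r2 - (1 - r2) / (nrow(g) - 2)
  r2
}

#' Partitioned LD scores
#'
#' For every panel variant j and every annotation C computes
#' `l(j, C) = sum_{k in C, |pos_k - pos_j| <= windowBp} r2(j, k)`,
#' including the self term (r^2 = 1) when j is a member of C.  Computation
#' is chunked per chromosome using standardized-genotype cross-products.
#'
#' @param panel a [GenotypePanel-class].
#' @param annotations named list of [AnnotationSet-class] objects (or
#'   numeric membership vectors over panel variants).
#' @param windowBp window half-width in base pairs (> 0).
#' @param biasAdjust use the finite-sample-adjusted r^2 estimator (self
#'   terms remain exactly 1).
#' @param chunkSize number of focal variants per cross-product chunk.
#' @return A [PartitionedLdScoreTable-class].
#' @export
partitionedLdScores <- function(panel, annotations, windowBp = 1000000L,
                                biasAdjust = FALSE, chunkSize = 500L) {
  stopifnot(windowBp > 0)
  if (is.null(names(annotations)) || any(!nzchar(names(annotations))))
    stop("annotations must be a named list")
  g <- genotypes(panel)
  n <- nrow(g); m <- ncol(g)
  vr <- variantRanges(panel)
  A <- vapply(names(annotations), function(a) {
    x <- annotations[[a]]
    mem <- if (is(x, "AnnotationSet")) annotateVariants(panel, x)
           else as.numeric(x)
    stopifnot(length(mem) == m)
    if (sum(mem) == 0)
      warning("annotation '", a, "' covers no panel variant; ",
              "LD-score column will be all zero")
    mem
  }, numeric(m))
  Xs <- scale(g)
  pos <- start(vr)
  chr <- as.character(seqnames(vr))
  scores <- matrix(0, m, ncol(A), dimnames = list(variantIds(panel),
                                                  colnames(A)))
  for (cc in unique(chr)) {
    idx <- which(chr == cc)
    p <- pos[idx]
    for (lo in seq(1L, length(idx), by = chunkSize)) {
      hi <- min(lo + chunkSize - 1L, length(idx))
      # window bounds for the whole chunk, then per-column masking
      wlo <- findInterval(p[lo] - windowBp - 0.5, p) + 1L
      whi <- findInterval(p[hi] + windowBp + 0.5, p)
      cols <- idx[wlo:whi]
      r <- crossprod(Xs[, idx[lo:hi], drop = FALSE],
                     Xs[, cols, drop = FALSE]) / (n - 1)
      r2 <- r * r
      if (biasAdjust) {
        r2 <- r2 - (1 - r2) / (n - 2)
        # self terms are exact
        for (q in seq_len(hi - lo + 1L)) {
          self <- match(idx[lo + q - 1L], cols)
          r2[q, self] <- 1
        }
      }
      inWin <- abs(outer(p[lo:hi], p[wlo:whi], "-")) <= windowBp
      r2[!inWin] <- 0
      scores[idx[lo:hi], ] <- scores[idx[lo:hi], , drop = FALSE] +
        r2 %*% A[cols, , drop = FALSE]
    }
  }
  new("PartitionedLdScoreTable", scores = scores, variants = vr,
      window = as.integer(windowBp), panelId = "panel")
}

#' LD expansion of lead variants
#'
#' For each lead variant, finds all panel variants within `windowBp` whose
#' r^2 with the lead is strictly greater than `r2Threshold`; the lead
#' itself (r^2 = 1) is always included.  Used to make locus overlap robust
#' to tag-variant differences between association studies.
#'
#' @param panel a [GenotypePanel-class].
#' @param leads character vector of lead variant ids.
#' @param r2Threshold strict lower bound on r^2 (default 0.8).
#' @param windowBp search window half-width in bp.
#' @return A data.frame with columns `lead`, `variant`, `chr`, `pos`, `r2`
#'   (one row per neighborhood member).  Leads absent from the panel yield
#'   a lead-only row with NA position and a warning.
#' @export
expandLeads <- function(panel, leads, r2Threshold = 0.8,
                        windowBp = 1000000L) {
  g <- genotypes(panel)
  vr <- variantRanges(panel)
  ids <- variantIds(panel)
  pos <- start(vr); chr <- as.character(seqnames(vr))
  out <- vector("list", length(leads))
  absent <- setdiff(leads, ids)
  if (length(absent))
    warning("lead(s) absent from panel, recorded unexpanded: ",
            paste(absent, collapse = ", "))
  for (k in seq_along(leads)) {
    lead <- leads[k]
    j <- match(lead, ids)
    if (is.na(j)) {
      out[[k]] <- data.frame(lead = lead, variant = lead, chr = NA_character_,
                             pos = NA_integer_, r2 = 1)
      next
    }
    near <- which(chr == chr[j] & abs(pos - pos[j]) <= windowBp)
    r2 <- as.numeric(cor(g[, j], g[, near, drop = FALSE]))^2
    keep <- near[r2 > r2Threshold | near == j]
    out[[k]] <- data.frame(lead = lead, variant = ids[keep],
                           chr = chr[keep], pos = pos[keep],
                           r2 = r2[match(keep, near)])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "r2Threshold") <- r2Threshold
  attr(res, "windowBp") <- windowBp
  res
}

#' Variant positions of LD neighborhoods as GRanges
#'
#' Converts the [expandLeads()] table (or any data.frame with
#' `chr`/`pos`/`variant`/`lead` columns) into a width-1 `GRanges` suitable
#' for peak overlap.
#'
#' @param neighborhoods data.frame as returned by [expandLeads()].
#' @return A `GRanges` with `variant` and `lead` metadata columns.
#' @export
neighborhoodRanges <- function(neighborhoods) {
  nb <- neighborhoods[!is.na(neighborhoods$pos), , drop = FALSE]
  GRanges(nb$chr, IRanges(nb$pos, width = 1L),
          variant = nb$variant, lead = nb$lead)
}
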