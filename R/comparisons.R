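#' @include cheers.R annotations.R
NULL

#' Cross-disorder variant-peak sharing counts
#'
#' Given per-disorder sets of overlapped peaks (each peak counted once per
#' disorder regardless of how many variants support it), computes the
#' disjoint intersection cells over the disorder power set — the numbers
#' behind a Venn/upset summary.
#'
#' @param overlaps named list: per disorder, either the data.frame from
#'   [overlapVariants()] or a character vector of overlapped peak ids.
#' @return list with `membership` (logical peak x disorder matrix) and
#'   `cells` (data.frame `pattern`, `count`; patterns like `"A&B"`,
#'   disjoint, summing to the number of distinct overlapped peaks).
#' @export
sharingCounts <- function(overlaps) {
  stopifnot(is.list(overlaps), !is.null(names(overlaps)))
  sets <- lapply(overlaps, function(x)
    if (is.data.frame(x)) unique(x$peak) else unique(as.character(x)))
  peaks <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) peaks %in% s,
                       logical(length(peaks)))
  if (length(peaks) == 1L)
    membership <- matrix(membership, nrow = 1L,
                         dimnames = list(peaks, names(sets)))
  else rownames(membership) <- peaks
  pattern <- apply(membership, 1L, function(row)
    paste(names(sets)[row], collapse = "&"))
  cells <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(cells) <- c("pattern", "count")
  cells <- cells[order(-cells$count, cells$pattern), , drop = FALSE]
  rownames(cells) <- NULL
  list(membership = membership, cells = cells)
}

#' Discordant cell-selective peaks between two disorders
#'
#' Selects peaks that are selective for at least one designated cell state
#' (normalized specificity rank strictly above `specificityThreshold`) and
#' splits them into those overlapped by disorder A's risk variants but not
#' disorder B's, and vice versa.  Optionally attaches regulatory-element
#' classes and per-variant paired association statistics from the two
#' disorders' summary-stat tables, to check whether apparent discordance
#' merely reflects thresholding of near-significant associations.
#'
#' @param peaks a [PeakSpecificityMatrix-class] (the shared peak universe).
#' @param overlapsA,overlapsB overlap tables from [overlapVariants()] for
#'   disorders A and B.
#' @param specificityThreshold strict rank threshold (default 0.9).
#' @param states designated cell states (default: all).
#' @param classes optional list of [AnnotationSet-class] element classes
#'   for [classifyPeakElements()].
#' @param statsA,statsB optional summary-stat data.frames for paired
#'   per-variant statistics at the discordant peaks.
#' @return list with `selectivePeaks`, `onlyA`, `onlyB` (peak id vectors;
#'   `onlyA` and `onlyB` are disjoint by construction), `classes`
#'   (per-peak labels, when requested) and `variantStats` (paired
#'   BETA/Z/P per overlapping variant, when requested).
#' @export
discordantPeaks <- function(peaks, overlapsA, overlapsB,
                            specificityThreshold = 0.9, states = NULL,
                            classes = NULL, statsA = NULL, statsB = NULL) {
  nr <- specificityRank(peaks, normalized = TRUE)
  if (is.null(states)) states <- colnames(nr)
  selective <- rownames(nr)[
    apply(nr[, states, drop = FALSE], 1L, max) > specificityThreshold]
  pa <- intersect(unique(overlapsA$peak), selective)
  pb <- intersect(unique(overlapsB$peak), selective)
  onlyA <- setdiff(pa, pb)
  onlyB <- setdiff(pb, pa)
  out <- list(selectivePeaks = selective, onlyA = onlyA, onlyB = onlyB)
  if (!is.null(classes)) {
    disc <- rowRanges(peaks)[c(onlyA, onlyB)]
    out$classes <- classifyPeakElements(disc, classes)
  }
  if (!is.null(statsA) && !is.null(statsB)) {
    subA <- overlapsA[overlapsA$peak %in% c(onlyA, onlyB), , drop = FALSE]
    subB <- overlapsB[overlapsB$peak %in% c(onlyA, onlyB), , drop = FALSE]
    subA$disorder <- rep("A", nrow(subA))
    subB$disorder <- rep("B", nrow(subB))
    vars <- rbind(subA, subB)
    pick <- function(stats, v) {
      i <- match(v, stats$SNP)
      data.frame(beta = stats$BETA[i], z = stats$BETA[i] / stats$SE[i],
                 p = stats$P[i])
    }
    a <- pick(statsA, vars$variant); b <- pick(statsB, vars$variant)
    names(a) <- paste0(names(a), "_A"); names(b) <- paste0(names(b), "_B")
    out$variantStats <- cbind(vars, a, b)
  }
  out
}

#' Classify peaks by regulatory-element type
#'
#' Attaches to every peak each element class (promoter, enhancer, genic
#' enhancer, ...) whose intervals share at least one base pair with the
#' peak; multi-label by default, with an optional priority collapse
#' (promoter > genic enhancer > enhancer) for single-label summaries.
#'
#' @param peaks `GRanges` of peak intervals (named) or a
#'   [PeakSpecificityMatrix-class].
#' @param classes named list of [AnnotationSet-class] objects.
#' @param priority optional character vector of class names in decreasing
#'   priority; when given, one label per peak (`NA` if none).
#' @return Multi-label: named list of character vectors (one per peak).
#'   With `priority`: named character vector.
#' @export
classifyPeakElements <- function(peaks, classes, priority = NULL) {
  if (is(peaks, "PeakSpecificityMatrix")) peaks <- rowRanges(peaks)
  if (is.null(names(peaks))) names(peaks) <- paste0("peak", seq_along(peaks))
  hitmat <- vapply(classes, function(a)
    overlapsAny(peaks, annotationRanges(a), ignore.strand = TRUE),
    logical(length(peaks)))
  if (length(peaks) == 1L)
    hitmat <- matrix(hitmat, nrow = 1L,
                     dimnames = list(names(peaks), names(classes)))
  if (!is.null(priority)) {
    lab <- apply(hitmat[, priority, drop = FALSE], 1L, function(row) {
      i <- which(row)[1]
      if (is.na(i)) NA_character_ else priority[i]
    })
    return(setNames(lab, names(peaks)))
  }
  out <- apply(hitmat, 1L, function(row) names(classes)[row],
               simplify = FALSE)
  setNames(out, names(peaks))
}

# All permutations of 1..n as an n! x n integer matrix (n <= 10).
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Spearman correlation with exact small-sample p-value and bootstrap CI
#'
#' Computes Spearman's statistic `S = sum(d_i^2)` (squared rank
#' differences) and `rho = 1 - 6S / (n(n^2 - 1))`.  Without ties and for
#' `n <= 10`, the p-value is exact, from full enumeration of all `n!` rank
#' permutations (two-sided by default: twice the smaller tail probability
#' of S, capped at 1 — the convention under which a sample rho of 0 gives
#' p = 1).  For larger n a t approximation is used.  With ties, the
#' general rank-correlation formula applies and exact enumeration is
#' disabled with a warning.  A percentile bootstrap confidence interval
#' (default 10,000 replicates, seeded) accompanies the estimate.
#'
#' @param x,y paired numeric vectors, `n >= 3`, no missing values.
#' @param nBoot bootstrap replicates (0 disables the CI).
#' @param seed seed for the bootstrap.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param conf confidence level for the bootstrap CI.
#' @return list of class `"CorrelationResult"`: `n`, `S`, `rho`, `p`,
#'   `method` (`"exact"`, `"t-approximation"` or `"ties"`), `ci`,
#'   `nBoot`, `seed`.
#' @examples
#' r <- spearmanExact(1:9, c(2, 1, 4, 3, 5, 7, 6, 9, 8), nBoot = 0)
#' r$rho
#' @export
spearmanExact <- function(x, y, nBoot = 10000L, seed = 1L,
                          alternative = c("two.sided", "greater", "less"),
                          conf = 0.95) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  rx <- rank(x); ry <- rank(y)
  ties <- anyDuplicated(rx) || anyDuplicated(ry)
  if (ties) {
    warning("ties present: using the general rank-correlation formula; ",
            "exact enumeration disabled")
    rho <- cor(rx, ry)
    S <- sum((rx - ry)^2)
  } else {
    S <- sum((rx - ry)^2)
    rho <- 1 - 6 * S / (n * (n^2 - 1))
  }
  if (!ties && n <= 10L) {
    perms <- allPermutations(n)
    base <- seq_len(n)
    Sdist <- rowSums(sweep(perms, 2L, base)^2)
    pLess <- mean(Sdist <= S)      # small S = positive correlation
    pGreater <- mean(Sdist >= S)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(pLess, pGreater)),
      greater = pLess,             # rho > 0 corresponds to small S
      less = pGreater)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    pUpper <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(pUpper, 1 - pUpper)),
      greater = pUpper, less = 1 - pUpper)
    method <- if (ties) "ties" else "t-approximation"
  }
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0) {
    ci <- withSeed(seed, {
      reps <- vapply(seq_len(nBoot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        suppressWarnings(cor(x[idx], y[idx], method = "spearman"))
      }, numeric(1))
      reps <- reps[!is.na(reps)]
      unname(quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
    })
  }
  structure(list(n = n, S = S, rho = rho, p = p, method = method,
                 ci = ci, nBoot = nBoot, seed = seed,
                 alternative = alternative),
            class = "CorrelationResult")
}

#' Reconstruct Spearman's rho and exact p from a printed S statistic
#'
#' Published analyses often report only Spearman's `S = sum(d_i^2)` with
#' the residual degrees of freedom (n - 2).  Without ties,
#' `rho = 1 - 6S / (n(n^2 - 1))`, and for `n <= 10` the exact two-sided
#' p-value can be recovered by enumerating the permutation distribution
#' of S (twice the smaller tail, capped at 1).
#'
#' @param S Spearman's sum of squared rank differences.
#' @param n number of pairs.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list with `rho` and `p` (`p` is NA for n > 10).
#' @examples
#' spearmanFromS(16, 9)   # rho 0.867, p 0.005
#' @export
spearmanFromS <- function(S, n,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  rho <- 1 - 6 * S / (n * (n^2 - 1))
  p <- NA_real_
  if (n <= 10L) {
    Sdist <- rowSums(sweep(allPermutations(n), 2L, seq_len(n))^2)
    pLess <- mean(Sdist <= S); pGreater <- mean(Sdist >= S)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(pLess, pGreater)),
      greater = pLess, less = pGreater)
  }
  list(rho = rho, p = p)
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat("Spearman correlation: S(", x$n - 2, ") = ", x$S,
      ", rho = ", signif(x$rho, 3), ", p = ", signif(x$p, 3),
      " (", x$method, ", ", x$alternative, ")\n", sep = "")
  if (!anyNA(x$ci))
    cat("  bootstrap CI [", signif(x$ci[1], 3), ", ", signif(x$ci[2], 3),
        "] (", x$nBoot, " replicates)\n", sep = "")
  invisible(x)
}
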