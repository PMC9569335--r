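# Shared fixture builders; everything is generated in code at test time.

library(GenomicRanges)

# A GenotypePanel from an explicit genotype matrix (variants in columns),
# with variants placed 1 kb apart on chr1.
makePanel <- function(geno, spacing = 1000L) {
  m <- ncol(geno)
  ids <- sprintf("var%06d", seq_len(m))
  colnames(geno) <- ids
  storage.mode(geno) <- "integer"
  f <- colMeans(geno) / 2
  variants <- GRanges("chr1", IRanges(seq_len(m) * spacing, width = 1L),
                      variant = ids, maf = pmin(f, 1 - f))
  new("GenotypePanel", genotypes = geno, variants = variants,
      blockSize = 0L, rho = NA_real_)
}

# Random labelled segmentation on a toy genome of `genomeBp` bases.
randomSegmentation <- function(nSegments, genomeBp, seed) {
  set.seed(seed)
  starts <- sort(sample.int(genomeBp - 50L, nSegments))
  ends <- pmin(starts + sample(10:200, nSegments, replace = TRUE), genomeBp)
  labels <- sample(c(epienrich::activeStateLabels(), "1_Quies", "5_Tx"),
                   nSegments, replace = TRUE)
  GRanges("chr1", IRanges(starts, ends), state = labels)
}

# Per-base-pair coverage oracle: which of bases 1..genomeBp are covered.
perBaseCover <- function(gr, genomeBp) {
  cov <- logical(genomeBp)
  for (i in seq_along(gr))
    cov[seq.int(max(1L, start(gr)[i]), min(genomeBp, end(gr)[i]))] <- TRUE
  cov
}

# Brute-force double-loop partitioned LD scores (oracle).
bruteLdScores <- function(panel, memberships, windowBp) {
  g <- epienrich::genotypes(panel)
  pos <- start(epienrich::variantRanges(panel))
  m <- ncol(g)
  out <- matrix(0, m, length(memberships),
                dimnames = list(colnames(g), names(memberships)))
  for (j in seq_len(m)) for (k in seq_len(m)) {
    if (abs(pos[k] - pos[j]) > windowBp) next
    r2 <- suppressWarnings(cor(g[, j], g[, k])^2)
    for (a in seq_along(memberships))
      if (memberships[[a]][k] > 0) out[j, a] <- out[j, a] + r2
  }
  out
}

# Hand-coded BH step-up rule (oracle, independent of stats::p.adjust).
bhStepUp <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# A tiny processed peak matrix with controllable signal.
makePeakMatrix <- function(signal, starts = NULL, width = 100L, ...) {
  n <- nrow(signal)
  if (is.null(starts)) starts <- seq_len(n) * 1000L
  peaks <- GRanges("chr1", IRanges(starts, width = width))
  epienrich::specificityScores(signal, peaks = peaks, ...)
}
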