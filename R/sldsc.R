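#' @include AllGenerics.R
NULL

# Align a summary-stat table and an LD-score table on shared variants,
# preserving genome order.
alignStatsScores <- function(stats, ldscores) {
  checkSumstats(stats, require = c("SNP", "CHISQ", "N"))
  ids <- variantIds(ldscores)
  common <- intersect(stats$SNP, ids)
  if (!length(common)) stop("no shared variants between tables")
  ord <- ids[ids %in% common]
  list(stats = stats[match(ord, stats$SNP), , drop = FALSE],
       scores = ldScores(ldscores)[match(ord, ids), , drop = FALSE])
}

# Delete-one-block jackknife over contiguous blocks, using per-block
# normal-equation contributions.  Returns theta-hat, per-block estimates
# and jackknife SEs.
blockJackknifeLS <- function(X, y, w, nBlocks) {
  m <- nrow(X); p <- ncol(X)
  blocks <- split(seq_len(m), cut(seq_len(m), nBlocks, labels = FALSE))
  Xw <- X * w
  Atot <- crossprod(Xw, X)
  ctot <- crossprod(Xw, y)
  theta <- solve(Atot, ctot)
  jk <- matrix(NA_real_, nBlocks, p, dimnames = list(NULL, colnames(X)))
  for (b in seq_len(nBlocks)) {
    ib <- blocks[[b]]
    Ab <- crossprod(Xw[ib, , drop = FALSE], X[ib, , drop = FALSE])
    cb <- crossprod(Xw[ib, , drop = FALSE], y[ib])
    jk[b, ] <- solve(Atot - Ab, ctot - cb)
  }
  se <- sqrt((nBlocks - 1) / nBlocks *
             colSums(sweep(jk, 2L, colMeans(jk))^2))
  list(theta = as.numeric(theta), jackknife = jk, se = se)
}

#' Stratified LD-score regression
#'
#' Estimates per-annotation coefficients tau_C of the partitioned
#' heritability model by regressing per-variant GWAS chi-square statistics
#' on `N * l(j, C)` with a free intercept.  Standard errors come from a
#' delete-one-block jackknife over contiguous variant blocks; the reported
#' p-values are one-sided tests that tau_C > 0, Benjamini-Hochberg adjusted
#' across the model annotations.
#'
#' By default a single heteroskedasticity reweighting pass is applied:
#' after an initial OLS fit, weights `1 / (2 * (1 + N * tauBar *
#' lTotal_j)^2)` (the inverse of the model variance of a scaled 1-df
#' chi-square) are formed from a crude aggregate coefficient tauBar and the
#' model is refit once.  Weighting affects efficiency only; both modes are
#' consistent for the planted coefficients.
#'
#' @param stats summary-statistic data.frame (needs `SNP`, `CHISQ`, `N`).
#' @param ldscores a [PartitionedLdScoreTable-class].
#' @param modelAnnotations character vector of annotation columns to put in
#'   the model (default: all columns of `ldscores`).
#' @param nBlocks number of jackknife blocks (default 200); reduced with a
#'   warning when fewer than `2 * nBlocks` variants are available.
#' @param weights `"ldsc"` (one reweighting pass, default) or `"none"`
#'   (plain OLS).
#' @param totalColumn column name holding l(j, all-variants) for the weight
#'   formula; when absent, the row sum over model columns is used.
#' @return A [RegressionResult-class].
#' @export
fitSldsc <- function(stats, ldscores, modelAnnotations = NULL,
                     nBlocks = 200L, weights = c("ldsc", "none"),
                     totalColumn = "total") {
  weights <- match.arg(weights)
  if (is.null(modelAnnotations)) modelAnnotations <- colnames(ldScores(ldscores))
  al <- alignStatsScores(stats, ldscores)
  miss <- setdiff(modelAnnotations, colnames(al$scores))
  if (length(miss))
    stop("no LD-score column for annotation(s): ", paste(miss, collapse = ", "))
  L <- al$scores[, modelAnnotations, drop = FALSE]
  y <- al$stats$CHISQ
  N <- al$stats$N
  m <- length(y)
  X <- cbind(intercept = 1, L * N)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("rank-deficient model: collinear LD-score column(s): ",
         paste(setdiff(bad, "intercept"), collapse = ", "))
  }
  if (m < 2L * nBlocks) {
    nBlocks <- max(2L, floor(m / 2))
    warning("fewer variants than 2 * nBlocks; reducing jackknife blocks to ",
            nBlocks)
  }
  w <- rep(1, m)
  if (weights == "ldsc") {
    lTotal <- if (totalColumn %in% colnames(al$scores))
      al$scores[, totalColumn] else rowSums(L)
    ols <- solve(crossprod(X), crossprod(X, y))
    tauBar <- max(0, (mean(y) - ols[1]) / (mean(N) * mean(lTotal)))
    w <- 1 / (2 * (1 + N * tauBar * lTotal)^2)
  }
  fit <- blockJackknifeLS(X, y, w, nBlocks)
  tau <- fit$theta[-1] / 1   # coefficients of N*l are tau in per-SNP units
  se <- fit$se[-1]
  z <- tau / se
  p <- pnorm(z, lower.tail = FALSE)
  cf <- data.frame(annotation = modelAnnotations, tau = tau, se = se,
                   z = z, p = p,
                   p_adjusted = p.adjust(p, method = "BH"),
                   stringsAsFactors = FALSE)
  new("RegressionResult", coefficients = cf, intercept = fit$theta[1],
      interceptSE = fit$se[1], jackknife = fit$jackknife,
      nVariants = as.integer(m), nBlocks = as.integer(nBlocks),
      target = NA_character_, weighted = weights == "ldsc")
}

#' Conditional stratified LD-score regression
#'
#' Fits the same engine as [fitSldsc()] with the union of a target
#' annotation and a set of conditioning annotations as model terms, so the
#' target coefficient is estimated conditional on (e.g.) potentially
#' confounding tissues whose regulatory elements overlap the target's.
#' With an empty conditioning set this reduces exactly to [fitSldsc()].
#'
#' @param stats,ldscores,nBlocks,weights as in [fitSldsc()].
#' @param targetAnnotation single annotation name of interest.
#' @param conditioningAnnotations character vector of annotations to add
#'   (must not contain the target).
#' @return A [RegressionResult-class] with the `target` slot set.
#' @export
fitConditional <- function(stats, ldscores, targetAnnotation,
                           conditioningAnnotations = character(),
                           nBlocks = 200L, weights = c("ldsc", "none")) {
  stopifnot(length(targetAnnotation) == 1L)
  if (targetAnnotation %in% conditioningAnnotations)
    stop("target annotation must not be in the conditioning set")
  res <- fitSldsc(stats, ldscores,
                  modelAnnotations = c(targetAnnotation,
                                       conditioningAnnotations),
                  nBlocks = nBlocks, weights = weights)
  res@target <- targetAnnotation
  validObject(res)
  res
}

#' One-sided two-sample Z-test for a coefficient difference
#'
#' Compares one annotation's coefficient between two models (typically the
#' original and a conditioned fit):
#' `Z = (beta1 - beta2) / sqrt(SE1^2 + SE2^2)`, one-sided
#' `p = 1 - Phi(Z)`.
#'
#' @param result1,result2 [RegressionResult-class] objects containing
#'   `annotation`.
#' @param annotation annotation name to compare.
#' @return Named numeric vector `c(z, p)`.
#' @export
coefficientDifferenceTest <- function(result1, result2, annotation) {
  grab <- function(res) {
    cf <- coefficientTable(res)
    i <- match(annotation, cf$annotation)
    if (is.na(i)) stop("annotation '", annotation, "' not in model")
    cf[i, c("tau", "se")]
  }
  a <- grab(result1); b <- grab(result2)
  z <- (a$tau - b$tau) / sqrt(a$se^2 + b$se^2)
  c(z = z, p = pnorm(z, lower.tail = FALSE))
}

#' Total SNP heritability and its Z-score
#'
#' For binary annotations, total h2 = sum_C tau_C * |C| where |C| is the
#' number of model variants in C; the SE reuses the regression's
#' delete-one-block jackknife estimates, and the heritability Z-score is
#' estimate / SE (a standard power proxy for a GWAS).
#'
#' @param result a [RegressionResult-class].
#' @param annotationSizes named numeric vector, variants per model
#'   annotation.
#' @return Named numeric vector `c(h2, se, z)`.
#' @export
heritabilitySummary <- function(result, annotationSizes) {
  cf <- coefficientTable(result)
  miss <- setdiff(cf$annotation, names(annotationSizes))
  if (length(miss))
    stop("missing annotation size(s): ", paste(miss, collapse = ", "))
  sizes <- annotationSizes[cf$annotation]
  h2 <- sum(cf$tau * sizes)
  jk <- result@jackknife[, -1, drop = FALSE] %*% sizes
  B <- nrow(result@jackknife)
  se <- sqrt((B - 1) / B * sum((jk - mean(jk))^2))
  c(h2 = h2, se = se, z = if (se > 0) h2 / se else NA_real_)
}
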