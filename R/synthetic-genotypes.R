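#' @include config.R
NULL

#' Simulate an LD-block-structured genotype panel
#'
#' Generates a reference panel of allele counts with a simple, controllable
#' LD structure: within fixed-size blocks the latent Gaussian follows an
#' AR-1 process with correlation `rhoLD`, blocks are mutually independent,
#' and two independent latent "haplotype" draws are thresholded at the
#' variant's target minor allele frequency so genotypes are in
#' Hardy-Weinberg proportions.  Variants are placed at regular spacing on a
#' single synthetic chromosome `chr1`.
#'
#' @param config a [simulationConfig()] object.
#' @return A [GenotypePanel-class] object; deterministic given
#'   `config$seed`.
#' @examples
#' panel <- simulateGenotypePanel(simulationConfig(seed = 7,
#'   nIndividuals = 200, nVariants = 100, blockSize = 10))
#' dim(genotypes(panel))
#' @export
simulateGenotypePanel <- function(config) {
  validateSimulationConfig(config)
  m <- config$nVariants; n <- config$nIndividuals
  b <- config$blockSize; rho <- config$rhoLD
  withSeed(stageSeed(config$seed, "genotypes"), {
    block <- rep(seq_len(ceiling(m / b)), each = b, length.out = m)
    # MAF is drawn per LD block: variants in strong LD necessarily have
    # near-identical allele frequencies, and per-variant thresholds would
    # otherwise attenuate the within-block r^2 far below rhoLD^2
    maf <- runif(max(block), config$mafRange[1], config$mafRange[2])[block]
    thr <- qnorm(1 - maf)
    geno <- matrix(0L, n, m)
    for (hap in 1:2) {
      z <- matrix(rnorm(n * m), n, m)
      if (rho > 0) {
        for (j in 2:m) {
          if (block[j] == block[j - 1L])
            z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * z[, j]
        }
      }
      geno <- geno + (sweep(z, 2L, thr, ">") * 1L)
    }
    # guarantee polymorphism (relevant only for tiny panels / extreme MAF)
    mono <- which(colMeans(geno) %in% c(0, 2))
    for (j in mono) {
      repeat {
        g <- (rnorm(n) > thr[j]) + (rnorm(n) > thr[j])
        if (length(unique(g)) > 1L) { geno[, j] <- g; break }
      }
    }
    ids <- sprintf("var%06d", seq_len(m))
    colnames(geno) <- ids
    variants <- GRanges("chr1",
      IRanges(start = as.integer(seq_len(m)) * config$variantSpacing,
              width = 1L),
      variant = ids, maf = maf, block = block)
    new("GenotypePanel", genotypes = geno, variants = variants,
        blockSize = b, rho = rho)
  })
}

#' Simulate a chromatin-state segmentation
#'
#' Tiles the synthetic genome with contiguous segments carrying IDEAS-style
#' state labels.  Quiescent states dominate, with active
#' promoter/enhancer states (`10_TssA`, `8_TssAFlnk`, `14_TssWk`, `4_Enh`,
#' `6_EnhG`, `17_EnhGA`) interspersed, so downstream annotation building
#' has realistic sparse coverage.
#'
#' @param config a [simulationConfig()] object.
#' @param segmentBp mean segment length in bp (segments are
#'   exponential-length, minimum 200 bp).
#' @param activeWeight total probability mass given to the six active
#'   states (split equally); the remainder is `1_Quies`/`5_Tx` background.
#' @return A `GRanges` with a `state` metadata column covering
#'   `[1, genome length]` without gaps.
#' @export
simulateSegmentation <- function(config, segmentBp = 5000, activeWeight = 0.25) {
  validateSimulationConfig(config)
  L <- genomeLength(config)
  withSeed(stageSeed(config$seed, "segmentation"), {
    nSeg <- ceiling(L / segmentBp) + 50L
    lens <- pmax(200, round(rexp(nSeg, 1 / segmentBp)))
    ends <- cumsum(lens)
    keep <- ends - lens + 1 <= L
    lens <- lens[keep]; ends <- pmin(ends[keep], L)
    starts <- ends - lens + 1
    starts[1] <- 1
    ends[length(ends)] <- L
    act <- c("10_TssA", "8_TssAFlnk", "14_TssWk", "4_Enh", "6_EnhG", "17_EnhGA")
    bg <- c("1_Quies", "5_Tx")
    states <- sample(c(act, bg), length(lens), replace = TRUE,
                     prob = c(rep(activeWeight / 6, 6),
                              rep((1 - activeWeight) / 2, 2)))
    GRanges("chr1", IRanges(starts, ends), state = states)
  })
}

#' Simulate GWAS summary statistics under the partitioned-heritability model
#'
#' Two modes:
#' \describe{
#'   \item{analytic}{chi-square statistics are drawn directly from the
#'     stratified LD-score model: `chisq_j = (1 + N * sum_C tau_C *
#'     l(j, C)) * X` with `X` a central 1-df chi-square draw, using LD
#'     scores computed from `panel`.  This validates the regression engine
#'     against its own model assumption.}
#'   \item{phenotype}{per-variant effects `beta_j ~ Normal(0, sum_C tau_C
#'     a_jC)` on standardized genotypes, a phenotype is built on the
#'     panel's individuals with environmental noise scaling total variance
#'     to 1, and per-variant marginal regressions give the chi-squares
#'     (effective N is the panel size).  This validates the engine against
#'     the data-generating process.}
#' }
#'
#' @param panel a [GenotypePanel-class].
#' @param annotations named list of [AnnotationSet-class] objects covering
#'   a subset of panel variants; names must match `names(config$plantedTau)`.
#' @param config a [simulationConfig()]; `config$plantedTau` carries the
#'   true per-SNP heritability coefficients to plant.
#' @param mode `"analytic"` or `"phenotype"`.
#' @param ldscores optional precomputed [PartitionedLdScoreTable-class] for
#'   analytic mode (computed from `panel` if missing).
#' @param windowBp LD-score window for analytic mode when `ldscores` is
#'   not supplied.
#' @return A summary-statistic `data.frame` with columns
#'   `SNP, CHR, BP, A1, A2, BETA, SE, P, CHISQ, N, FRQ` and attributes
#'   `trueTau`, `mode`, `seed`.
#' @export
simulateSummaryStats <- function(panel, annotations, config,
                                 mode = c("analytic", "phenotype"),
                                 ldscores = NULL, windowBp = 100000L) {
  mode <- match.arg(mode)
  validateSimulationConfig(config)
  tau <- config$plantedTau
  if (!all(names(tau) %in% names(annotations)))
    stop("plantedTau names must match annotation names")
  geno <- genotypes(panel)
  m <- ncol(geno)
  A <- vapply(names(tau),
              function(a) annotateVariants(panel, annotations[[a]]),
              numeric(m))
  h2 <- sum(colSums(A) * tau)
  if (h2 > 1)
    stop("invalid configuration: planted tau implies total heritability ",
         signif(h2, 3), " > 1")
  withSeed(stageSeed(config$seed, paste0("sumstats-", mode)), {
    if (mode == "analytic") {
      if (is.null(ldscores))
        ldscores <- partitionedLdScores(panel, annotations[names(tau)],
                                        windowBp = windowBp)
      L <- ldScores(ldscores)[, names(tau), drop = FALSE]
      N <- config$gwasN
      scale <- 1 + N * as.numeric(L %*% tau)
      chisq <- scale * rchisq(m, df = 1L)
      beta <- sqrt(chisq / N) * sample(c(-1, 1), m, replace = TRUE)
      se <- rep(1 / sqrt(N), m)
    } else {
      n <- nrow(geno)
      N <- n
      sds <- apply(geno, 2L, sd)
      Xs <- scale(geno, center = TRUE, scale = sds)
      perVar <- as.numeric(A %*% tau)
      betaTrue <- rnorm(m, 0, sqrt(perVar))
      g <- as.numeric(Xs %*% betaTrue)
      envVar <- max(1 - h2, 1e-6)
      y <- g + rnorm(n, 0, sqrt(envVar))
      ys <- (y - mean(y)) / sd(y)
      r <- as.numeric(crossprod(Xs, ys)) / (n - 1)
      chisq <- (n - 2) * r^2 / pmax(1 - r^2, 1e-12)
      beta <- r
      se <- abs(r) / sqrt(pmax(chisq, 1e-12))
      se[chisq < 1e-12] <- 1 / sqrt(n)
    }
    vr <- variantRanges(panel)
    stats <- data.frame(
      SNP = variantIds(panel),
      CHR = as.character(seqnames(vr)),
      BP = start(vr),
      A1 = "A", A2 = "G",
      BETA = beta, SE = se,
      P = pchisq(chisq, df = 1L, lower.tail = FALSE),
      CHISQ = chisq, N = N,
      FRQ = colMeans(geno) / 2,
      stringsAsFactors = FALSE)
    attr(stats, "trueTau") <- tau
    attr(stats, "mode") <- mode
    attr(stats, "seed") <- config$seed
    if (mode == "phenotype") attr(stats, "h2Genetic") <- var(g)
    stats
  })
}
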