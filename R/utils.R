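#' @include AllClasses.R
NULL

#' Derive a per-stage seed from a master seed
#'
#' Hierarchical seeding: one master seed plus a stage label give a
#' reproducible, stage-specific RNG seed (always below 2^31 - 1), so each
#' pipeline stage and each Monte-Carlo replicate stream is independently
#' reproducible.
#'
#' @param seed master integer seed.
#' @param stage character label of the stage or stream.
#' @return An integer seed.
#' @examples
#' stageSeed(1, "genotypes")
#' @export
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Required columns of a summary-statistic table (tab-separated at I/O).
sumstatColumns <- function()
  c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "CHISQ", "N", "FRQ")

checkSumstats <- function(stats, require = c("SNP", "CHR", "BP", "P")) {
  stopifnot(is.data.frame(stats))
  miss <- setdiff(require, names(stats))
  if (length(miss))
    stop("summary statistics lack required column(s): ",
         paste(miss, collapse = ", "))
  invisible(stats)
}

# GRanges of width-1 variant positions from a summary-stat table.
sumstatRanges <- function(stats) {
  checkSumstats(stats)
  GRanges(paste0(ifelse(grepl("^chr", stats$CHR), "", "chr"), stats$CHR),
          IRanges(stats$BP, width = 1L), variant = stats$SNP)
}

#' MHC region constants
#'
#' The extended major histocompatibility complex locus on chromosome 6 is
#' conventionally excluded from enrichment analyses because of its extreme
#' LD.  Two builds are provided because different pipeline stages
#' conventionally run on different builds: heritability partitioning uses
#' the GRCh37 extended region chr6:25-34 Mb, while lead-locus clumping uses
#' the GRCh38 region chr6:28,510,120-33,480,577.
#'
#' @param build `"GRCh37"` or `"GRCh38"`.
#' @return A width-recorded [GenomicRanges::GRanges] of length 1 with the
#'   build stored in `mcols()$build`.
#' @examples
#' mhcRegion("GRCh38")
#' @export
mhcRegion <- function(build = c("GRCh37", "GRCh38")) {
  build <- match.arg(build)
  r <- switch(build,
    GRCh37 = GRanges("chr6", IRanges(25000000L, 34000000L)),
    GRCh38 = GRanges("chr6", IRanges(28510120L, 33480577L)))
  mcols(r)$build <- build
  r
}

# Internal: coerce "chr"-less chromosome labels.
normChr <- function(x) ifelse(grepl("^chr", x), x, paste0("chr", x))
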