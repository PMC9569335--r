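#' @include AllGenerics.R
NULL

#' Read and write the package's plain-text formats
#'
#' All tables are tab-separated with a header; annotations and peaks use
#' BED (0-based, half-open) through \pkg{rtracklayer}, converted once at
#' the boundary to the internal 1-based `GRanges` convention; gene sets
#' use GMT.
#'
#' @param stats,panel,ldscores,annotation,peaks object to write.
#' @param path file path.
#' @param name annotation name (on read).
#' @return Readers return the corresponding object; writers return the
#'   path invisibly.
#' @name epienrich-io
NULL

#' @rdname epienrich-io
#' @export
writeSummaryStats <- function(stats, path) {
  checkSumstats(stats)
  fwrite(as.data.table(stats[, intersect(sumstatColumns(), names(stats))]),
         path, sep = "\t")
  invisible(path)
}

#' @rdname epienrich-io
#' @export
readSummaryStats <- function(path) {
  as.data.frame(fread(path, sep = "\t"))
}

#' @rdname epienrich-io
#' @export
writeGenotypePanel <- function(panel, path) {
  vr <- variantRanges(panel)
  map <- data.frame(variant = variantIds(panel),
                    chr = as.character(seqnames(vr)), pos = start(vr))
  fwrite(as.data.table(map), paste0(path, ".map.tsv"), sep = "\t")
  fwrite(as.data.table(genotypes(panel)), paste0(path, ".geno.tsv"),
         sep = "\t")
  invisible(path)
}

#' @rdname epienrich-io
#' @export
readGenotypePanel <- function(path) {
  map <- as.data.frame(fread(paste0(path, ".map.tsv"), sep = "\t"))
  g <- as.matrix(fread(paste0(path, ".geno.tsv"), sep = "\t"))
  storage.mode(g) <- "integer"
  colnames(g) <- map$variant
  f <- colMeans(g) / 2
  variants <- GRanges(map$chr, IRanges(map$pos, width = 1L),
                      variant = map$variant, maf = pmin(f, 1 - f))
  new("GenotypePanel", genotypes = g, variants = variants,
      blockSize = 0L, rho = NA_real_)
}

#' @rdname epienrich-io
#' @export
writeLdScores <- function(ldscores, path) {
  tab <- data.frame(variant = variantIds(ldscores),
                    ldScores(ldscores), check.names = FALSE)
  fwrite(as.data.table(tab), path, sep = "\t")
  invisible(path)
}

#' @rdname epienrich-io
#' @export
readLdScores <- function(path, variants) {
  tab <- as.data.frame(fread(path, sep = "\t"))
  sc <- as.matrix(tab[, -1, drop = FALSE])
  rownames(sc) <- tab$variant
  stopifnot(identical(tab$variant, as.character(mcols(variants)$variant)))
  new("PartitionedLdScoreTable", scores = sc, variants = variants,
      window = NA_integer_, panelId = "file")
}

#' @rdname epienrich-io
#' @export
writeAnnotationBed <- function(annotation, path) {
  r <- if (is(annotation, "AnnotationSet")) annotationRanges(annotation)
       else annotation
  rtracklayer::export(r, path, format = "BED")
  invisible(path)
}

#' @rdname epienrich-io
#' @export
readAnnotationBed <- function(path, name = "annotation") {
  annotationSet(name, rtracklayer::import(path, format = "BED"))
}

#' @rdname epienrich-io
#' @export
readSegmentationBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(mcols(gr)$name))
    stop("segmentation BED must carry the state label in column 4")
  mcols(gr)$state <- mcols(gr)$name
  gr
}

#' @rdname epienrich-io
#' @export
writePeakMatrix <- function(peaks, path) {
  rtracklayer::export(granges(rowRanges(peaks)), paste0(path, ".bed"),
                      format = "BED")
  tab <- data.frame(peak = rownames(assay(peaks, "signal")),
                    assay(peaks, "signal"), check.names = FALSE)
  fwrite(as.data.table(tab), paste0(path, ".signal.tsv"), sep = "\t")
  invisible(path)
}

#' Read a gene model from TSV
#'
#' Expects columns `gene_id, chr, start, end, strand` (1-based inclusive
#' coordinates); the TSS is derived from the strand.
#'
#' @param path file path.
#' @return A `GRanges` with `gene_id` and `tss` metadata.
#' @export
readGeneModel <- function(path) {
  tab <- as.data.frame(fread(path, sep = "\t"))
  need <- c("gene_id", "chr", "start", "end", "strand")
  stopifnot(all(need %in% names(tab)))
  g <- GRanges(tab$chr, IRanges(tab$start, tab$end), strand = tab$strand,
               gene_id = tab$gene_id)
  mcols(g)$tss <- ifelse(tab$strand == "-", tab$end, tab$start)
  g
}

#' @rdname readGeneModel
#' @param genes gene model `GRanges`.
#' @export
writeGeneModel <- function(genes, path) {
  tab <- data.frame(gene_id = mcols(genes)$gene_id,
                    chr = as.character(seqnames(genes)),
                    start = start(genes), end = end(genes),
                    strand = as.character(strand(genes)))
  fwrite(as.data.table(tab), path, sep = "\t")
  invisible(path)
}

#' Read / write GMT gene sets
#'
#' Reading delegates to [fgsea::gmtPathways()]; writing emits the standard
#' `name <tab> description <tab> gene...` lines.
#'
#' @param path file path.
#' @param sets named list of character vectors.
#' @return `readGmt()`: named list of character vectors.
#' @export
readGmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE))
    stop("reading GMT requires the 'fgsea' package")
  fgsea::gmtPathways(path)
}

#' @rdname readGmt
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(s)
    paste(c(s, "na", sets[[s]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
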