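#' @include AllGenerics.R utils.R
NULL

#' Chromatin-state groups defining regulatory element classes
#'
#' IDEAS-style segmentation labels grouped into the active regulatory
#' classes used throughout the package: the global "active" annotation is
#' the union of active transcription start sites (`10_TssA`), TSS-flanking
#' (`8_TssAFlnk`), weak TSS (`14_TssWk`), enhancers (`4_Enh`), genic
#' enhancers (`6_EnhG`) and transcribed genic enhancers (`17_EnhGA`);
#' `classStateGroups()` splits the same six labels into promoter, enhancer
#' and genic-enhancer classes.
#'
#' @return `activeStateLabels()`: a character vector of six labels.
#'   `classStateGroups()`: a named list of three character vectors.
#' @export
activeStateLabels <- function()
  c("10_TssA", "8_TssAFlnk", "14_TssWk", "4_Enh", "6_EnhG", "17_EnhGA")

#' @rdname activeStateLabels
#' @export
classStateGroups <- function()
  list(promoter = c("10_TssA", "8_TssAFlnk", "14_TssWk"),
       enhancer = "4_Enh",
       genic_enhancer = c("6_EnhG", "17_EnhGA"))

#' Construct an AnnotationSet
#'
#' Builds a binary genomic annotation from arbitrary intervals, merging
#' overlapping and adjacent intervals so the result is maximally merged.
#'
#' @param name annotation name.
#' @param ranges a `GRanges` (any state; will be reduced).
#' @param provenance optional character vector, e.g. merged state labels.
#' @return An [AnnotationSet-class].
#' @export
annotationSet <- function(name, ranges, provenance = character()) {
  new("AnnotationSet", name = name,
      ranges = sort(reduce(ranges, min.gapwidth = 1L)),
      provenance = provenance)
}

#' Merge chromatin-state segments into a binary "active" annotation
#'
#' Takes a genome segmentation (intervals labelled with chromatin states)
#' and returns the maximally merged union of all segments whose label
#' belongs to `stateGroup`.  Used to build the single binary annotation of
#' active regulatory elements per tissue that the heritability-partitioning
#' engine consumes.
#'
#' @param segmentation a `GRanges` with a `state` metadata column.
#' @param stateGroup character vector of state labels to merge; defaults to
#'   the six active promoter/enhancer states ([activeStateLabels()]).
#' @param name name for the resulting annotation.
#' @return An [AnnotationSet-class]; its covered length equals the length
#'   of the set-theoretic union of the selected segments.
#' @examples
#' seg <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1, 101, 201), c(100, 200, 300)),
#'   state = c("10_TssA", "1_Quies", "4_Enh"))
#' mergeActiveStates(seg)
#' @export
mergeActiveStates <- function(segmentation, stateGroup = activeStateLabels(),
                              name = "active") {
  if (is.null(mcols(segmentation)$state))
    stop("segmentation must carry a 'state' metadata column")
  present <- unique(as.character(mcols(segmentation)$state))
  unknown <- setdiff(stateGroup, present)
  if (length(unknown))
    warning("state label(s) not present in segmentation: ",
            paste(unknown, collapse = ", "))
  sel <- segmentation[mcols(segmentation)$state %in% stateGroup]
  annotationSet(name, granges(sel), provenance = stateGroup)
}

#' Split a segmentation into regulatory-element class annotations
#'
#' Builds the three fixed element-class annotations — promoters
#' (`10_TssA`, `8_TssAFlnk`, `14_TssWk`), enhancers (`4_Enh`) and genic
#' enhancers (`6_EnhG`, `17_EnhGA`).  Their base-level union equals the
#' global active annotation produced by [mergeActiveStates()].
#'
#' @param segmentation a `GRanges` with a `state` metadata column.
#' @return Named list of three [AnnotationSet-class] objects
#'   (`promoter`, `enhancer`, `genic_enhancer`).
#' @export
classAnnotations <- function(segmentation) {
  groups <- classStateGroups()
  out <- lapply(names(groups), function(cls)
    suppressWarnings(
      mergeActiveStates(segmentation, groups[[cls]], name = cls)))
  names(out) <- names(groups)
  out
}

#' Per-variant binary annotation membership
#'
#' Computes the indicator a_jC: 1 iff variant j's position lies inside one
#' of the annotation's intervals.  Variant positions are 1-based; interval
#' containment follows the package's internal 1-based closed convention
#' (equivalent to BED half-open at I/O).
#'
#' @param variants a [GenotypePanel-class], a `GRanges` of width-1 variant
#'   positions, or a summary-statistic data.frame with `CHR`/`BP` columns.
#' @param annotation an [AnnotationSet-class].
#' @return Numeric 0/1 vector, one entry per variant, with attribute
#'   `nMembers`.
#' @export
annotateVariants <- function(variants, annotation) {
  gr <- if (is(variants, "GenotypePanel")) variantRanges(variants)
        else if (is(variants, "GRanges")) variants
        else sumstatRanges(variants)
  stopifnot(is(annotation, "AnnotationSet"))
  ann <- annotationRanges(annotation)
  missingChr <- setdiff(unique(as.character(seqnames(gr))),
                        unique(as.character(seqnames(ann))))
  if (length(missingChr) && length(ann))
    message("annotateVariants: chromosome(s) absent from annotation '",
            annotationName(annotation), "': ",
            paste(missingChr, collapse = ", "), " (membership 0)")
  member <- as.numeric(suppressWarnings(overlapsAny(gr, ann)))
  attr(member, "nMembers") <- sum(member)
  member
}

#' Remove records intersecting a genomic region
#'
#' Drops every variant or interval that intersects `region` (one or more
#' shared base pairs), typically the MHC region ([mhcRegion()]).
#'
#' @param x a `GRanges`, [AnnotationSet-class], or summary-statistic
#'   data.frame with `CHR`/`BP`.
#' @param region a `GRanges` of regions to exclude.
#' @return The filtered object (same type), with attribute `nRemoved`
#'   (for `AnnotationSet`, recorded in `provenance`).
#' @export
excludeRegion <- function(x, region) {
  stopifnot(is(region, "GRanges"))
  if (is(x, "AnnotationSet")) {
    r <- annotationRanges(x)
    keep <- !suppressWarnings(overlapsAny(r, region, ignore.strand = TRUE))
    out <- new("AnnotationSet", name = annotationName(x), ranges = r[keep],
               provenance = c(x@provenance,
                              sprintf("excluded %d interval(s) in region",
                                      sum(!keep))))
    attr(out, "nRemoved") <- sum(!keep)
    return(out)
  }
  if (is(x, "GRanges")) {
    keep <- !suppressWarnings(overlapsAny(x, region, ignore.strand = TRUE))
    out <- x[keep]
  } else {
    gr <- sumstatRanges(x)
    keep <- !suppressWarnings(overlapsAny(gr, region, ignore.strand = TRUE))
    out <- x[keep, , drop = FALSE]
  }
  attr(out, "nRemoved") <- sum(!keep)
  out
}
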