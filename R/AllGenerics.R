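#' @include AllClasses.R
NULL

#' Accessors for epienrich classes
#'
#' Small accessor functions; user code should use these rather than `@`.
#'
#' @param x an epienrich S4 object.
#' @param ... unused.
#' @return The requested component; see the class documentation pages.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("annotationName", function(x) standardGeneric("annotationName"))
#' @rdname accessors
#' @export
setGeneric("annotationRanges", function(x) standardGeneric("annotationRanges"))
#' @rdname accessors
#' @export
setGeneric("coveredBases", function(x) standardGeneric("coveredBases"))
#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("variantRanges", function(x) standardGeneric("variantRanges"))
#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))
#' @rdname accessors
#' @export
setGeneric("ldScores", function(x) standardGeneric("ldScores"))
#' @rdname accessors
#' @export
setGeneric("ldWindow", function(x) standardGeneric("ldWindow"))
#' @rdname accessors
#' @export
setGeneric("specificityScore", function(x) standardGeneric("specificityScore"))
#' @rdname accessors
#' @export
setGeneric("specificityRank", function(x, normalized = TRUE)
  standardGeneric("specificityRank"))
#' @rdname accessors
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))
#' @rdname accessors
#' @export
setGeneric("coefficientTable", function(x) standardGeneric("coefficientTable"))
#' @rdname accessors
#' @export
setGeneric("modelIntercept", function(x) standardGeneric("modelIntercept"))
#' @rdname accessors
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))
#' @rdname accessors
#' @export
setGeneric("overlapTable", function(x) standardGeneric("overlapTable"))

#' @rdname accessors
#' @export
setMethod("annotationName", "AnnotationSet", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("annotationRanges", "AnnotationSet", function(x) x@ranges)
#' @rdname accessors
#' @export
setMethod("coveredBases", "AnnotationSet", function(x) sum(width(x@ranges)))
#' @rdname accessors
#' @export
setMethod("genotypes", "GenotypePanel", function(x) x@genotypes)
#' @rdname accessors
#' @export
setMethod("variantRanges", "GenotypePanel", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("variantIds", "GenotypePanel",
  function(x) as.character(mcols(x@variants)$variant))
#' @rdname accessors
#' @export
setMethod("variantRanges", "PartitionedLdScoreTable", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("variantIds", "PartitionedLdScoreTable",
  function(x) as.character(mcols(x@variants)$variant))
#' @rdname accessors
#' @export
setMethod("ldScores", "PartitionedLdScoreTable", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("ldWindow", "PartitionedLdScoreTable", function(x) x@window)
#' @rdname accessors
#' @export
setMethod("specificityScore", "PeakSpecificityMatrix",
  function(x) assay(x, "score"))
#' @rdname accessors
#' @export
setMethod("specificityRank", "PeakSpecificityMatrix",
  function(x, normalized = TRUE)
    assay(x, if (normalized) "normRank" else "rank"))
#' @rdname accessors
#' @export
setMethod("peakRanges", "PeakSpecificityMatrix", function(x) rowRanges(x))
#' @rdname accessors
#' @export
setMethod("coefficientTable", "RegressionResult", function(x) x@coefficients)
#' @rdname accessors
#' @export
setMethod("modelIntercept", "RegressionResult",
  function(x) c(estimate = x@intercept, se = x@interceptSE))
#' @rdname accessors
#' @export
setMethod("enrichmentTable", "CheersResult", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("overlapTable", "CheersResult", function(x) x@overlaps)

#' @export
setMethod("length", "AnnotationSet", function(x) length(x@ranges))

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet \"", object@name, "\": ", length(object@ranges),
      " intervals, ", sum(width(object@ranges)), " bp covered\n", sep = "")
  if (length(object@provenance))
    cat("  merged from:", paste(object@provenance, collapse = ", "), "\n")
})

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel: ", nrow(object@genotypes), " individuals x ",
      ncol(object@genotypes), " variants\n", sep = "")
  cat("  LD blocks of ", object@blockSize, " variants, AR-1 rho = ",
      object@rho, "\n", sep = "")
})

setMethod("show", "PartitionedLdScoreTable", function(object) {
  cat("PartitionedLdScoreTable: ", nrow(object@scores), " variants x ",
      ncol(object@scores), " annotations (window ", object@window,
      " bp, panel \"", object@panelId, "\")\n", sep = "")
  cat("  annotations:", paste(colnames(object@scores), collapse = ", "), "\n")
})

setMethod("show", "RegressionResult", function(object) {
  cat("RegressionResult (", if (object@weighted) "WLS" else "OLS", "): ",
      object@nVariants, " variants, ", object@nBlocks,
      " jackknife blocks\n", sep = "")
  cat("  intercept ", signif(object@intercept, 4), " (SE ",
      signif(object@interceptSE, 3), ")\n", sep = "")
  if (!is.na(object@target)) cat("  target annotation:", object@target, "\n")
  print(object@coefficients, digits = 4, row.names = FALSE)
})

setMethod("show", "CheersResult", function(object) {
  cat("CheersResult (", object@method, " null): ", object@nPeaksTotal,
      " peaks in universe, ", nrow(object@overlaps),
      " variant-peak overlaps\n", sep = "")
  print(object@table, digits = 4, row.names = FALSE)
})
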