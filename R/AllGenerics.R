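#' @rdname ObservationTable
#' @param x an object.
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname ObservationTable
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname ObservationTable
#' @export
setGeneric("sampleTotals", function(x) standardGeneric("sampleTotals"))

#' @rdname ObservationTable
#' @export
setGeneric("featureTotals", function(x) standardGeneric("featureTotals"))

setMethod("featureIds", "ObservationTable", function(x) rownames(x))
setMethod("sampleIds", "ObservationTable", function(x) colnames(x))
setMethod("sampleTotals", "ObservationTable",
          function(x) Matrix::colSums(counts(x)))
setMethod("featureTotals", "ObservationTable",
          function(x) Matrix::rowSums(counts(x)))

setMethod("featureIds", "ANY", function(x) rownames(x))
setMethod("sampleIds", "SampleMetadata", function(x) rownames(x))

#' @rdname ObservationTable
#' @param object an \code{ObservationTable}.
#' @importFrom BiocGenerics counts
#' @export counts
#' @exportMethod counts
setMethod("counts", "ObservationTable",
          function(object) SummarizedExperiment::assay(object, "counts"))

#' Validation issues recorded while loading sample metadata
#'
#' @param x a \linkS4class{SampleMetadata}.
#' @return data.frame with columns \code{sample_id}, \code{field},
#'   \code{problem} (zero rows when the file was clean).
#' @export
validationIssues <- function(x) {
  stopifnot(methods::is(x, "SampleMetadata"))
  x@issues
}
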