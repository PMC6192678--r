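#' @import methods
#' @importFrom stats quantile sd var optim pnorm pchisq p.adjust wilcox.test
#'   rmultinom rexp runif rbinom rnorm qnorm setNames
#' @importFrom utils read.delim write.table head combn packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom S4Vectors DFrame
#' @importFrom S4Vectors DataFrame
NULL

#' Sample-by-tag-sequence observation table
#'
#' An \code{ObservationTable} holds sparse non-negative integer counts of
#' tag sequences (amplicon sequence variants, rows) across samples
#' (columns). It extends
#' \linkS4class{SummarizedExperiment} with a single \code{counts} assay, so
#' all the usual subsetting and accessor machinery applies.
#'
#' Invariants enforced by the validity method: unique feature and sample
#' identifiers, and integral counts \eqn{\ge 0}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @aliases ObservationTable-class
#' @exportClass ObservationTable
setClass("ObservationTable", contains = "SummarizedExperiment")

setValidity("ObservationTable", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    return("feature and sample identifiers are required")
  if (anyDuplicated(rownames(m))) return("duplicate feature identifiers")
  if (anyDuplicated(colnames(m))) return("duplicate sample identifiers")
  v <- if (inherits(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(v) && any(v < 0)) return("negative counts")
  if (length(v) && any(v != round(v))) return("non-integer counts")
  TRUE
})

#' Construct an ObservationTable
#'
#' @param counts numeric matrix-like (dense or \pkg{Matrix} sparse),
#'   features as rows, samples as columns, non-negative integers.
#' @param featureIds,sampleIds identifiers; default taken from
#'   \code{dimnames(counts)}.
#' @return an \linkS4class{ObservationTable}.
#' @examples
#' ot <- ObservationTable(matrix(c(1, 0, 2, 3), 2, 2,
#'   dimnames = list(c("f1", "f2"), c("s1", "s2"))))
#' sampleTotals(ot)
#' @export
ObservationTable <- function(counts, featureIds = rownames(counts),
                             sampleIds = colnames(counts)) {
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(featureIds, sampleIds)
  obj <- methods::new("ObservationTable",
    SummarizedExperiment::SummarizedExperiment(assays = list(counts = m)))
  methods::validObject(obj)
  obj
}

#' Per-sample metadata with EMPO structure
#'
#' Extends \link[S4Vectors]{DataFrame} (rows = samples, row names = sample
#' identifiers) with an \code{issues} slot recording validation findings
#' (EMPO level-1/level-2 inconsistencies, out-of-range pH or latitude).
#' Offending samples are reported and retained, never silently dropped.
#'
#' Expected columns include \code{study_id}, \code{empo_1}, \code{empo_2},
#' \code{empo_3}, and optional \code{host_scientific_name},
#' \code{latitude_deg}, \code{ph}, \code{temperature_deg_c},
#' \code{salinity_psu}; extra columns are allowed.
#'
#' @slot issues data.frame with columns \code{sample_id}, \code{field},
#'   \code{problem}.
#' @aliases SampleMetadata-class
#' @exportClass SampleMetadata
setClass("SampleMetadata", contains = "DFrame",
         representation(issues = "data.frame"))

#' Presence-absence matrix prepared for nestedness analysis
#'
#' Logical taxa-by-samples matrix with all-zero rows and columns removed
#' (and recorded), as consumed by \code{\link{nodf}}.
#'
#' @slot presence logical matrix, taxa as rows.
#' @slot droppedRows,droppedCols identifiers removed because empty.
#' @aliases PresenceMatrix-class
#' @exportClass PresenceMatrix
setClass("PresenceMatrix",
         representation(presence = "matrix",
                        droppedRows = "character",
                        droppedCols = "character"))

setValidity("PresenceMatrix", function(object) {
  if (!is.logical(object@presence)) return("presence must be logical")
  TRUE
})

#' NODF nestedness test result
#'
#' @slot nodf named numeric: \code{rows}, \code{cols}, \code{overall}
#'   components on the [0, 1] scale.
#' @slot statistic which component was tested.
#' @slot nullModel null model used.
#' @slot nullMean,nullVariance null moments of the tested component.
#' @slot ses standardized effect size (observed - mean) / sd.
#' @slot pAnalytic two-sided Wald p value (NA unless analytic mode ran).
#' @slot pEmpirical one-sided empirical p value (NA unless empirical ran).
#' @slot nullSample numeric vector of null statistics (may be empty).
#' @slot momentsSource "analytic" or "empirical".
#' @aliases NodfResult-class
#' @exportClass NodfResult
setClass("NodfResult",
         representation(nodf = "numeric", statistic = "character",
                        nullModel = "character", nullMean = "numeric",
                        nullVariance = "numeric", ses = "numeric",
                        pAnalytic = "numeric", pEmpirical = "numeric",
                        nullSample = "numeric", momentsSource = "character"))

#' Richness upper-envelope fit
#'
#' Least-squares fit of \eqn{S_0 \exp(-|x-\mu|/b)} (Laplace) or
#' \eqn{S_0 \exp(-(x-\mu)^2/(2\sigma^2))} (Gaussian) to binned upper
#' percentiles of richness.
#'
#' @slot family "laplace" or "gaussian".
#' @slot mu mode, in covariate units.
#' @slot scale Laplace scale b, or Gaussian sigma (covariate units).
#' @slot amplitude fitted peak richness S0.
#' @slot sse residual sum of squares.
#' @slot nPoints number of fitted bins.
#' @aliases EnvelopeFit-class
#' @exportClass EnvelopeFit
setClass("EnvelopeFit",
         representation(family = "character", mu = "numeric",
                        scale = "numeric", amplitude = "numeric",
                        sse = "numeric", nPoints = "integer"))

setMethod("show", "ObservationTable", function(object) {
  cat(sprintf("ObservationTable: %d features x %d samples, %s total counts\n",
              nrow(object), ncol(object),
              format(sum(sampleTotals(object)), big.mark = ",")))
})

setMethod("show", "SampleMetadata", function(object) {
  cat(sprintf("SampleMetadata: %d samples, %d fields, %d validation issue(s)\n",
              nrow(object), ncol(object), nrow(object@issues)))
})

setMethod("show", "PresenceMatrix", function(object) {
  cat(sprintf("PresenceMatrix: %d taxa x %d samples (fill %.3f)\n",
              nrow(object@presence), ncol(object@presence),
              mean(object@presence)))
})

setMethod("show", "NodfResult", function(object) {
  cat(sprintf("NODF %s = %.4f (rows %.4f, cols %.4f) | null %s\n",
              object@statistic, object@nodf[object@statistic],
              object@nodf["rows"], object@nodf["cols"], object@nullModel))
  cat(sprintf("  null mean %.4f, sd %.4g (%s), SES %.2f, p_analytic %.3g, p_empirical %.3g\n",
              object@nullMean, sqrt(object@nullVariance),
              object@momentsSource, object@ses, object@pAnalytic,
              object@pEmpirical))
})

setMethod("show", "EnvelopeFit", function(object) {
  cat(sprintf("%s envelope: mu = %.3f, %s = %.3f, S0 = %.1f, sse = %.4g (%d bins)\n",
              object@family, object@mu,
              if (object@family == "laplace") "b" else "sigma",
              object@scale, object@amplitude, object@sse, object@nPoints))
})
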