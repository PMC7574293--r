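#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

.MODALITIES <- c("expression-linear", "expression-log2", "methylation-beta")

#' Container for a mixed-cell omics matrix
#'
#' A \code{MixedOmicsExperiment} is a
#' \linkS4class{SummarizedExperiment} carrying one feature-by-sample assay
#' (\code{"values"}) plus a modality tag that records the measurement scale:
#' linear-scale expression intensities, log2 expression, or methylation beta
#' values. Several operations are scale-sensitive (deconvolution requires the
#' linear / beta scale, differential expression the log2 scale), so the tag is
#' validated rather than assumed.
#'
#' @slot modality character(1), one of \code{"expression-linear"},
#'   \code{"expression-log2"}, \code{"methylation-beta"}.
#'
#' @seealso \code{\link{MixedOmicsExperiment}} (constructor),
#'   \code{\link{modality}}, \code{\link{omicsMatrix}}
#' @exportClass MixedOmicsExperiment
setClass("MixedOmicsExperiment",
  contains = "SummarizedExperiment",
  representation(modality = "character")
)

setValidity("MixedOmicsExperiment", function(object) {
  msg <- NULL
  if (length(object@modality) != 1L || !object@modality %in% .MODALITIES) {
    msg <- c(msg, sprintf(
      "modality must be one of: %s", paste(.MODALITIES, collapse = ", ")
    ))
  }
  if (length(assays(object)) < 1L) {
    msg <- c(msg, "an assay matrix is required")
  } else {
    m <- assay(object, 1L)
    if (!is.numeric(m)) msg <- c(msg, "assay must be numeric")
    if (identical(object@modality, "methylation-beta") && is.numeric(m)) {
      rng <- suppressWarnings(range(m, na.rm = TRUE))
      if (is.finite(rng[1L]) && (rng[1L] < 0 || rng[2L] > 1)) {
        msg <- c(msg, "methylation beta values must lie in [0, 1]")
      }
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a MixedOmicsExperiment
#'
#' @param values numeric matrix, features in rows, samples in columns. Row and
#'   column names are used as feature and sample identifiers.
#' @param modality measurement scale: \code{"expression-linear"},
#'   \code{"expression-log2"} or \code{"methylation-beta"}.
#' @param sampleData optional \code{data.frame}/\code{DataFrame} of per-sample
#'   metadata (group, RIN, preservation, ...), one row per column of
#'   \code{values}.
#' @param dynRange optional numeric(2) giving the dynamic range of the array
#'   (used as expression box bounds downstream); stored in \code{metadata()}.
#'
#' @return A \linkS4class{MixedOmicsExperiment}.
#' @examples
#' m <- matrix(runif(12), 4, 3,
#'   dimnames = list(paste0("cg", 1:4), paste0("S", 1:3)))
#' MixedOmicsExperiment(m, "methylation-beta")
#' @export
MixedOmicsExperiment <- function(values, modality, sampleData = NULL,
                                 dynRange = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("f%05d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  }
  cd <- if (is.null(sampleData)) {
    DataFrame(row.names = colnames(values))
  } else {
    DataFrame(sampleData, row.names = colnames(values))
  }
  se <- SummarizedExperiment(assays = list(values = values), colData = cd)
  obj <- new("MixedOmicsExperiment", se, modality = modality)
  if (!is.null(dynRange)) {
    stopifnot(length(dynRange) == 2L, dynRange[1L] < dynRange[2L])
    metadata(obj)$dynRange <- as.numeric(dynRange)
  }
  obj
}

#' @rdname MixedOmicsExperiment
#' @param x,object a \code{MixedOmicsExperiment}.
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname MixedOmicsExperiment
#' @export
setMethod("modality", "MixedOmicsExperiment", function(x) x@modality)

#' @rdname MixedOmicsExperiment
#' @export
setGeneric("omicsMatrix", function(x) standardGeneric("omicsMatrix"))

#' @rdname MixedOmicsExperiment
#' @export
setMethod("omicsMatrix", "MixedOmicsExperiment", function(x) assay(x, 1L))

#' @rdname MixedOmicsExperiment
#' @export
setMethod("show", "MixedOmicsExperiment", function(object) {
  cat(sprintf(
    "MixedOmicsExperiment [%s]: %d features x %d samples\n",
    object@modality, nrow(object), ncol(object)
  ))
  callNextMethod()
})

#' Group-wise deconvolution design matrix
#'
#' Samples-by-coefficients matrix of cell-type proportions (each row on the
#' unit simplex) for one sample group: one column per major cell type plus a
#' final "weighed intercept" column holding the summed proportions of all
#' minor (non-major, non-excluded) cell types.
#'
#' @slot design numeric matrix, samples x (majors + 1), entries in [0, 1],
#'   rows summing to 1.
#' @slot majorTypes character, ordered major cell-type labels.
#' @slot minorTypes character, labels pooled into the intercept column.
#' @slot excluded character, labels removed before renormalization.
#' @slot conditionNumber numeric(1), kappa of the design.
#'
#' @seealso \code{\link{buildDesign}}
#' @exportClass DeconvDesign
setClass("DeconvDesign", representation(
  design = "matrix",
  majorTypes = "character",
  minorTypes = "character",
  excluded = "character",
  conditionNumber = "numeric"
))

setValidity("DeconvDesign", function(object) {
  d <- object@design
  msg <- NULL
  if (any(d < -1e-9 | d > 1 + 1e-9)) {
    msg <- c(msg, "design entries must lie in [0, 1]")
  }
  if (any(abs(rowSums(d) - 1) > 1e-6)) {
    msg <- c(msg, "design rows must sum to 1 within 1e-6")
  }
  if (ncol(d) != length(object@majorTypes) + 1L) {
    msg <- c(msg, "design must have one column per major type plus intercept")
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname DeconvDesign-class
#' @param object a \code{DeconvDesign}.
#' @export
setMethod("show", "DeconvDesign", function(object) {
  cat(sprintf(
    "DeconvDesign: %d samples, majors [%s], intercept pools [%s], kappa = %.3g\n",
    nrow(object@design), paste(object@majorTypes, collapse = ", "),
    paste(object@minorTypes, collapse = ", "), object@conditionNumber
  ))
})

#' @rdname DeconvDesign-class
#' @param x a \code{DeconvDesign}.
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' @rdname DeconvDesign-class
#' @export
setMethod("designMatrix", "DeconvDesign", function(x) x@design)

#' @rdname DeconvDesign-class
#' @export
setGeneric("majorTypes", function(x) standardGeneric("majorTypes"))

#' @rdname DeconvDesign-class
#' @export
setMethod("majorTypes", "DeconvDesign", function(x) x@majorTypes)

#' Deconvolved cell-type profile estimates for one sample group
#'
#' Holds, per feature, the box-constrained least-squares estimates of the
#' cell-type-specific signal (one coefficient per major cell type plus the
#' pooled-minor "other" intercept), the matching regression standard errors,
#' the residual degrees of freedom (n - p, shared by all coefficients of a
#' feature), and solver diagnostics.
#'
#' @slot group character(1) sample-group label.
#' @slot modality measurement scale of the estimates.
#' @slot estimates numeric matrix, features x coefficients.
#' @slot se numeric matrix, same shape, regression standard errors
#'   (unconstrained-OLS formula; see \code{\link{deconvolveGroup}}).
#' @slot df numeric, residual degrees of freedom per feature.
#' @slot bounds numeric(2) box bounds the estimates satisfy.
#' @slot nActive integer, number of active box constraints per feature.
#' @slot objective numeric, residual sum of squares per feature.
#'
#' @seealso \code{\link{deconvolveGroup}}, \code{\link{welchFromEstimates}}
#' @exportClass CellProfileEstimate
setClass("CellProfileEstimate", representation(
  group = "character",
  modality = "character",
  estimates = "matrix",
  se = "matrix",
  df = "numeric",
  bounds = "numeric",
  nActive = "integer",
  objective = "numeric"
))

setValidity("CellProfileEstimate", function(object) {
  msg <- NULL
  est <- object@estimates
  if (!identical(dim(est), dim(object@se))) {
    msg <- c(msg, "estimates and se must have identical dimensions")
  }
  ok <- is.finite(est)
  tol <- 1e-8 * max(1, abs(object@bounds[2L]))
  if (any(est[ok] < object@bounds[1L] - tol | est[ok] > object@bounds[2L] + tol)) {
    msg <- c(msg, "estimates must lie within the declared bounds")
  }
  if (any(object@se[is.finite(object@se)] < 0)) msg <- c(msg, "SEs must be >= 0")
  if (any(object@df < 1)) msg <- c(msg, "residual df must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' @rdname CellProfileEstimate-class
#' @param x,object a \code{CellProfileEstimate}.
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))

#' @rdname CellProfileEstimate-class
#' @export
setMethod("estimates", "CellProfileEstimate", function(x) x@estimates)

#' @rdname CellProfileEstimate-class
#' @export
setGeneric("standardErrors", function(x) standardGeneric("standardErrors"))

#' @rdname CellProfileEstimate-class
#' @export
setMethod("standardErrors", "CellProfileEstimate", function(x) x@se)

#' @rdname CellProfileEstimate-class
#' @export
setGeneric("residualDf", function(x) standardGeneric("residualDf"))

#' @rdname CellProfileEstimate-class
#' @export
setMethod("residualDf", "CellProfileEstimate", function(x) x@df)

#' @rdname CellProfileEstimate-class
#' @export
setMethod("show", "CellProfileEstimate", function(object) {
  cat(sprintf(
    "CellProfileEstimate [%s, %s]: %d features x %d coefficients (%s)\n",
    object@group, object@modality, nrow(object@estimates),
    ncol(object@estimates), paste(colnames(object@estimates), collapse = ", ")
  ))
  cat(sprintf(
    "  bounds [%.4g, %.4g]; %d features with active box constraints\n",
    object@bounds[1L], object@bounds[2L], sum(object@nActive > 0L)
  ))
})
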