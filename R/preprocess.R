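#' Background-correct expression foreground signals ("minimum" method)
#'
#' Subtracts mean background from median foreground per feature and array.
#' Any corrected value that is zero or negative is replaced by half the
#' minimum positive corrected value on that array, so all outputs are
#' strictly positive (the "minimum" background-correction convention).
#'
#' @param foregroundMedian,backgroundMean nonnegative numeric matrices of
#'   identical shape (features x arrays).
#' @return \linkS4class{MixedOmicsExperiment} with modality
#'   \code{"expression-linear"}.
#' @examples
#' fg <- matrix(c(100, 30, 45), 3, 1, dimnames = list(1:3, "A"))
#' bg <- matrix(c(40, 40, 40), 3, 1, dimnames = list(1:3, "A"))
#' omicsMatrix(backgroundCorrect(fg, bg))  # 60, 2.5, 5
#' @export
backgroundCorrect <- function(foregroundMedian, backgroundMean) {
  if (!identical(dim(foregroundMedian), dim(backgroundMean))) {
    stop("foreground and background matrices must have the same shape")
  }
  if (any(foregroundMedian < 0) || any(backgroundMean < 0)) {
    stop("signals must be nonnegative")
  }
  corrected <- foregroundMedian - backgroundMean
  for (j in seq_len(ncol(corrected))) {
    pos <- corrected[, j] > 0
    if (!any(pos)) {
      stop(sprintf("array %d has no positive background-corrected value", j))
    }
    corrected[!pos, j] <- min(corrected[pos, j]) / 2
  }
  MixedOmicsExperiment(corrected, "expression-linear")
}

#' Quantile-normalize a matrix across samples
#'
#' Forces every column to the identical empirical distribution (the
#' cross-column means of the sorted values); ties receive the mean of the
#' tied rank values, making the result deterministic and order-independent.
#' The transform preserves within-column rank order and is idempotent.
#'
#' @param x numeric matrix or \linkS4class{MixedOmicsExperiment} (the
#'   modality tag is preserved). No missing values.
#' @return object of the same class as \code{x}, quantile-normalized.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(6, 4, 5)))
#' @export
quantileNormalize <- function(x) {
  m <- if (is(x, "MixedOmicsExperiment")) omicsMatrix(x) else as.matrix(x)
  if (anyNA(m)) stop("missing values must be handled before normalization")
  if (ncol(m) < 2L) {
    warning("single-column input returned unchanged")
    return(x)
  }
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(qn) <- dimnames(m)
  if (is(x, "MixedOmicsExperiment")) .replaceAssay(x, qn) else qn
}

#' Filter expression probes on Agilent-style flags
#'
#' Applies the probe-retention rules: control probes are removed; any probe
#' flagged non-uniform, saturated or population-outlier on any array is
#' removed; a probe is kept only if, in at least one sample group, at least
#' 50\% of its arrays are flagged both found and positive-and-significant.
#'
#' @param flags list with logical probe x array matrices \code{found},
#'   \code{positiveAndSignificant}, \code{nonUniform}, \code{saturated},
#'   \code{popOutlier}, and a named logical vector \code{isControl}.
#' @param groups character/factor of sample-group labels, one per array.
#' @param minFraction retention fraction within a group (default 0.5).
#' @return list: \code{keep} (named logical mask), \code{dropCounts}
#'   (per-rule counts; a probe is counted under every rule it violates).
#' @export
filterExpressionProbes <- function(flags, groups, minFraction = 0.5) {
  req <- c("found", "positiveAndSignificant", "nonUniform", "saturated",
           "popOutlier")
  if (!all(req %in% names(flags))) {
    stop("flags must contain: ", paste(req, collapse = ", "))
  }
  for (f in req) {
    if (anyNA(flags[[f]])) stop(sprintf("flag '%s' has missing values", f))
  }
  groups <- as.character(groups)
  if (any(table(groups) == 0L)) stop("every group needs at least one sample")
  probes <- rownames(flags$found)

  ctrl <- flags$isControl[probes]
  ctrl[is.na(ctrl)] <- FALSE
  badAny <- rowSums(flags$nonUniform | flags$saturated |
                      flags$popOutlier) > 0L
  ok <- flags$found & flags$positiveAndSignificant
  keptByGroup <- vapply(unique(groups), function(g) {
    rowMeans(ok[, groups == g, drop = FALSE]) >= minFraction
  }, logical(length(probes)))
  foundRule <- rowSums(keptByGroup) > 0L

  keep <- !ctrl & !badAny & foundRule
  names(keep) <- probes
  list(
    keep = keep,
    dropCounts = c(
      control = sum(ctrl),
      non_uniform = sum(rowSums(flags$nonUniform) > 0L),
      saturated = sum(rowSums(flags$saturated) > 0L),
      population_outlier = sum(rowSums(flags$popOutlier) > 0L),
      not_found = sum(!foundRule & !ctrl & !badAny)
    )
  )
}

#' Average technical replicate probes
#'
#' Collapses rows sharing a replicate-group identifier to their arithmetic
#' per-sample mean; singleton groups pass through unchanged.
#'
#' @param x numeric matrix (features x samples) or
#'   \linkS4class{MixedOmicsExperiment}.
#' @param replicateGroups named character: replicate-group id per feature
#'   (names are feature ids of \code{x}).
#' @return object of the same class, one row per replicate group (first-seen
#'   order).
#' @export
averageReplicates <- function(x, replicateGroups) {
  m <- if (is(x, "MixedOmicsExperiment")) omicsMatrix(x) else as.matrix(x)
  g <- replicateGroups[rownames(m)]
  if (anyNA(g)) stop("every feature needs a replicate-group id")
  if (!all(table(g) >= 1L)) stop("empty replicate group")
  first <- !duplicated(g)
  out <- rowsum(m, group = g, reorder = FALSE)
  cnt <- as.vector(table(g)[rownames(out)])
  out <- out / cnt
  out <- out[unique(g[first]), , drop = FALSE]
  if (is(x, "MixedOmicsExperiment")) {
    MixedOmicsExperiment(out, modality(x),
                         sampleData = as.data.frame(colData(x)),
                         dynRange = metadata(x)$dynRange)
  } else {
    out
  }
}

#' Filter CpGs on detection p values and annotation
#'
#' Drops CpGs failing the detection p threshold (default 0.01; by default a
#' failure in any sample drops the CpG), mapping to chrX/chrY, flagged as
#' SNP-affected, or flagged as cross-reactive.
#'
#' @param detectionP numeric CpG x sample matrix of detection p values.
#' @param annotation data.frame with \code{cpg_id}, \code{chrom},
#'   \code{snp_affected}, \code{cross_reactive} covering every CpG.
#' @param threshold detection p threshold (a p >= threshold fails).
#' @param mode \code{"any"}: fail in any sample drops the CpG;
#'   \code{"fraction"}: drop when the failing fraction exceeds
#'   \code{maxFailFraction}.
#' @param maxFailFraction used by \code{mode = "fraction"}.
#' @return list: \code{keep} (named logical), \code{dropCounts} per rule.
#' @export
filterCpGs <- function(detectionP, annotation, threshold = 0.01,
                       mode = c("any", "fraction"), maxFailFraction = 0.05) {
  mode <- match.arg(mode)
  ids <- rownames(detectionP)
  hit <- match(ids, annotation$cpg_id)
  if (anyNA(hit)) {
    stop("CpGs missing annotation: ",
         paste(utils::head(ids[is.na(hit)], 5L), collapse = ", "))
  }
  ann <- annotation[hit, ]
  if (any(detectionP < 0 | detectionP > 1)) {
    stop("detection p values must lie in [0, 1]")
  }
  fail <- detectionP >= threshold
  detDrop <- if (mode == "any") {
    rowSums(fail) > 0L
  } else {
    rowMeans(fail) > maxFailFraction
  }
  sexDrop <- ann$chrom %in% c("chrX", "chrY", "X", "Y")
  snpDrop <- as.logical(ann$snp_affected)
  crossDrop <- as.logical(ann$cross_reactive)
  keep <- !(detDrop | sexDrop | snpDrop | crossDrop)
  names(keep) <- ids
  list(
    keep = keep,
    dropCounts = c(detection_p = sum(detDrop),
                   sex_chromosome = sum(sexDrop),
                   snp_affected = sum(snpDrop),
                   cross_reactive = sum(crossDrop))
  )
}
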