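#' Per-probe correlation of expression with RNA integrity
#'
#' Pearson correlation of each probe's (log2) expression with the per-sample
#' RIN, with a two-sided t-test p value. On quantile-normalized degraded
#' data the spectrum characteristically contains both signs: probes that
#' decay faster than average correlate positively with RIN, slower-decaying
#' probes negatively, because rank-based normalization redistributes the
#' overall signal loss.
#'
#' @param x numeric matrix (probes x samples) or
#'   \linkS4class{MixedOmicsExperiment}.
#' @param rin numeric, one RIN per sample; must vary.
#' @return data.frame of class \code{RinCorrelationSpectrum}: \code{probe},
#'   \code{r}, \code{p}, \code{scored} (FALSE for zero-variance probes,
#'   whose r/p are NA). Attribute \code{summary} holds the fraction of
#'   scored probes with positive / negative r.
#' @export
rinCorrelations <- function(x, rin) {
  m <- if (is(x, "MixedOmicsExperiment")) omicsMatrix(x) else as.matrix(x)
  n <- ncol(m)
  if (n < 3L) stop("at least 3 samples are required")
  if (length(rin) != n) stop("one RIN per sample required")
  if (stats::sd(rin) == 0) stop("RIN is constant: no degradation axis")
  sds <- apply(m, 1L, stats::sd)
  scored <- sds > 0
  r <- rep(NA_real_, nrow(m))
  r[scored] <- as.vector(stats::cor(t(m[scored, , drop = FALSE]), rin))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out <- data.frame(probe = rownames(m), r = r, p = p, scored = scored,
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- c(
    frac_positive = mean(r[scored] > 0),
    frac_negative = mean(r[scored] < 0)
  )
  class(out) <- c("RinCorrelationSpectrum", class(out))
  out
}

#' Remove probes correlated with RIN (correlation filtering)
#'
#' Retains probes whose absolute Pearson correlation with RIN is below the
#' threshold. The threshold is a required, explicit parameter: it is a
#' study-specific trade-off between degradation removal and transcript loss,
#' so no silent default is applied in pipeline runs. Probes that cannot be
#' scored (zero variance) are retained.
#'
#' @inheritParams rinCorrelations
#' @param rThreshold absolute-correlation threshold in (0, 1].
#' @return list: \code{filtered} (same class as \code{x}, retained probes),
#'   \code{removed} (probe ids), \code{spectrum}.
#' @export
correlationFilter <- function(x, rin, rThreshold) {
  .assertScalarNumber(rThreshold, "rThreshold")
  if (rThreshold <= 0 || rThreshold > 1) {
    stop("rThreshold must lie in (0, 1]")
  }
  spec <- rinCorrelations(x, rin)
  drop <- spec$scored & abs(spec$r) >= rThreshold
  keepIds <- spec$probe[!drop]
  filtered <- if (is(x, "MixedOmicsExperiment")) {
    x[keepIds, ]
  } else {
    as.matrix(x)[keepIds, , drop = FALSE]
  }
  list(filtered = filtered, removed = spec$probe[drop], spectrum = spec)
}

#' Correct RIN-associated degradation bias by per-probe linear regression
#'
#' Fits, per probe, \code{value ~ intercept + b * RIN} (plus group indicator
#' columns when \code{covariates} is supplied) by least squares and subtracts
#' the RIN term: \code{corrected = observed - b * (RIN - rinRef)}. Only the
#' RIN slope is removed, so group effects encoded in the covariates are
#' preserved. In covariate-free mode the least-squares residual property
#' makes every corrected probe's correlation with RIN numerically zero. No
#' probes are lost.
#'
#' @inheritParams rinCorrelations
#' @param covariates optional vector of group labels (one per sample) to
#'   include as indicator covariates; a warning (with condition number) is
#'   issued when they are nearly collinear with RIN.
#' @param rinRef reference RIN the data are shifted to; defaults to the
#'   cohort mean RIN, keeping corrected values on the observed scale.
#' @return list: \code{corrected} (same class/shape as \code{x}),
#'   \code{slopes} (named per-probe RIN slope), \code{rinRef}.
#' @export
linearCorrection <- function(x, rin, covariates = NULL, rinRef = mean(rin)) {
  m <- if (is(x, "MixedOmicsExperiment")) omicsMatrix(x) else as.matrix(x)
  if (ncol(m) < 3L) stop("at least 3 samples are required")
  if (length(rin) != ncol(m)) stop("one RIN per sample required")
  if (stats::sd(rin) == 0) stop("RIN is constant: no degradation axis")

  X <- cbind(intercept = 1, rin = rin)
  if (!is.null(covariates)) {
    f <- factor(covariates)
    if (nlevels(f) > 1L) {
      X <- cbind(X, stats::model.matrix(~f)[, -1L, drop = FALSE])
    }
    fit <- stats::lm.fit(stats::model.matrix(~f), rin)
    if (sum(fit$residuals^2) < 1e-10 * sum((rin - mean(rin))^2)) {
      warning(sprintf(
        "covariates are collinear with RIN (design condition number %.3g); RIN slope is not identifiable",
        kappa(X)
      ))
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient correction design; dropping redundant columns")
  }
  coefs <- t(qr.coef(qrX, t(m)))
  slopes <- coefs[, "rin"]
  slopes[!is.finite(slopes)] <- 0  # singular fits: no correction
  corrected <- m - outer(slopes, rin - rinRef)
  out <- if (is(x, "MixedOmicsExperiment")) {
    .replaceAssay(x, corrected)
  } else {
    corrected
  }
  list(corrected = out, slopes = slopes, rinRef = rinRef)
}

#' Principal-component scores for sample-level diagnostics
#'
#' Feature-centered PCA of the samples, used to visualize how strongly RNA
#' degradation (or any batch axis) dominates overall variance before and
#' after correction. Component signs are fixed deterministically: the
#' largest-magnitude loading of each component is made positive.
#'
#' @param x numeric matrix (features x samples) or
#'   \linkS4class{MixedOmicsExperiment}.
#' @param nComponents number of components requested; reduced with a warning
#'   when the matrix rank is lower.
#' @return list: \code{scores} (samples x components),
#'   \code{varianceExplained} (percent per component), \code{loadings}.
#' @export
pcaScores <- function(x, nComponents = 2) {
  m <- if (is(x, "MixedOmicsExperiment")) omicsMatrix(x) else as.matrix(x)
  if (nrow(m) < nComponents) stop("more components than features")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  avail <- sum(pc$sdev > 1e-12)
  if (avail < nComponents) {
    warning(sprintf("rank %d < %d requested components", avail, nComponents))
    nComponents <- avail
  }
  idx <- seq_len(nComponents)
  rot <- pc$rotation[, idx, drop = FALSE]
  sc <- pc$x[, idx, drop = FALSE]
  for (j in idx) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) {
      rot[, j] <- -rot[, j]
      sc[, j] <- -sc[, j]
    }
  }
  list(
    scores = sc,
    varianceExplained = 100 * pc$sdev[idx]^2 / sum(pc$sdev^2),
    loadings = rot
  )
}
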