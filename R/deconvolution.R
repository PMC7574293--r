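#' Build a group-wise deconvolution design from differential cell counts
#'
#' Converts per-sample cell-count percentages into the samples x coefficients
#' design of the deconvolution regression: one column per major cell type
#' plus a final "weighed intercept" column equal to the summed proportions of
#' all remaining (minor) cell types, which absorbs their pooled profile and
#' preserves residual degrees of freedom. Excluded cell types (monocytes by
#' default: too scarce to be estimable and absent in some groups) are removed
#' before renormalizing each row to the unit simplex.
#'
#' @param cellCounts data.frame with one percentage column per cell type
#'   (rows ~ samples, summing to ~100); a \code{sample_id} column, if
#'   present, provides row names.
#' @param majorTypes ordered major cell-type labels (design column order).
#' @param excluded cell types removed before renormalization.
#' @param renormalize divide rows by their post-exclusion sum (default);
#'   \code{FALSE} keeps raw proportions (rows then sum to < 1 and validity
#'   checking is relaxed accordingly - only offered for sensitivity checks).
#' @return a \linkS4class{DeconvDesign}.
#' @examples
#' cc <- data.frame(AM = 27.9, NG = 54.7, EO = 12.9, LY = 0.7, MO = 0.1,
#'                  CC = 1.6, SC = 2.1)
#' designMatrix(buildDesign(cc, c("AM", "NG", "EO")))
#' @export
buildDesign <- function(cellCounts, majorTypes, excluded = "MO",
                        renormalize = TRUE) {
  cellCols <- setdiff(colnames(cellCounts),
                      c("sample_id", "group"))
  if (!all(majorTypes %in% cellCols)) {
    stop("major cell type(s) absent from the count table: ",
         paste(setdiff(majorTypes, cellCols), collapse = ", "))
  }
  m <- as.matrix(cellCounts[, cellCols, drop = FALSE])
  if (any(abs(rowSums(m) - 100) > 0.5)) {
    stop("cell-count rows must sum to ~100%")
  }
  keepCols <- setdiff(cellCols, excluded)
  m <- m[, keepCols, drop = FALSE] / 100
  rs <- rowSums(m)
  if (any(rs <= 0)) stop("a sample has zero counts after exclusion")
  if (renormalize) m <- m / rs
  minors <- setdiff(keepCols, majorTypes)
  design <- cbind(
    m[, majorTypes, drop = FALSE],
    other = if (length(minors)) {
      rowSums(m[, minors, drop = FALSE])
    } else {
      rep(0, nrow(m))
    }
  )
  if (!is.null(cellCounts$sample_id)) {
    rownames(design) <- cellCounts$sample_id
  }
  new("DeconvDesign",
      design = design, majorTypes = majorTypes,
      minorTypes = minors, excluded = as.character(excluded),
      conditionNumber = kappa(design))
}

#' Solve one box-constrained least-squares problem exactly
#'
#' Minimizes \code{||y - F beta||^2} subject to \code{lower <= beta <= upper}
#' (a strictly convex quadratic program when F has full column rank). The
#' solver first computes the unconstrained least-squares solution; if it is
#' interior to the box it is returned directly. Otherwise the active set of
#' the optimum is found by exact enumeration: for every assignment of each
#' coefficient to \{free, at lower, at upper\}, the equality-constrained
#' minimizer is computed and the best feasible candidate returned. For the
#' small per-feature designs used here (p <= ~6) this is exact and fast.
#'
#' @param F numeric design matrix (n x p, n >= p).
#' @param y numeric response vector of length n.
#' @param lower,upper box bounds, scalars or length-p vectors.
#' @param ridge diagonal inflation added to \code{crossprod(F)} when it is
#'   numerically singular (logged in the diagnostics).
#' @return list: \code{beta}, \code{objective} (residual sum of squares),
#'   \code{active} (-1 lower / 0 free / +1 upper per coefficient),
#'   \code{ridged} (logical).
#' @examples
#' solveBoxLS(diag(2), c(0.5, 1.2), 0, 1)$beta  # 0.5, 1.0
#' @export
solveBoxLS <- function(F, y, lower, upper, ridge = 1e-8) {
  F <- as.matrix(F)
  p <- ncol(F)
  if (length(lower) == 1L) lower <- rep(lower, p)
  if (length(upper) == 1L) upper <- rep(upper, p)
  if (any(lower >= upper)) stop("infeasible bounds: lower must be < upper")
  if (nrow(F) < p) stop("more coefficients than observations")
  if (any(!is.finite(y))) stop("response contains non-finite values")

  XtX <- crossprod(F)
  Xty <- crossprod(F, y)
  yty <- sum(y^2)
  ridged <- FALSE
  if (rcond(XtX) < 1e-12) {
    XtX <- XtX + diag(ridge * max(1, diag(XtX)), p)
    ridged <- TRUE
  }
  obj <- function(b) as.numeric(yty - 2 * crossprod(b, Xty) +
                                  crossprod(b, XtX %*% b))
  tol <- 1e-10 * max(1, abs(upper - lower))

  ols <- as.vector(solve(XtX, Xty))
  if (all(ols >= lower - tol & ols <= upper + tol)) {
    beta <- pmin(pmax(ols, lower), upper)
    return(list(beta = stats::setNames(beta, colnames(F)),
                objective = obj(beta),
                active = integer(p), ridged = ridged))
  }

  states <- as.matrix(expand.grid(rep(list(c(0L, -1L, 1L)), p)))
  best <- NULL
  bestObj <- Inf
  bestActive <- integer(p)
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    if (all(s == 0L)) next  # unconstrained case handled above
    b <- ifelse(s == -1L, lower, ifelse(s == 1L, upper, NA_real_))
    freeIdx <- which(s == 0L)
    if (length(freeIdx)) {
      rhs <- Xty[freeIdx] -
        XtX[freeIdx, -freeIdx, drop = FALSE] %*% b[-freeIdx]
      bf <- tryCatch(
        as.vector(solve(XtX[freeIdx, freeIdx, drop = FALSE], rhs)),
        error = function(e) NULL
      )
      if (is.null(bf)) next
      if (any(bf < lower[freeIdx] - tol | bf > upper[freeIdx] + tol)) next
      b[freeIdx] <- pmin(pmax(bf, lower[freeIdx]), upper[freeIdx])
    }
    o <- obj(b)
    if (o < bestObj - 1e-15) {
      bestObj <- o
      best <- b
      bestActive <- s
    }
  }
  if (is.null(best)) stop("box-constrained solve failed to converge")
  list(beta = stats::setNames(best, colnames(F)), objective = bestObj,
       active = as.integer(bestActive), ridged = ridged)
}

#' Resolve box bounds for a modality
#'
#' Methylation estimates are constrained to [0, 1]; expression estimates to
#' the dynamic range of the array, taken from the object's stored
#' \code{dynRange} or, failing that, the observed min/max of the matrix
#' (\code{"auto"}).
#'
#' @param x a \linkS4class{MixedOmicsExperiment}.
#' @param bounds \code{"auto"} or numeric(2).
#' @return numeric(2) lower/upper bounds.
#' @export
resolveBounds <- function(x, bounds = "auto") {
  if (is.numeric(bounds)) {
    stopifnot(length(bounds) == 2L, bounds[1L] < bounds[2L])
    return(as.numeric(bounds))
  }
  switch(modality(x),
    "methylation-beta" = c(0, 1),
    "expression-linear" = {
      dr <- metadata(x)$dynRange
      if (is.null(dr)) dr <- range(omicsMatrix(x))
      as.numeric(dr)
    },
    stop("no bounds defined for modality ", modality(x))
  )
}

#' Deconvolve cell-type-specific profiles for one sample group
#'
#' Fits, per feature, the box-constrained least-squares regression of the
#' mixed-cell signal on the cell-fraction design (one coefficient per major
#' cell type plus the pooled-minor intercept). Expression must be on the
#' linear scale and methylation on the beta scale - the mixing model is
#' linear in those units; log2 input is a hard error. Standard errors use
#' the unconstrained-regression formula
#' \code{SE_j = sigma_hat * sqrt([(F'F)^-1]_jj)} with
#' \code{sigma_hat^2 = RSS / (n - p)} even when box constraints are active;
#' features with active constraints are flagged (\code{nActive > 0}) so
#' users can filter.
#'
#' @param x \linkS4class{MixedOmicsExperiment} restricted to the group's
#'   samples; modality \code{"expression-linear"} or
#'   \code{"methylation-beta"}.
#' @param design a \linkS4class{DeconvDesign} whose rows match the samples
#'   of \code{x}.
#' @param bounds \code{"auto"} (see \code{\link{resolveBounds}}) or
#'   numeric(2).
#' @param group group label stored with the result.
#' @return a \linkS4class{CellProfileEstimate}.
#' @export
deconvolveGroup <- function(x, design, bounds = "auto", group = "group") {
  stopifnot(is(x, "MixedOmicsExperiment"), is(design, "DeconvDesign"))
  if (modality(x) == "expression-log2") {
    stop("deconvolution requires linear-scale expression: ",
         "transform with 2^x and set modality 'expression-linear'")
  }
  FF <- designMatrix(design)
  if (nrow(FF) != ncol(x)) {
    stop("design rows must match the samples of the matrix")
  }
  if (!is.null(rownames(FF)) &&
      !identical(rownames(FF), colnames(x))) {
    if (!all(colnames(x) %in% rownames(FF))) {
      stop("design and matrix sample identifiers do not match")
    }
    FF <- FF[colnames(x), , drop = FALSE]
  }
  n <- nrow(FF)
  p <- ncol(FF)
  if (n <= p) stop("insufficient degrees of freedom (n <= p)")
  b <- resolveBounds(x, bounds)

  Y <- omicsMatrix(x)
  XtX <- crossprod(FF)
  ridged <- FALSE
  if (rcond(XtX) < 1e-12) {
    XtX <- XtX + diag(1e-8 * max(1, diag(XtX)), p)
    ridged <- TRUE
    warning("near-singular design: tiny ridge applied")
  }
  XtXinv <- solve(XtX)
  # unconstrained OLS for all features at once (fast path)
  B <- Y %*% FF %*% XtXinv  # features x p
  tol <- 1e-10 * max(1, b[2L] - b[1L])
  interior <- rowSums(B < b[1L] - tol | B > b[2L] + tol) == 0L

  est <- pmin(pmax(B, b[1L]), b[2L])
  nActive <- integer(nrow(Y))
  failed <- logical(nrow(Y))
  for (f in which(!interior)) {
    sol <- tryCatch(
      solveBoxLS(FF, Y[f, ], b[1L], b[2L]),
      error = function(e) NULL
    )
    if (is.null(sol)) {
      est[f, ] <- NA_real_
      failed[f] <- TRUE
    } else {
      est[f, ] <- sol$beta
      nActive[f] <- sum(sol$active != 0L)
    }
  }

  fitted <- est %*% t(FF)
  rss <- rowSums((Y - fitted)^2)
  sigma2 <- rss / (n - p)
  se <- sqrt(outer(sigma2, pmax(diag(XtXinv), 0)))
  dimnames(est) <- dimnames(se) <- list(rownames(Y), colnames(FF))

  new("CellProfileEstimate",
      group = group, modality = modality(x),
      estimates = est, se = se,
      df = rep(as.numeric(n - p), nrow(Y)),
      bounds = b, nActive = nActive, objective = rss)
}

#' Regression standard errors for a fitted feature
#'
#' The standard regression-analysis SE formula used throughout the
#' deconvolution: \code{sigma_hat^2 = RSS / (n - p)},
#' \code{SE_j = sigma_hat * sqrt([(F'F)^-1]_jj)}, with residual df
#' \code{n - p} shared by all coefficients of a feature.
#'
#' @param F design matrix (n x p, n > p).
#' @param residuals numeric vector (length n) or matrix (features x n).
#' @return list: \code{se} (matrix, features x p), \code{df}.
#' @export
estimateSEs <- function(F, residuals) {
  F <- as.matrix(F)
  n <- nrow(F)
  p <- ncol(F)
  if (n <= p) stop("insufficient degrees of freedom (n <= p)")
  R <- if (is.matrix(residuals)) residuals else matrix(residuals, nrow = 1L)
  if (ncol(R) != n) stop("residuals must have one value per observation")
  sigma2 <- rowSums(R^2) / (n - p)
  d <- diag(solve(crossprod(F)))
  se <- sqrt(outer(sigma2, pmax(d, 0)))
  colnames(se) <- colnames(F)
  list(se = se, df = n - p)
}
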