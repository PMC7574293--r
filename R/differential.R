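#' Significance threshold policies
#'
#' Returns the cutoff pair (BH-adjusted p, minimum absolute effect) for a
#' given analysis context. Mixed-cell screens use BH p < 0.05 with
#' |log2FC| >= 1.5 (expression) or |delta beta| >= 0.1 (methylation).
#' Tests on deconvolved estimates use deliberately stricter p cutoffs
#' (0.005 expression, 0.001 methylation) at the same effect cutoffs,
#' compensating for likely non-normality of the estimate distributions.
#'
#' @param context \code{"mixed"} or \code{"deconvolved"}.
#' @param modality \code{"expression"} or \code{"methylation"}.
#' @return list: \code{pAdj}, \code{minEffect}, \code{context},
#'   \code{modality}.
#' @export
thresholdPolicy <- function(context = c("mixed", "deconvolved"),
                            modality = c("expression", "methylation")) {
  context <- match.arg(context)
  modality <- match.arg(modality)
  pAdj <- if (context == "mixed") {
    0.05
  } else if (modality == "methylation") {
    0.001
  } else {
    0.005
  }
  minEffect <- if (modality == "expression") 1.5 else 0.1
  list(pAdj = pAdj, minEffect = minEffect, context = context,
       modality = modality)
}

#' Welch unequal-variance t-test from raw group values
#'
#' Row-wise Welch two-sample test:
#' \code{t = (mean(x) - mean(y)) / sqrt(s1^2/n1 + s2^2/n2)} with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p value. With zero
#' variance in both groups, equal means give t = 0 / p = 1; unequal means an
#' underflow-guarded near-zero p.
#'
#' @param x,y numeric matrices (features x samples; >= 2 samples each) or
#'   vectors (treated as a single feature).
#' @return data.frame: \code{t}, \code{df}, \code{p} per feature.
#' @examples
#' welchFromSamples(c(1, 2, 3), c(1, 2, 3))  # t = 0, p = 1
#' @export
welchFromSamples <- function(x, y) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (!is.matrix(y)) y <- matrix(y, nrow = 1L)
  if (nrow(x) != nrow(y)) stop("x and y must cover the same features")
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 values")
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  .welch(m1 - m2, v1 / n1, n1 - 1, v2 / n2, n2 - 1,
         features = rownames(x))
}

#' Welch t-test from deconvolved estimates and their standard errors
#'
#' Compares two regression estimates:
#' \code{t = (b1 - b2) / sqrt(se1^2 + se2^2)} with Welch-Satterthwaite
#' degrees of freedom
#' \code{(se1^2 + se2^2)^2 / (se1^4/df1 + se2^4/df2)} and a two-sided p.
#' This is the test applied across disease groups to the cell-type-specific
#' estimates produced by \code{\link{deconvolveGroup}}.
#'
#' @param b1,se1,df1 estimate, standard error and residual df for group 1
#'   (vectors over features).
#' @param b2,se2,df2 likewise for group 2.
#' @return data.frame: \code{t}, \code{df}, \code{p} per feature.
#' @export
welchFromEstimates <- function(b1, se1, df1, b2, se2, df2) {
  if (any(c(se1, se2) < 0, na.rm = TRUE)) stop("SEs must be >= 0")
  if (any(c(df1, df2) < 1)) stop("dfs must be >= 1")
  .welch(b1 - b2, se1^2, df1, se2^2, df2, features = names(b1))
}

# shared Welch core: delta, squared SE components and their dfs
.welch <- function(delta, c1, df1, c2, df2, features = NULL) {
  tot <- c1 + c2
  t <- ifelse(tot > 0, delta / sqrt(tot),
              ifelse(delta == 0, 0, sign(delta) * Inf))
  df <- ifelse(tot > 0, tot^2 / (c1^2 / df1 + c2^2 / df2), df1 + df2)
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df = df),
              .Machine$double.xmin)
  p[t == 0 & tot == 0] <- 1
  data.frame(feature = if (is.null(features)) {
    seq_along(delta)
  } else {
    features
  }, t = t, df = df, p = pmin(p, 1), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (sorted ascending, \code{adj_i = min_{j>=i}
#' p_j * m / j}, capped at 1, returned in input order). Missing values are
#' propagated and their count reported via a message.
#'
#' @param p numeric vector of p values in [0, 1] (NA allowed).
#' @return adjusted p values, same length and order.
#' @export
bhAdjust <- function(p) {
  nNA <- sum(is.na(p))
  if (nNA > 0L) message(nNA, " missing p value(s) propagated")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Effect sizes per modality and context
#'
#' Methylation effects are differences of group beta means/estimates (delta
#' beta). Mixed-cell expression effects are differences of group log2 means.
#' Deconvolved expression effects are \code{log2(b1 / b2)} of the
#' linear-scale estimates, which the box constraints keep strictly positive;
#' a nonpositive estimate is an assertion failure.
#'
#' @param modality \code{"expression"} or \code{"methylation"}.
#' @param context \code{"mixed"} or \code{"deconvolved"}.
#' @param stat1,stat2 per-feature group summaries: mixed-cell log2 means /
#'   beta means, or deconvolved estimates.
#' @return numeric effect vector.
#' @export
computeEffects <- function(modality = c("expression", "methylation"),
                           context = c("mixed", "deconvolved"),
                           stat1, stat2) {
  modality <- match.arg(modality)
  context <- match.arg(context)
  if (modality == "methylation") {
    return(stat1 - stat2)
  }
  if (context == "mixed") {
    return(stat1 - stat2)  # difference of log2 means
  }
  if (any(stat1 <= 0 | stat2 <= 0, na.rm = TRUE)) {
    stop("deconvolved expression estimates must be > 0 (bounds violated?)")
  }
  log2(stat1 / stat2)
}

#' Apply a threshold policy and summarize calls
#'
#' Marks a feature significant iff its BH-adjusted p and absolute effect
#' pass the policy cutoffs; splits calls into up/down by effect sign.
#'
#' @param table data.frame with at least \code{effect} and \code{p_adj}.
#' @param policy a \code{\link{thresholdPolicy}}.
#' @return the table with \code{significant} and \code{direction} columns;
#'   attribute \code{summary} holds \code{c(up, down, total)} and the policy.
#' @export
callSignificant <- function(table, policy) {
  stopifnot(all(c("effect", "p_adj") %in% colnames(table)))
  sig <- !is.na(table$p_adj) & table$p_adj < policy$pAdj &
    abs(table$effect) >= policy$minEffect
  table$significant <- sig
  table$direction <- ifelse(!sig, "ns",
                            ifelse(table$effect > 0, "up", "down"))
  attr(table, "summary") <- list(
    counts = c(up = sum(sig & table$effect > 0),
               down = sum(sig & table$effect < 0),
               total = sum(sig)),
    policy = policy
  )
  table
}

#' Differential table from two groups of raw samples
#'
#' Mixed-cell differential analysis: Welch test per feature, effects per
#' modality (log2-mean difference for expression - supply log2 values - or
#' delta beta for methylation), BH adjustment, policy-based calls.
#'
#' @param x,y numeric matrices (features x samples) for the two groups
#'   (e.g. disease vs control). For expression, log2-scale values.
#' @param modality \code{"expression"} or \code{"methylation"}.
#' @return data.frame of class \code{DifferentialTable}: feature, effect,
#'   t, df, p, p_adj, significant, direction, context.
#' @export
differentialFromSamples <- function(x, y,
                                    modality = c("expression",
                                                 "methylation")) {
  modality <- match.arg(modality)
  w <- welchFromSamples(x, y)
  w$effect <- computeEffects(modality, "mixed", rowMeans(x), rowMeans(y))
  w$p_adj <- bhAdjust(w$p)
  out <- callSignificant(w, thresholdPolicy("mixed", modality))
  out$context <- "mixed"
  class(out) <- c("DifferentialTable", class(out))
  out
}

#' Differential table from deconvolved estimates of one cell type
#'
#' Compares one cell type's deconvolved profile between two groups via
#' \code{\link{welchFromEstimates}}, with deconvolved effect sizes and the
#' stricter deconvolved-context policy.
#'
#' @param est1,est2 \linkS4class{CellProfileEstimate}s for the two groups
#'   (same features and coefficient set).
#' @param cellType coefficient (cell-type column) to compare.
#' @return data.frame of class \code{DifferentialTable} (context = the cell
#'   type label).
#' @export
differentialFromEstimates <- function(est1, est2, cellType) {
  stopifnot(is(est1, "CellProfileEstimate"),
            is(est2, "CellProfileEstimate"))
  if (!cellType %in% colnames(estimates(est1))) {
    stop(sprintf("cell type '%s' not among the estimated coefficients",
                 cellType))
  }
  feats <- intersect(rownames(estimates(est1)), rownames(estimates(est2)))
  b1 <- estimates(est1)[feats, cellType]
  b2 <- estimates(est2)[feats, cellType]
  w <- welchFromEstimates(
    b1, standardErrors(est1)[feats, cellType], residualDf(est1)[1L],
    b2, standardErrors(est2)[feats, cellType], residualDf(est2)[1L]
  )
  modality <- if (est1@modality == "methylation-beta") {
    "methylation"
  } else {
    "expression"
  }
  w$effect <- computeEffects(modality, "deconvolved", b1, b2)
  w$p_adj <- bhAdjust(w$p)
  out <- callSignificant(w, thresholdPolicy("deconvolved", modality))
  out$context <- cellType
  class(out) <- c("DifferentialTable", class(out))
  out
}
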