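# Independent oracles and shared fixtures for the test suite.

# Benjamini-Hochberg step-up, written out explicitly (independent of
# p.adjust): sort ascending, adj_i = min_{j >= i} p_j * m / j, cap at 1.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Exact upper-tail hypergeometric P(X >= k) by combinatorial enumeration.
hyperOracle <- function(k, K, N, n) {
  if (k == 0L) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Exact minimum of ||y - F b||^2 over the [0,1]^2 grid with the given step:
# for each grid value of b1 the objective is quadratic in b2, so only the
# two grid points bracketing the clamped analytic minimizer can attain the
# per-b1 minimum.
gridOracleMin <- function(F, y, step = 1e-3) {
  XtX <- crossprod(F)
  Xty <- crossprod(F, y)
  yty <- sum(y^2)
  best <- Inf
  for (v in seq(0, 1, by = step)) {
    b2star <- (Xty[2L] - XtX[1L, 2L] * v) / XtX[2L, 2L]
    cand <- unique(pmin(pmax(
      c(floor(b2star / step), ceiling(b2star / step)) * step, 0), 1))
    for (w in cand) {
      o <- yty - 2 * (v * Xty[1L] + w * Xty[2L]) +
        XtX[1L, 1L] * v^2 + 2 * XtX[1L, 2L] * v * w + XtX[2L, 2L] * w^2
      if (o < best) best <- o
    }
  }
  best
}

# Small cached study shared by several test files (cheap to build once).
smallStudyConfig <- function(nFeatures = 400, ...) {
  sputumStudyConfig(
    nPerGroup = c(asthma = 6, copd = 6, control = 6),
    nFeatures = nFeatures,
    ...
  )
}

.studyCache <- new.env(parent = emptyenv())
cachedStudy <- function(key = "small", builder = NULL) {
  if (is.null(.studyCache[[key]])) {
    .studyCache[[key]] <- if (is.null(builder)) {
      simulateSputumStudy(smallStudyConfig(), seed = 101)
    } else {
      builder()
    }
  }
  .studyCache[[key]]
}
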