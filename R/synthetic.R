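#' Cell-fraction model for sputum differential counts
#'
#' Group-specific Dirichlet models of the seven-part sputum differential cell
#' count (alveolar macrophages AM, neutrophils NG, eosinophils EO, lymphocytes
#' LY, monocytes MO, ciliated cells CC, squamous cells SC). Default means are
#' the published group means for eosinophilic asthma, stable COPD and healthy
#' controls; each group has a single Dirichlet concentration parameter chosen
#' so that the marginal SD of the dominant cell type approximates the
#' published SD (a Dirichlet guarantees valid simplex rows, which independent
#' truncated normals do not).
#'
#' @param means named list of named numeric vectors (percentages per cell
#'   type, one vector per group). Normalized internally to sum to 1.
#' @param concentration named numeric, Dirichlet concentration per group;
#'   \code{Inf} collapses sampling to the mean vector.
#' @return An object of class \code{FractionModel}.
#' @examples
#' m <- sputumFractionModel()
#' m$means$asthma
#' @export
sputumFractionModel <- function(
    means = list(
      asthma  = c(AM = 27.9, NG = 54.7, EO = 12.9, LY = 0.7, MO = 0.1,
                  CC = 1.6, SC = 2.1),
      copd    = c(AM = 9.0, NG = 88.9, EO = 1.0, LY = 0.2, MO = 0.0,
                  CC = 0.4, SC = 0.6),
      control = c(AM = 52.3, NG = 40.3, EO = 0.2, LY = 2.0, MO = 0.2,
                  CC = 1.6, SC = 3.4)
    ),
    concentration = c(asthma = 3.2, copd = 21, control = 3.0)) {
  means <- lapply(means, function(m) {
    if (any(m < 0)) stop("fraction means must be >= 0")
    m / sum(m)
  })
  if (!all(names(means) %in% names(concentration))) {
    stop("every group needs a concentration parameter")
  }
  structure(list(means = means, concentration = concentration),
            class = "FractionModel")
}

#' Sample a differential cell-count table
#'
#' Draws per-sample cell-type percentage rows from the group's Dirichlet model.
#' Rows sum to 100 exactly (up to floating point); column means converge to
#' the model means as \code{n} grows.
#'
#' @param group group label present in \code{model}.
#' @param n number of samples (>= 1).
#' @param model a \code{\link{sputumFractionModel}}.
#' @param seed optional integer seed (RNG state is restored afterwards);
#'   \code{NULL} uses the current RNG stream.
#' @param prefix sample-identifier prefix.
#' @return \code{data.frame} with \code{sample_id}, \code{group} and one
#'   percentage column per cell type.
#' @examples
#' cc <- generateCellFractions("asthma", 5, seed = 1)
#' rowSums(cc[, -(1:2)])
#' @export
generateCellFractions <- function(group, n, model = sputumFractionModel(),
                                  seed = NULL, prefix = group) {
  if (!group %in% names(model$means)) {
    stop(sprintf("unknown group label '%s'", group))
  }
  if (n < 1) stop("n must be >= 1")
  m <- model$means[[group]]
  conc <- model$concentration[[group]]
  withSeed(seed, {
    if (is.infinite(conc)) {
      p <- matrix(m, n, length(m), byrow = TRUE)
    } else {
      alpha <- conc * m
      g <- vapply(alpha, function(a) {
        if (a <= 0) rep(0, n) else stats::rgamma(n, shape = a, rate = 1)
      }, numeric(n))
      if (n == 1L) g <- matrix(g, nrow = 1L)
      p <- g / rowSums(g)
    }
    colnames(p) <- names(m)
    data.frame(
      sample_id = sprintf("%s_%02d", prefix, seq_len(n)),
      group = group, 100 * p,
      stringsAsFactors = FALSE, check.names = FALSE
    )
  })
}

#' RNA-degradation model
#'
#' Describes (i) the RIN distribution per preservation method as a truncated
#' normal (defaults: RLT buffer 8.6 +/- 0.4 bounded to [7.6, 9.1]; HOPE
#' fixation 4.3 +/- 0.6 bounded to [3.2, 5.1]) and (ii) probe-specific
#' degradation susceptibility: a fraction of probes carries an exponential
#' decay rate lambda >= 0, so a sample at RIN r retains
#' \code{2^(-lambda * (rinRef - r))} of a probe's linear signal; samples at
#' \code{rinRef} are unaffected.
#'
#' @param rinLaw named list, per preservation method, of
#'   \code{c(mean, sd, min, max)}.
#' @param rinRef RIN at which no decay occurs.
#' @param susceptibleFraction fraction of probes with lambda > 0.
#' @param lambdaMean mean decay rate (log2 units per RIN unit) among
#'   susceptible probes (exponentially distributed). The default is
#'   calibrated so that degradation dominates the leading principal
#'   component of an uncorrected mixed-cell expression study, the situation
#'   that motivates in-silico correction.
#' @return An object of class \code{DegradationModel}.
#' @export
degradationModel <- function(
    rinLaw = list(
      RLT  = c(mean = 8.6, sd = 0.4, min = 7.6, max = 9.1),
      HOPE = c(mean = 4.3, sd = 0.6, min = 3.2, max = 5.1)
    ),
    rinRef = 9, susceptibleFraction = 0.5, lambdaMean = 0.3) {
  stopifnot(susceptibleFraction >= 0, susceptibleFraction <= 1,
            lambdaMean >= 0)
  structure(list(rinLaw = rinLaw, rinRef = rinRef,
                 susceptibleFraction = susceptibleFraction,
                 lambdaMean = lambdaMean),
            class = "DegradationModel")
}

#' Sample RIN values for one preservation method
#'
#' Truncated-normal sampling by inverse-CDF; all values fall inside the
#' method's \code{[min, max]} bounds. \code{sd = 0} returns the mean.
#'
#' @param preservation preservation label present in \code{model$rinLaw}
#'   (defaults: \code{"RLT"}, \code{"HOPE"}).
#' @param n number of samples.
#' @param model a \code{\link{degradationModel}}.
#' @param seed optional integer seed.
#' @return numeric vector of RIN values.
#' @export
generateRIN <- function(preservation, n, model = degradationModel(),
                        seed = NULL) {
  law <- model$rinLaw[[preservation]]
  if (is.null(law)) {
    stop(sprintf("unknown preservation label '%s'", preservation))
  }
  mu <- law[["mean"]]; s <- law[["sd"]]
  lo <- law[["min"]]; hi <- law[["max"]]
  withSeed(seed, {
    if (s == 0) return(rep(mu, n))
    pa <- stats::pnorm((lo - mu) / s)
    pb <- stats::pnorm((hi - mu) / s)
    mu + s * stats::qnorm(stats::runif(n, pa, pb))
  })
}

#' Configuration of the latent cell-type profile generator
#'
#' @param cellTypes cell-type labels (order fixes design-column order).
#' @param groups sample groups; the first is the baseline carrying no spiked
#'   effects.
#' @param exprLog2Range range of baseline per-feature log2 expression.
#' @param exprCellTypeSd SD of per-cell-type deviation around the baseline
#'   (log2 units).
#' @param dynRange dynamic range of the simulated expression array (linear
#'   scale); all expression profile values are clipped into it.
#' @param betaJitterSd SD of per-cell-type deviation of methylation beta
#'   around the per-feature baseline.
#' @param markersPerType number of marker features spiked per marker cell
#'   type, per modality.
#' @param markerTypes cell types receiving markers (monocytes are avoided by
#'   default: they are excluded from deconvolution designs, so MO signal is
#'   pure nuisance).
#' @param markerLog2Boost log2 units added to a marker's own cell type (and
#'   one unit subtracted elsewhere).
#' @param markerBetaLow,markerBetaHigh beta in the marker's own cell type /
#'   in all other cell types (methylation markers are hypomethylated in their
#'   cell type).
#' @param nDegPerGroup,degLog2FC spiked expression effects per non-baseline
#'   group and their nominal log2 fold change.
#' @param nDmpPerGroup,dmpDelta spiked methylation effects per non-baseline
#'   group and their nominal delta beta. DMP features are laid out in blocks
#'   of three consecutive features so that, once positions are assigned, true
#'   effects form mergeable regions.
#' @param effectCellTypes named list: which cell types may carry effects in
#'   each non-baseline group.
#' @return list of class \code{ProfileConfig}.
#' @export
profileConfig <- function(
    cellTypes = c("AM", "NG", "EO", "LY", "MO", "CC", "SC"),
    groups = c("control", "asthma", "copd"),
    exprLog2Range = c(6, 12), exprCellTypeSd = 1, dynRange = c(1, 65536),
    betaJitterSd = 0.08,
    markersPerType = 25, markerTypes = c("AM", "NG", "EO"),
    markerLog2Boost = 3, markerBetaLow = 0.1, markerBetaHigh = 0.85,
    nDegPerGroup = 51, degLog2FC = 1.5,
    nDmpPerGroup = 51, dmpDelta = 0.2,
    effectCellTypes = list(asthma = c("AM", "NG", "EO"),
                           copd = c("AM", "NG"))) {
  structure(as.list(environment()), class = "ProfileConfig")
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate latent cell-type profiles with known truth
#'
#' Draws, per cell type and per group, linear-scale expression and
#' methylation-beta profiles. The baseline group carries no effects;
#' non-baseline groups receive spiked effects (random sign) on configured
#' cell types. Any effect that would push a beta value outside [0,1] or an
#' expression value outside the dynamic range is clipped and the achieved
#' (post-clip) effect recorded in the truth table.
#'
#' @param nFeatures features per modality.
#' @param config a \code{\link{profileConfig}}.
#' @param seed optional integer seed.
#' @return list of class \code{CellTypeProfileTruth} with elements
#'   \code{cellTypes}, \code{groups}, \code{expression} / \code{methylation}
#'   (per group: cell types x features matrices), \code{markers},
#'   \code{effects} (truth table: feature, modality, group, cell_type,
#'   nominal, achieved, clipped), \code{dynRange}.
#' @export
generateProfiles <- function(nFeatures, config = profileConfig(),
                             seed = NULL) {
  if (nFeatures < 1) stop("nFeatures must be >= 1")
  ct <- config$cellTypes
  k <- length(ct)
  withSeed(seed, {
    exprIds <- sprintf("p%05d", seq_len(nFeatures))
    methIds <- sprintf("cg%05d", seq_len(nFeatures))

    baseLog2 <- stats::runif(nFeatures, config$exprLog2Range[1L],
                             config$exprLog2Range[2L])
    exprBase <- matrix(
      baseLog2, k, nFeatures, byrow = TRUE,
      dimnames = list(ct, exprIds)
    ) + matrix(stats::rnorm(k * nFeatures, 0, config$exprCellTypeSd),
               k, nFeatures)

    baseBeta <- .clip(stats::rbeta(nFeatures, 0.5, 0.5), 0.02, 0.98)
    methBase <- .clip(matrix(
      baseBeta, k, nFeatures, byrow = TRUE,
      dimnames = list(ct, methIds)
    ) + matrix(stats::rnorm(k * nFeatures, 0, config$betaJitterSd),
               k, nFeatures), 0.001, 0.999)

    # marker features: strongly cell-type-specific in both modalities
    nMarkTotal <- config$markersPerType * length(config$markerTypes)
    markIdx <- seq_len(min(nMarkTotal, nFeatures))
    markType <- rep(config$markerTypes, each = config$markersPerType)[markIdx]
    for (i in seq_along(markIdx)) {
      f <- markIdx[i]
      exprBase[, f] <- exprBase[, f] - 1
      exprBase[markType[i], f] <- baseLog2[f] + config$markerLog2Boost
      methBase[, f] <- config$markerBetaHigh
      methBase[markType[i], f] <- config$markerBetaLow
    }
    markers <- data.frame(
      feature = c(exprIds[markIdx], methIds[markIdx]),
      modality = rep(c("expression", "methylation"),
                     each = length(markIdx)),
      cell_type = rep(markType, 2L), stringsAsFactors = FALSE
    )

    dyn <- config$dynRange
    exprCtrl <- .clip(2^exprBase, dyn[1L], dyn[2L])
    methCtrl <- methBase

    baseline <- config$groups[1L]
    expression <- stats::setNames(
      rep(list(exprCtrl), length(config$groups)), config$groups)
    methylation <- stats::setNames(
      rep(list(methCtrl), length(config$groups)), config$groups)

    # spiked group effects on non-marker features; DMPs in blocks of 3
    free <- setdiff(seq_len(nFeatures), markIdx)
    effects <- list()
    for (g in setdiff(config$groups, baseline)) {
      gTypes <- config$effectCellTypes[[g]]
      if (is.null(gTypes)) next
      nDeg <- min(config$nDegPerGroup, length(free))
      degIdx <- sort(sample(free, nDeg))
      free <- setdiff(free, degIdx)
      degCt <- sample(gTypes, nDeg, replace = TRUE)
      degSign <- sample(c(-1, 1), nDeg, replace = TRUE)
      em <- expression[[g]]
      for (i in seq_len(nDeg)) {
        f <- degIdx[i]
        old <- em[degCt[i], f]
        newv <- .clip(old * 2^(degSign[i] * config$degLog2FC),
                      dyn[1L], dyn[2L])
        em[degCt[i], f] <- newv
        effects[[length(effects) + 1L]] <- data.frame(
          feature = exprIds[f], modality = "expression", group = g,
          cell_type = degCt[i],
          nominal = degSign[i] * config$degLog2FC,
          achieved = log2(newv / old),
          clipped = abs(log2(newv / old) -
                          degSign[i] * config$degLog2FC) > 1e-12,
          stringsAsFactors = FALSE
        )
      }
      expression[[g]] <- em

      # greedy non-overlapping triples of consecutive free indices
      nBlocks <- ceiling(min(config$nDmpPerGroup, length(free)) / 3)
      blockStarts <- integer(0)
      avail <- free
      while (length(blockStarts) < nBlocks && length(avail) >= 3L) {
        hit <- which(avail %in% (avail[1L] + 0:2))
        if (length(hit) == 3L) {
          blockStarts <- c(blockStarts, avail[1L])
          avail <- avail[-hit]
        } else {
          avail <- avail[-1L]
        }
      }
      mm <- methylation[[g]]
      usedDmp <- integer(0)
      for (b in blockStarts) {
        bct <- sample(gTypes, 1L)
        bsign <- sample(c(-1, 1), 1L)
        for (f in b:(b + 2L)) {
          old <- mm[bct, f]
          newv <- .clip(old + bsign * config$dmpDelta, 0.001, 0.999)
          mm[bct, f] <- newv
          effects[[length(effects) + 1L]] <- data.frame(
            feature = methIds[f], modality = "methylation", group = g,
            cell_type = bct, nominal = bsign * config$dmpDelta,
            achieved = newv - old,
            clipped = abs((newv - old) - bsign * config$dmpDelta) > 1e-12,
            stringsAsFactors = FALSE
          )
          usedDmp <- c(usedDmp, f)
        }
      }
      methylation[[g]] <- mm
      free <- setdiff(free, usedDmp)
    }
    effects <- if (length(effects)) {
      do.call(rbind, effects)
    } else {
      data.frame(feature = character(), modality = character(),
                 group = character(), cell_type = character(),
                 nominal = numeric(), achieved = numeric(),
                 clipped = logical(), stringsAsFactors = FALSE)
    }

    structure(list(
      cellTypes = ct, groups = config$groups, baseline = baseline,
      expression = expression, methylation = methylation,
      markers = markers, effects = effects, dynRange = dyn,
      exprIds = exprIds, methIds = methIds, config = config
    ), class = "CellTypeProfileTruth")
  })
}

#' Mix cell-type profiles into observed matrices
#'
#' The generative counterpart of the deconvolution model: each observed
#' feature value is \code{sum_c (fraction_c / 100) * profile_c} for the
#' sample's group, plus Gaussian noise, clipped to the valid range
#' (methylation [0,1]; expression to the dynamic range). Clipping events are
#' counted and reported.
#'
#' @param profiles a \code{\link{generateProfiles}} truth object.
#' @param fractions cell-count table (\code{\link{generateCellFractions}},
#'   possibly row-bound across groups) with a \code{group} column and one
#'   percentage column per cell type.
#' @param noiseSd named numeric: Gaussian noise SD per modality
#'   (\code{expression} on the linear scale, \code{methylation} in beta
#'   units).
#' @param seed optional integer seed.
#' @return list with \code{expression} and \code{methylation}
#'   (\linkS4class{MixedOmicsExperiment}s, features x samples) and
#'   \code{clipCounts}.
#' @export
mixProfiles <- function(profiles, fractions,
                        noiseSd = c(expression = 25, methylation = 0.02),
                        seed = NULL) {
  ct <- profiles$cellTypes
  if (!all(ct %in% colnames(fractions))) {
    stop("cell-type labels of profiles and fractions do not match")
  }
  FF <- as.matrix(fractions[, ct]) / 100
  if (any(abs(rowSums(FF) - 1) > 1e-6)) {
    stop("fraction rows must sum to 100%")
  }
  grp <- fractions$group
  if (!all(grp %in% names(profiles$expression))) {
    stop("fraction table contains groups absent from the profiles")
  }
  withSeed(seed, {
    mixOne <- function(profList, ids, lo, hi, sd) {
      n <- nrow(FF)
      out <- matrix(NA_real_, length(ids), n,
                    dimnames = list(ids, fractions$sample_id))
      for (g in unique(grp)) {
        rows <- which(grp == g)
        out[, rows] <- t(FF[rows, , drop = FALSE] %*% profList[[g]])
      }
      if (sd > 0) out <- out + stats::rnorm(length(out), 0, sd)
      clipped <- sum(out < lo | out > hi)
      list(m = .clip(out, lo, hi), clipped = clipped)
    }
    ex <- mixOne(profiles$expression, profiles$exprIds,
                 profiles$dynRange[1L], profiles$dynRange[2L],
                 noiseSd[["expression"]])
    me <- mixOne(profiles$methylation, profiles$methIds, 0, 1,
                 noiseSd[["methylation"]])
    sampleData <- fractions[, c("sample_id", "group")]
    list(
      expression = MixedOmicsExperiment(ex$m, "expression-linear",
                                        sampleData = sampleData,
                                        dynRange = profiles$dynRange),
      methylation = MixedOmicsExperiment(me$m, "methylation-beta",
                                         sampleData = sampleData),
      clipCounts = c(expression = ex$clipped, methylation = me$clipped)
    )
  })
}

#' Apply RIN-dependent degradation to a linear expression matrix
#'
#' Each probe p in sample s is attenuated to
#' \code{value * 2^(-lambda_p * (rinRef - RIN_s))}, floored at the lower end
#' of the dynamic range. Samples at \code{rinRef} are unchanged, as are
#' probes with \code{lambda_p = 0}. With heterogeneous lambda, rank-based
#' quantile normalization of the degraded matrix later induces the
#' characteristic sign-mixed probe-RIN correlation spectrum.
#'
#' @param expr \linkS4class{MixedOmicsExperiment}, modality
#'   \code{"expression-linear"}.
#' @param rin numeric, one RIN per sample (column).
#' @param model a \code{\link{degradationModel}}.
#' @param seed optional integer seed (used when \code{lambda} is drawn).
#' @param lambda optional per-probe decay rates (all >= 0); drawn from the
#'   model when \code{NULL}.
#' @return the degraded \code{MixedOmicsExperiment}; the lambda truth is in
#'   \code{metadata(.)$lambda}.
#' @export
injectDegradation <- function(expr, rin, model = degradationModel(),
                              seed = NULL, lambda = NULL) {
  stopifnot(is(expr, "MixedOmicsExperiment"))
  if (modality(expr) != "expression-linear") {
    stop("degradation acts on the linear expression scale")
  }
  m <- omicsMatrix(expr)
  if (length(rin) != ncol(m)) stop("one RIN per sample required")
  withSeed(seed, {
    if (is.null(lambda)) {
      sus <- stats::runif(nrow(m)) < model$susceptibleFraction
      lambda <- ifelse(
        sus & model$lambdaMean > 0,
        stats::rexp(nrow(m), rate = 1 / model$lambdaMean), 0
      )
    }
    if (any(lambda < 0)) stop("negative decay rates are not allowed")
    att <- outer(lambda, model$rinRef - rin, function(l, d) 2^(-l * d))
    lo <- metadata(expr)$dynRange[1L]
    if (is.null(lo)) lo <- 0
    out <- pmax(m * att, lo)
    res <- .replaceAssay(expr, out)
    metadata(res)$lambda <- stats::setNames(lambda, rownames(m))
    metadata(res)$rinRef <- model$rinRef
    res
  })
}

# swap the assay of a MixedOmicsExperiment, keeping everything else
.replaceAssay <- function(x, newValues) {
  SummarizedExperiment::assay(x, 1L, withDimnames = FALSE) <- newValues
  x
}
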