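#' Configuration of the synthetic sputum study
#'
#' Bundles every parameter of the end-to-end synthetic scenario: group sizes,
#' fraction and degradation models, profile generator settings, mixing noise,
#' the group-to-preservation split (COPD samples are preferentially
#' HOPE-preserved, confounding degradation with group, as in the motivating
#' cohort; set \code{confoundPreservation = FALSE} for a balanced split), and
#' the synthetic genome annotation (CpG layout, probe flags, gene models,
#' gene sets).
#'
#' @param nPerGroup named integer: samples per group.
#' @param nFeatures features per modality.
#' @param noiseSd mixing noise SD per modality (expression: linear scale;
#'   methylation: beta units).
#' @param fractionModel a \code{\link{sputumFractionModel}}.
#' @param degradation a \code{\link{degradationModel}}.
#' @param profile a \code{\link{profileConfig}}.
#' @param preservationSplit named list: per group, counts of RLT / HOPE
#'   samples (must sum to the group size). \code{NULL} derives counts from
#'   the motivating cohort's proportions (RLT fraction about 0.6 asthma,
#'   0.3 COPD, 0.7 controls). Used when \code{confoundPreservation} is
#'   \code{TRUE}.
#' @param confoundPreservation keep the group-preservation confounding of the
#'   motivating cohort (\code{TRUE}) or assign preservation in a balanced
#'   alternating fashion (\code{FALSE}).
#' @param minRin intake threshold: samples below are rejected by
#'   \code{\link{validateInputs}} / the pipeline.
#' @param cpgSpacing genomic spacing (bp) between consecutive CpGs.
#' @param fracChrX,fracChrY fraction of CpGs placed on sex chromosomes.
#' @param fracSnp,fracCross fraction of CpGs flagged SNP-affected /
#'   cross-reactive.
#' @param fracDetectionFail fraction of CpGs given a failing detection p in
#'   one sample.
#' @param fracControlProbes fraction of expression probes marked as controls.
#' @param nBadProbes probes planted per expression flag rule (non-uniform,
#'   saturated, population outlier; each on a single array).
#' @param nLowFound probes planted to fail the 50\%-found rule in all groups.
#' @param foundRate per-cell probability that a regular probe is found and
#'   positive-and-significant on an array.
#' @param nReplicatePairs expression probes duplicated as technical
#'   replicates (averaged back to probe level during preprocessing).
#' @param genesPerWindow CpGs per synthetic gene body.
#' @param nGeneSets,geneSetSize random gene sets in the synthetic GMT.
#' @return list of class \code{StudyConfig}.
#' @export
sputumStudyConfig <- function(
    nPerGroup = c(asthma = 10, copd = 10, control = 10),
    nFeatures = 2000,
    noiseSd = c(expression = 25, methylation = 0.02),
    fractionModel = sputumFractionModel(),
    degradation = degradationModel(),
    profile = profileConfig(),
    preservationSplit = NULL,
    confoundPreservation = TRUE,
    minRin = 3,
    cpgSpacing = 500, fracChrX = 0.03, fracChrY = 0.01,
    fracSnp = 0.02, fracCross = 0.01, fracDetectionFail = 0.01,
    fracControlProbes = 0.02, nBadProbes = 15, nLowFound = 30,
    foundRate = 0.97, nReplicatePairs = 25,
    genesPerWindow = 10, nGeneSets = 20, geneSetSize = 25) {
  structure(as.list(environment()), class = "StudyConfig")
}

#' Simulate a complete synthetic sputum study
#'
#' Generates, under one seed, everything the analysis pipeline consumes:
#' differential cell counts, per-sample RIN and preservation, latent
#' cell-type profiles with spiked group effects, mixed-cell expression
#' (RIN-degraded, with replicate probes and Agilent-style probe flags) and
#' methylation matrices, CpG annotation with planted filter truth, synthetic
#' gene models tiling the CpG layout, and gene sets including one set
#' enriched for true DMR genes. All planted truths are returned so that
#' every downstream stage can be validated.
#'
#' @param config a \code{\link{sputumStudyConfig}}.
#' @param seed integer seed; the full study is a deterministic function of
#'   (config, seed).
#' @return list of class \code{SputumStudy}; see Details.
#' @details Components: \code{fractions}, \code{samples} (sample_id, group,
#'   rin, preservation), \code{profiles} (truth), \code{expression}
#'   (degraded, linear), \code{expressionClean} (pre-degradation),
#'   \code{methylation}, \code{lambda}, \code{probeFlags},
#'   \code{replicateGroups}, \code{cpgAnnotation}, \code{detectionP},
#'   \code{genes}, \code{probeGeneMap}, \code{geneSets}, \code{plantedCounts},
#'   \code{clipCounts}, \code{config}, \code{seed}.
#' @examples
#' study <- simulateSputumStudy(sputumStudyConfig(
#'   nPerGroup = c(asthma = 4, copd = 4, control = 4), nFeatures = 200),
#'   seed = 1)
#' study$samples[1:3, ]
#' @export
simulateSputumStudy <- function(config = sputumStudyConfig(), seed = 1) {
  withSeed(seed, {
    groups <- names(config$nPerGroup)

    fractions <- do.call(rbind, lapply(groups, function(g) {
      generateCellFractions(g, config$nPerGroup[[g]],
                            model = config$fractionModel)
    }))

    # preservation and RIN, optionally confounded with group
    pres <- unlist(lapply(groups, function(g) {
      n <- config$nPerGroup[[g]]
      if (isTRUE(config$confoundPreservation)) {
        sp <- config$preservationSplit[[g]]
        if (is.null(sp)) {
          rltFrac <- unname(c(asthma = 0.6, copd = 0.3, control = 0.7)[g])
          if (is.na(rltFrac)) rltFrac <- 0.5
          nr <- round(rltFrac * n)
          sp <- c(RLT = nr, HOPE = n - nr)
        }
        if (sum(sp) != n) stop("preservation split must sum to group size")
        rep(names(sp), sp)
      } else {
        rep(c("RLT", "HOPE"), length.out = n)
      }
    }))
    rin <- numeric(length(pres))
    for (p in unique(pres)) {
      idx <- which(pres == p)
      rin[idx] <- generateRIN(p, length(idx), model = config$degradation)
    }
    samples <- data.frame(
      sample_id = fractions$sample_id, group = fractions$group,
      rin = rin, preservation = pres, stringsAsFactors = FALSE
    )

    profiles <- generateProfiles(config$nFeatures, config = config$profile)
    mixed <- mixProfiles(profiles, fractions, noiseSd = config$noiseSd)

    expr <- mixed$expression
    colData(expr)$rin <- rin
    colData(expr)$preservation <- pres
    meth <- mixed$methylation
    colData(meth)$rin <- rin
    colData(meth)$preservation <- pres

    # technical replicate probes: duplicate rows with extra jitter
    exprM <- omicsMatrix(expr)
    nRep <- min(config$nReplicatePairs, nrow(exprM))
    effExpr <- unique(profiles$effects$feature[
      profiles$effects$modality == "expression"])
    repCand <- setdiff(rownames(exprM), c(effExpr, profiles$markers$feature))
    repBase <- sort(sample(repCand, nRep))
    dup <- exprM[repBase, , drop = FALSE] +
      stats::rnorm(nRep * ncol(exprM), 0, config$noiseSd[["expression"]])
    dup <- .clip(dup, profiles$dynRange[1L], profiles$dynRange[2L])
    rownames(dup) <- paste0(repBase, "_r2")
    exprAll <- rbind(exprM, dup)
    replicateGroups <- stats::setNames(
      c(rownames(exprM), repBase), rownames(exprAll))

    sampleData <- data.frame(samples, check.names = FALSE)
    exprFull <- MixedOmicsExperiment(exprAll, "expression-linear",
                                     sampleData = sampleData,
                                     dynRange = profiles$dynRange)
    degraded <- injectDegradation(exprFull, rin, model = config$degradation)

    flags <- .plantProbeFlags(rownames(exprAll), samples, profiles, config)
    ann <- .plantCpgAnnotation(profiles, samples, config)
    geneAnn <- .tileGenes(ann$annotation, config)
    geneSets <- .makeGeneSets(geneAnn, profiles, ann$annotation, config)

    probeGeneMap <- data.frame(
      probe_id = rownames(exprM),
      gene_id = geneAnn$gene_id[(seq_len(nrow(exprM)) - 1L) %%
                                  nrow(geneAnn) + 1L],
      stringsAsFactors = FALSE
    )

    structure(list(
      fractions = fractions, samples = samples, profiles = profiles,
      expression = degraded, expressionClean = exprFull,
      methylation = meth,
      lambda = metadata(degraded)$lambda,
      probeFlags = flags$flags, replicateGroups = replicateGroups,
      cpgAnnotation = ann$annotation, detectionP = ann$detectionP,
      genes = geneAnn, probeGeneMap = probeGeneMap, geneSets = geneSets,
      plantedCounts = c(flags$planted, ann$planted),
      clipCounts = mixed$clipCounts,
      config = config, seed = seed
    ), class = "SputumStudy")
  })
}

# Agilent-style flag truth with planted per-rule drop sets (disjoint).
.plantProbeFlags <- function(probeIds, samples, profiles, config) {
  n <- length(probeIds)
  ns <- nrow(samples)
  protected <- unique(c(
    profiles$effects$feature[profiles$effects$modality == "expression"],
    profiles$markers$feature[profiles$markers$modality == "expression"]
  ))
  pool <- setdiff(probeIds, protected)
  take <- function(k) {
    k <- min(k, length(pool))
    out <- sample(pool, k)
    pool <<- setdiff(pool, out)
    out
  }
  ctrl <- take(round(config$fracControlProbes * n))
  nonUni <- take(config$nBadProbes)
  satur <- take(config$nBadProbes)
  outlier <- take(config$nBadProbes)
  lowFound <- take(config$nLowFound)

  mk <- function() matrix(TRUE, n, ns, dimnames = list(probeIds,
                                                       samples$sample_id))
  found <- matrix(stats::runif(n * ns) < config$foundRate, n, ns,
                  dimnames = list(probeIds, samples$sample_id))
  posSig <- matrix(stats::runif(n * ns) < config$foundRate, n, ns,
                   dimnames = list(probeIds, samples$sample_id))
  # planted low-found probes fail the 50% rule in every group
  found[lowFound, ] <- FALSE
  nonUniform <- !mk(); saturated <- !mk(); popOutlier <- !mk()
  arr <- sample.int(ns, length(nonUni), replace = TRUE)
  nonUniform[cbind(match(nonUni, probeIds), arr)] <- TRUE
  arr <- sample.int(ns, length(satur), replace = TRUE)
  saturated[cbind(match(satur, probeIds), arr)] <- TRUE
  arr <- sample.int(ns, length(outlier), replace = TRUE)
  popOutlier[cbind(match(outlier, probeIds), arr)] <- TRUE

  list(
    flags = list(
      found = found, positiveAndSignificant = posSig,
      nonUniform = nonUniform, saturated = saturated,
      popOutlier = popOutlier,
      isControl = stats::setNames(probeIds %in% ctrl, probeIds)
    ),
    planted = c(expr_control = length(ctrl), expr_non_uniform = length(nonUni),
                expr_saturated = length(satur), expr_outlier = length(outlier),
                expr_low_found = length(lowFound))
  )
}

# CpG genomic layout and filter truth. Effect CpGs stay autosomal/unflagged.
.plantCpgAnnotation <- function(profiles, samples, config) {
  ids <- profiles$methIds
  n <- length(ids)
  effMeth <- unique(profiles$effects$feature[
    profiles$effects$modality == "methylation"])
  pool <- setdiff(ids, effMeth)
  take <- function(k) {
    k <- min(k, length(pool))
    out <- sample(pool, k)
    pool <<- setdiff(pool, out)
    out
  }
  xIds <- take(round(config$fracChrX * n))
  yIds <- take(round(config$fracChrY * n))
  snpIds <- take(round(config$fracSnp * n))
  crossIds <- take(round(config$fracCross * n))
  detIds <- take(round(config$fracDetectionFail * n))

  autosomal <- setdiff(ids, c(xIds, yIds))
  nChrom <- 22L
  perChrom <- ceiling(length(autosomal) / nChrom)
  chromIdx <- rep(seq_len(nChrom), each = perChrom)[seq_along(autosomal)]
  chrom <- stats::setNames(rep(NA_character_, n), ids)
  pos <- stats::setNames(rep(NA_real_, n), ids)
  chrom[autosomal] <- paste0("chr", chromIdx)
  pos[autosomal] <- 10000 + config$cpgSpacing *
    (stats::ave(seq_along(autosomal), chromIdx, FUN = seq_along) - 1)
  chrom[xIds] <- "chrX"
  pos[xIds] <- 10000 + config$cpgSpacing * (seq_along(xIds) - 1)
  chrom[yIds] <- "chrY"
  pos[yIds] <- 10000 + config$cpgSpacing * (seq_along(yIds) - 1)

  detP <- matrix(stats::runif(n * nrow(samples), 0, 0.005), n, nrow(samples),
                 dimnames = list(ids, samples$sample_id))
  # one failing (probe, sample) cell per planted probe
  detP[cbind(match(detIds, ids),
             sample.int(nrow(samples), length(detIds), replace = TRUE))] <- 0.02

  list(
    annotation = data.frame(
      cpg_id = ids, chrom = chrom, pos = as.integer(pos),
      snp_affected = ids %in% snpIds, cross_reactive = ids %in% crossIds,
      stringsAsFactors = FALSE
    ),
    detectionP = detP,
    planted = c(meth_chrX = length(xIds), meth_chrY = length(yIds),
                meth_snp = length(snpIds), meth_cross = length(crossIds),
                meth_detection = length(detIds))
  )
}

# Non-overlapping gene bodies covering consecutive autosomal CpG windows.
.tileGenes <- function(annotation, config) {
  auto <- annotation[!annotation$chrom %in% c("chrX", "chrY"), ]
  auto <- auto[order(auto$chrom, auto$pos), ]
  genes <- do.call(rbind, lapply(split(auto, auto$chrom), function(a) {
    w <- config$genesPerWindow
    k <- floor(nrow(a) / w)
    if (k == 0L) return(NULL)
    idx <- seq_len(k * w)
    win <- rep(seq_len(k), each = w)
    data.frame(
      chrom = a$chrom[1L],
      start = tapply(a$pos[idx], win, min) - 100L,
      end = tapply(a$pos[idx], win, max) + 100L,
      stringsAsFactors = FALSE
    )
  }))
  rownames(genes) <- NULL
  genes <- genes[order(genes$chrom, genes$start), ]
  genes$gene_id <- sprintf("G%04d", seq_len(nrow(genes)))
  genes$strand <- rep(c("+", "-"), length.out = nrow(genes))
  genes[, c("gene_id", "chrom", "start", "end", "strand")]
}

# Random gene sets plus one set seeded with true asthma DMR genes.
.makeGeneSets <- function(genes, profiles, annotation, config) {
  universe <- genes$gene_id
  sets <- lapply(seq_len(config$nGeneSets), function(i) {
    sample(universe, min(config$geneSetSize, length(universe)))
  })
  names(sets) <- sprintf("SET%02d", seq_len(config$nGeneSets))
  effCpg <- profiles$effects[profiles$effects$modality == "methylation" &
                               profiles$effects$group == "asthma", "feature"]
  ann <- annotation[match(unique(effCpg), annotation$cpg_id), ]
  ann <- ann[!is.na(ann$pos), ]
  hitGenes <- unique(unlist(lapply(seq_len(nrow(ann)), function(i) {
    g <- genes[genes$chrom == ann$chrom[i] & genes$start <= ann$pos[i] &
                 genes$end >= ann$pos[i], "gene_id"]
    g
  })))
  avail <- setdiff(universe, hitGenes)
  pad <- sample(avail, min(length(avail),
                           max(0, config$geneSetSize - length(hitGenes))))
  sets[["SPIKED_ASTHMA_DMR"]] <- unique(c(hitGenes, pad))
  list(sets = sets, universe = universe)
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Emits TSV matrices (full double precision, so re-reading reproduces the
#' matrices exactly), the cell-count and sample tables, truth tables, gene
#' models, a GMT of gene sets and a \code{config.yaml} holding scalar
#' configuration plus the seed - sufficient to regenerate the study
#' bit-identically with \code{\link{simulateSputumStudy}}.
#'
#' @param study a \code{\link{simulateSputumStudy}} result.
#' @param outDir output directory.
#' @param overwrite refuse to write into an existing directory unless
#'   \code{TRUE}.
#' @return \code{outDir}, invisibly.
#' @export
writeDataset <- function(study, outDir, overwrite = FALSE) {
  if (dir.exists(outDir) && !overwrite) {
    stop(sprintf("directory '%s' exists; set overwrite = TRUE", outDir))
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(
    df, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  writeMatrixTSV(omicsMatrix(study$expression),
                 file.path(outDir, "expression.tsv"), "probe_id")
  writeMatrixTSV(omicsMatrix(study$methylation),
                 file.path(outDir, "methylation.tsv"), "cpg_id")
  wt(study$fractions, "cell_counts.tsv")
  wt(study$samples, "samples.tsv")
  wt(study$cpgAnnotation, "cpg_annotation.tsv")
  writeMatrixTSV(study$detectionP, file.path(outDir, "detection_p.tsv"),
                 "cpg_id")
  wt(study$genes, "genes.tsv")
  wt(study$probeGeneMap, "probe_gene_map.tsv")
  wt(study$profiles$effects, "truth_effects.tsv")

  truthProf <- do.call(rbind, lapply(study$profiles$groups, function(g) {
    rbind(
      data.frame(group = g, modality = "expression",
                 cell_type = rep(study$profiles$cellTypes,
                                 times = length(study$profiles$exprIds)),
                 feature = rep(study$profiles$exprIds,
                               each = length(study$profiles$cellTypes)),
                 value = as.vector(study$profiles$expression[[g]]),
                 stringsAsFactors = FALSE),
      data.frame(group = g, modality = "methylation",
                 cell_type = rep(study$profiles$cellTypes,
                                 times = length(study$profiles$methIds)),
                 feature = rep(study$profiles$methIds,
                               each = length(study$profiles$cellTypes)),
                 value = as.vector(study$profiles$methylation[[g]]),
                 stringsAsFactors = FALSE)
    )
  }))
  wt(truthProf, "truth_profiles.tsv")

  gmt <- vapply(names(study$geneSets$sets), function(nm) {
    paste(c(nm, "synthetic", study$geneSets$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(gmt, file.path(outDir, "gene_sets.gmt"))

  cfg <- study$config
  scalarCfg <- list(
    nPerGroup = as.list(cfg$nPerGroup),
    nFeatures = cfg$nFeatures,
    noiseSd = as.list(cfg$noiseSd),
    confoundPreservation = cfg$confoundPreservation,
    minRin = cfg$minRin, seed = study$seed
  )
  yaml::write_yaml(scalarCfg, file.path(outDir, "config.yaml"))
  invisible(outDir)
}
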