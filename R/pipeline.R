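#' Read a pipeline run configuration
#'
#' YAML with the scenario and analysis parameters; see the packaged
#' \code{demo.yaml} (\code{system.file("extdata", "demo.yaml",
#' package = "sputodeconv")}) for the committed demo scenario reproducing
#' the synthetic asthma/COPD/control study.
#'
#' @param path YAML file.
#' @return named list of class \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    seed = 1L, n_per_group = list(asthma = 10, copd = 10, control = 10),
    n_features = 2000,
    noise_sd = list(expression = 25, methylation = 0.02),
    confound_preservation = TRUE, min_rin = 3,
    rin_correction = "linear", r_threshold = NULL,
    majors = list(asthma = c("AM", "NG", "EO"), copd = c("AM", "NG"),
                  control = c("AM", "NG")),
    exclude = "MO", bounds = "auto",
    dmr_max_gap = 1000, dmr_min_cpgs = 2,
    enrich_p = 0.1, enrich_q = 0.2
  )
  cfg <- utils::modifyList(defaults, cfg)
  structure(cfg, class = c("RunConfig", "list"))
}

# study config implied by a run config
.studyConfigFrom <- function(cfg) {
  sputumStudyConfig(
    nPerGroup = unlist(cfg$n_per_group),
    nFeatures = cfg$n_features,
    noiseSd = unlist(cfg$noise_sd),
    confoundPreservation = isTRUE(cfg$confound_preservation),
    minRin = cfg$min_rin
  )
}

#' Validate pipeline inputs
#'
#' Report-only consistency checks of a simulated (or ingested) study against
#' a run configuration: matrix/sample/count alignment, fraction-row sums,
#' the RIN intake threshold, and modality tags.
#'
#' @param study a \code{\link{simulateSputumStudy}} result.
#' @param config a \code{\link{readRunConfig}} result (or NULL for the
#'   defaults).
#' @return data.frame of violations (zero rows when everything aligns).
#' @export
validateInputs <- function(study, config = NULL) {
  minRin <- if (is.null(config)) study$config$minRin else config$min_rin
  v <- list()
  add <- function(check, item, detail) {
    v[[length(v) + 1L]] <<- data.frame(check = check, item = item,
                                       detail = detail,
                                       stringsAsFactors = FALSE)
  }
  sExpr <- colnames(study$expression)
  sCounts <- study$fractions$sample_id
  for (miss in setdiff(sExpr, sCounts)) {
    add("counts_alignment", miss, "sample missing from cell counts")
  }
  for (miss in setdiff(sCounts, sExpr)) {
    add("matrix_alignment", miss, "counted sample missing from matrix")
  }
  ct <- study$profiles$cellTypes
  sums <- rowSums(study$fractions[, ct])
  for (i in which(abs(sums - 100) > 1e-6)) {
    add("fraction_sum", sCounts[i],
        sprintf("fractions sum to %.3f%%", sums[i]))
  }
  for (i in which(study$samples$rin < minRin)) {
    add("rin_intake", study$samples$sample_id[i],
        sprintf("RIN %.2f below intake threshold %g",
                study$samples$rin[i], minRin))
  }
  if (modality(study$expression) != "expression-linear") {
    add("modality", "expression", "expected expression-linear")
  }
  if (modality(study$methylation) != "methylation-beta") {
    add("modality", "methylation", "expected methylation-beta")
  }
  if (length(v)) {
    do.call(rbind, v)
  } else {
    data.frame(check = character(), item = character(),
               detail = character(), stringsAsFactors = FALSE)
  }
}

#' Run the full sputum-omics analysis pipeline
#'
#' Executes, from one configuration and seed: (1) synthetic-study generation
#' (including writing the dataset), (2) preprocessing (expression quantile
#' normalization, flag filtering and replicate averaging; methylation CpG
#' filtering), (3) RIN correction of log2 expression (linear-model mode by
#' default), (4) group-wise QP deconvolution of both modalities, (5)
#' differential analysis (mixed-cell and deconvolved, disease vs control),
#' and (6) DMP merging, region-gene mapping, DMR/DEG intersection and
#' gene-set enrichment. Every stage's outputs are written under
#' \code{outDir}, and \code{manifest.json} records the configuration hash,
#' seed, per-stage row counts and the MD5 of every output file, so two runs
#' with identical config and seed produce bit-identical manifests.
#'
#' @param config path to a YAML run configuration, or a \code{RunConfig}.
#' @param outDir output directory (created; must not exist unless
#'   \code{overwrite}).
#' @param overwrite allow writing into an existing directory.
#' @return the manifest, invisibly (also written as \code{manifest.json}).
#' @export
runPipeline <- function(config, outDir, overwrite = FALSE) {
  cfg <- if (is.character(config)) readRunConfig(config) else config
  if (dir.exists(outDir) && !overwrite) {
    stop(sprintf("directory '%s' exists; set overwrite = TRUE", outDir))
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  wt <- function(df, f) {
    utils::write.table(df, file.path(outDir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  }

  # 1 - simulate
  study <- simulateSputumStudy(.studyConfigFrom(cfg), seed = cfg$seed)
  writeDataset(study, file.path(outDir, "dataset"), overwrite = TRUE)
  viol <- validateInputs(study, cfg)
  if (nrow(viol)) {
    wt(viol, "validation.tsv")
    stop("input validation failed; see validation.tsv")
  }
  stages$simulate <- c(samples = nrow(study$samples),
                       features = study$config$nFeatures)

  # 2 - preprocess
  keepRin <- study$samples$rin >= cfg$min_rin
  exprRaw <- study$expression[, keepRin]
  samples <- study$samples[keepRin, ]
  fl <- filterExpressionProbes(
    lapply(study$probeFlags[c("found", "positiveAndSignificant",
                              "nonUniform", "saturated", "popOutlier")],
           function(m) m[, keepRin, drop = FALSE]) |>
      c(list(isControl = study$probeFlags$isControl)),
    samples$group
  )
  exprKept <- exprRaw[names(which(fl$keep)), ]
  exprQN <- quantileNormalize(exprKept)
  exprAvg <- averageReplicates(exprQN, study$replicateGroups)
  cpgF <- filterCpGs(study$detectionP, study$cpgAnnotation)
  methKept <- study$methylation[names(which(cpgF$keep)), ]
  stages$preprocess <- c(
    probes_kept = nrow(exprAvg), cpgs_kept = nrow(methKept),
    fl$dropCounts, cpgF$dropCounts
  )

  # 3 - RIN correction (log2 scale)
  log2m <- log2(pmax(omicsMatrix(exprAvg), 1e-6))
  if (identical(cfg$rin_correction, "filter")) {
    if (is.null(cfg$r_threshold)) {
      stop("correlation filtering requires an explicit r_threshold")
    }
    cf <- correlationFilter(log2m, samples$rin, cfg$r_threshold)
    corrected <- cf$filtered
    slopes <- NULL
  } else {
    lc <- linearCorrection(log2m, samples$rin)
    corrected <- lc$corrected
    slopes <- lc$slopes
    writeMatrixTSV(cbind(slope = slopes), file.path(outDir, "slopes.tsv"),
                   "probe_id")
  }
  writeMatrixTSV(corrected, file.path(outDir, "expression_corrected.tsv"),
                 "probe_id")
  pc <- pcaScores(corrected, 2)
  writeMatrixTSV(pc$scores, file.path(outDir, "pca_scores.tsv"), "sample_id")
  stages$rincorrect <- c(probes = nrow(corrected))

  # 4 - deconvolution per group, both modalities
  exprLin <- MixedOmicsExperiment(
    2^corrected, "expression-linear", sampleData = samples,
    dynRange = range(2^corrected)
  )
  counts <- study$fractions
  groups <- unique(samples$group)
  est <- list(expression = list(), methylation = list())
  for (g in groups) {
    majors <- unlist(cfg$majors[[g]])
    if (is.null(majors)) majors <- c("AM", "NG")
    gs <- samples$sample_id[samples$group == g]
    des <- buildDesign(counts[counts$sample_id %in% gs, ], majors,
                       excluded = cfg$exclude)
    est$expression[[g]] <- deconvolveGroup(
      exprLin[, gs], des, bounds = cfg$bounds, group = g)
    msLocal <- intersect(gs, colnames(study$methylation))
    est$methylation[[g]] <- deconvolveGroup(
      methKept[, msLocal], des, bounds = "auto", group = g)
    writeMatrixTSV(estimates(est$expression[[g]]),
                   file.path(outDir, sprintf("estimates_expr_%s.tsv", g)),
                   "probe_id")
    writeMatrixTSV(estimates(est$methylation[[g]]),
                   file.path(outDir, sprintf("estimates_meth_%s.tsv", g)),
                   "cpg_id")
  }
  stages$deconvolve <- c(groups = length(groups))

  # 5 - differential analysis: disease vs control
  diseaseGroups <- setdiff(groups, "control")
  diffTables <- list()
  for (g in diseaseGroups) {
    gs <- samples$sample_id[samples$group == g]
    cs <- samples$sample_id[samples$group == "control"]
    dm <- differentialFromSamples(corrected[, gs, drop = FALSE],
                                  corrected[, cs, drop = FALSE],
                                  "expression")
    diffTables[[paste0("mixed_expr_", g)]] <- dm
    mg <- omicsMatrix(methKept)
    dmm <- differentialFromSamples(mg[, gs, drop = FALSE],
                                   mg[, cs, drop = FALSE], "methylation")
    diffTables[[paste0("mixed_meth_", g)]] <- dmm
    # deconvolved comparisons need the cell type estimated in both groups
    for (ctName in intersect(
      intersect(unlist(cfg$majors[[g]]),
                colnames(estimates(est$expression[[g]]))),
      colnames(estimates(est$expression$control))
    )) {
      diffTables[[paste0("deconv_expr_", g, "_", ctName)]] <-
        differentialFromEstimates(est$expression[[g]],
                                  est$expression$control, ctName)
      diffTables[[paste0("deconv_meth_", g, "_", ctName)]] <-
        differentialFromEstimates(est$methylation[[g]],
                                  est$methylation$control, ctName)
    }
  }
  for (nm in names(diffTables)) {
    wt(diffTables[[nm]], sprintf("differential_%s.tsv", nm))
  }
  stages$differential <- vapply(diffTables, function(d) {
    sum(d$significant)
  }, numeric(1))

  # 6 - regions, mapping, intersection, enrichment (per disease group,
  #     deconvolved methylation pooled over its cell types)
  ann <- study$cpgAnnotation
  enrichment <- list()
  for (g in diseaseGroups) {
    dmpTabs <- diffTables[grepl(sprintf("^deconv_meth_%s_", g),
                                names(diffTables))]
    sig <- do.call(rbind, lapply(dmpTabs, function(d) {
      d[d$significant, c("feature", "effect")]
    }))
    regions <- if (!is.null(sig) && nrow(sig)) {
      sig <- sig[!duplicated(sig$feature), ]
      idx <- match(sig$feature, ann$cpg_id)
      mergeDmps(data.frame(
        cpg_id = sig$feature, chrom = ann$chrom[idx], pos = ann$pos[idx],
        delta_beta = sig$effect, stringsAsFactors = FALSE
      ), maxGap = cfg$dmr_max_gap, minCpgs = cfg$dmr_min_cpgs)
    } else {
      GRanges()
    }
    if (length(regions)) {
      writeRegionsBED(regions, file.path(outDir,
                                         sprintf("dmrs_%s.bed", g)))
      mapping <- mapRegionsToGenes(regions, study$genes)
      wt(mapping, sprintf("dmr_genes_%s.tsv", g))
      degTabs <- diffTables[grepl(sprintf("^deconv_expr_%s_", g),
                                  names(diffTables))]
      degProbes <- unique(unlist(lapply(degTabs, function(d) {
        d$feature[d$significant]
      })))
      degGenes <- study$probeGeneMap$gene_id[
        study$probeGeneMap$probe_id %in% degProbes]
      ov <- intersectDmrDeg(mapping$gene_id, degGenes)
      enr <- hypergeomEnrichment(unique(mapping$gene_id),
                                 study$geneSets$sets,
                                 study$geneSets$universe,
                                 cfg$enrich_p, cfg$enrich_q)
      wt(enr, sprintf("enrichment_%s.tsv", g))
      enrichment[[g]] <- c(regions = length(regions), ov$counts,
                           reported_sets = sum(enr$reported))
    } else {
      enrichment[[g]] <- c(regions = 0)
    }
  }
  stages$regions <- vapply(enrichment, function(x) x[["regions"]],
                           numeric(1))

  manifest <- list(
    config = unclass(cfg),
    config_hash = .md5String(cfg),
    seed = cfg$seed,
    stages = lapply(stages, as.list),
    files = .fileManifest(outDir)
  )
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  writeLines(json, file.path(outDir, "manifest.json"))
  invisible(manifest)
}

.md5String <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

# relative paths + md5 of every file under dir (excluding the manifest)
.fileManifest <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  md5 <- unname(tools::md5sum(file.path(dir, files)))
  stats::setNames(as.list(md5), files)
}
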