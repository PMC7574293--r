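# DMP merging, promoter/gene-body mapping, DMR/DEG intersection,
# hypergeometric enrichment, BED round trips.

test_that("mergeDmps applies the gap, size and delta-beta rules", {
  dmps <- data.frame(
    cpg_id = c("a", "b", "c"), chrom = "chr1",
    pos = c(100, 400, 5000), delta_beta = c(0.15, 0.12, 0.2)
  )
  gr <- mergeDmps(dmps, maxGap = 1000, minCpgs = 1)
  expect_equal(length(gr), 2L)
  expect_equal(GenomicRanges::start(gr), c(100, 5000))
  expect_equal(GenomicRanges::end(gr), c(400, 5000))
  expect_equal(S4Vectors::mcols(gr)$n_cpgs, c(2L, 1L))
  # a single CpG cannot form a region at minCpgs = 2
  expect_equal(length(mergeDmps(dmps[3, ], minCpgs = 2)), 0L)
  # a region whose max |delta beta| is 0.09 is dropped
  low <- data.frame(cpg_id = c("x", "y"), chrom = "chr2",
                    pos = c(10, 20), delta_beta = c(0.09, -0.05))
  expect_equal(length(mergeDmps(low)), 0L)
  # unsorted input is sorted with a message
  expect_message(mergeDmps(dmps[c(3, 1, 2), ]), "sort")
})

test_that("region-gene mapping enforces the 200 bp overlap on both strands", {
  genes <- data.frame(
    gene_id = c("plus", "minus"), chrom = "chr1",
    start = c(10001, 10001), end = c(20000, 20000),
    strand = c("+", "-"), stringsAsFactors = FALSE
  )
  # + strand: promoter covers the 1500 bp upstream of the body start
  regPlus <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(8601, 8900))
  names(regPlus) <- "R1"
  hitP <- mapRegionsToGenes(regPlus, genes[1, ])
  expect_equal(nrow(hitP), 1L)
  expect_equal(hitP$feature, "promoter")
  expect_equal(hitP$overlap, 300L)
  expect_equal(nrow(mapRegionsToGenes(regPlus, genes[1, ],
                                      minOverlap = 400)), 0L)
  # - strand: promoter lies downstream of the body end; a region spanning
  # the TSS overlaps the body by 100 and the promoter by 250
  regMinus <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(19901, 20250))
  names(regMinus) <- "R2"
  hitM <- mapRegionsToGenes(regMinus, genes[2, ], minOverlap = 200)
  expect_equal(nrow(hitM), 1L)
  expect_equal(hitM$feature, "promoter")
  expect_equal(hitM$overlap, 250L)
  hitM100 <- mapRegionsToGenes(regMinus, genes[2, ], minOverlap = 100)
  expect_setequal(hitM100$feature, c("promoter", "body"))
  expect_equal(hitM100$overlap[hitM100$feature == "body"], 100L)
})

test_that("mapping is symmetric under strand flip with mirrored coordinates", {
  L <- 30000L
  genes <- data.frame(gene_id = "g", chrom = "chr1",
                      start = 10001, end = 20000, strand = "+",
                      stringsAsFactors = FALSE)
  mirrored <- data.frame(gene_id = "g", chrom = "chr1",
                         start = L - 20000 + 1, end = L - 10001 + 1,
                         strand = "-", stringsAsFactors = FALSE)
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(8601, 8900))
  regMir <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(L - 8900 + 1, L - 8601 + 1))
  names(reg) <- names(regMir) <- "R"
  a <- mapRegionsToGenes(reg, genes)
  b <- mapRegionsToGenes(regMir, mirrored)
  expect_equal(a$feature, b$feature)
  expect_equal(a$overlap, b$overlap)
})

test_that("BED output is 0-based half-open and round-trips exactly", {
  gr <- GenomicRanges::GRanges(c("chr1", "chr2"),
                               IRanges::IRanges(c(100, 5000), c(400, 5000)))
  names(gr) <- c("DMR1", "DMR2")
  path <- tempfile(fileext = ".bed")
  writeRegionsBED(gr, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(bed$V2, c(99, 4999))  # starts shift by one, ends do not
  expect_equal(bed$V3, c(400, 5000))
  back <- readRegionsBED(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_identical(names(back), names(gr))
})

test_that("DMR/DEG intersection counts planted joint features", {
  expect_equal(intersectDmrDeg(c("a", "b"), c("c", "d"))$counts[["n_overlap"]],
               0L)
  expect_equal(length(intersectDmrDeg(letters[1:5], letters[1:5])$overlap),
               5L)
  study <- cachedStudy()
  eff <- study$profiles$effects
  effCpg <- unique(eff$feature[eff$modality == "methylation" &
                                 eff$group == "asthma"])
  ann <- study$cpgAnnotation
  idx <- match(effCpg, ann$cpg_id)
  dmrGenes <- unique(unlist(lapply(seq_along(effCpg), function(i) {
    g <- study$genes
    g$gene_id[g$chrom == ann$chrom[idx[i]] & g$start <= ann$pos[idx[i]] &
                g$end >= ann$pos[idx[i]]]
  })))
  spiked <- study$geneSets$sets[["SPIKED_ASTHMA_DMR"]]
  ov <- intersectDmrDeg(dmrGenes, spiked)
  expect_equal(ov$counts[["n_overlap"]], length(dmrGenes))
})

test_that("hypergeometric p values match exact enumeration", {
  # spot values
  expect_equal(
    hypergeomEnrichment(letters[1:5], list(s = letters[1:10]),
                        c(letters, LETTERS, paste0(letters, "2"),
                          paste0(LETTERS, "2"))[1:100])$p,
    hyperOracle(5, 10, 100, 5)
  )
  # k = 0 and saturation boundaries
  u <- sprintf("g%03d", 1:40)
  expect_equal(hypergeomEnrichment(u[1:5], list(s = u[30:40]), u)$p, 1)
  sat <- hypergeomEnrichment(u, list(s = u[1:10]), u)
  expect_equal(sat$p, 1)  # hits = universe draws every set member
  expect_error(hypergeomEnrichment("a", list(s = "a"), character(0)),
               "empty universe")

  # full enumeration for all configurations with N <= 30 (one comparison
  # per universe size keeps this fast)
  for (N in 2:30) {
    grid <- expand.grid(K = 1:N, n = 1:N)
    grid <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      data.frame(K = grid$K[i], n = grid$n[i],
                 k = 0:min(grid$K[i], grid$n[i]))
    }))
    pkg <- ifelse(grid$k == 0L, 1,
                  phyper(grid$k - 1, grid$K, N - grid$K, grid$n,
                         lower.tail = FALSE))
    oracle <- mapply(hyperOracle, grid$k, grid$K, N, grid$n)
    expect_equal(pkg, oracle, tolerance = 1e-12)
  }
})

test_that("the documented worked hypergeometric example reproduces", {
  u <- sprintf("g%03d", 1:100)
  set <- u[1:10]
  hits <- c(u[1:3], u[50:51])  # k = 3 of K = 10 with n = 5
  res <- hypergeomEnrichment(hits, list(s = set), u)
  expect_equal(res$p, 6.637e-3, tolerance = 1e-3)
  expect_equal(res$k, 3L)
})

test_that("enrichment is calibrated under a random-hit null", {
  set.seed(71)
  u <- sprintf("g%04d", 1:500)
  sets <- lapply(1:10, function(i) sample(u, 40))
  names(sets) <- sprintf("S%02d", 1:10)
  pvals <- unlist(lapply(1:100, function(i) {
    hypergeomEnrichment(sample(u, 50), sets, u)$p
  }))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.02)
})

test_that("GMT files round-trip through readGmt", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tg1\tg2\tg3", "SETB\tdesc\tg2\tg4"), path)
  sets <- readGmt(path)
  expect_identical(sets, list(SETA = c("g1", "g2", "g3"),
                              SETB = c("g2", "g4")))
})
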