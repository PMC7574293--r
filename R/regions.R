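#' @importFrom GenomicRanges GRanges promoters findOverlaps pintersect
#' @importFrom IRanges IRanges width
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
NULL

#' Merge significant DMPs into differentially methylated regions
#'
#' Transparent region builder: consecutive significant CpGs on one
#' chromosome whose neighbor distance is at most \code{maxGap} are merged; a
#' region is retained only if it contains at least \code{minCpgs} CpGs and
#' at least one CpG with |delta beta| > \code{minDelta}. Coordinates are
#' 1-based (array-manifest convention); a region spans its first to last CpG
#' position.
#'
#' @param dmps data.frame of significant CpGs: \code{cpg_id}, \code{chrom},
#'   \code{pos} (1-based), \code{delta_beta}. Sorted internally if needed
#'   (with a message).
#' @param maxGap maximum distance (bp) between consecutive member CpGs.
#' @param minCpgs minimum CpGs per region.
#' @param minDelta at least one member CpG must exceed this |delta beta|.
#' @return \code{GRanges} of regions with \code{n_cpgs},
#'   \code{max_abs_delta} and \code{cpg_ids} metadata columns.
#' @export
mergeDmps <- function(dmps, maxGap = 1000, minCpgs = 2, minDelta = 0.1) {
  need <- c("cpg_id", "chrom", "pos", "delta_beta")
  if (!all(need %in% colnames(dmps))) {
    stop("dmps must contain: ", paste(need, collapse = ", "))
  }
  if (nrow(dmps) == 0L) {
    return(GRanges())
  }
  ord <- order(dmps$chrom, dmps$pos)
  if (!identical(ord, seq_len(nrow(dmps)))) {
    message("input CpGs were not sorted; sorting by chromosome and position")
    dmps <- dmps[ord, ]
  }
  newRegion <- c(TRUE, dmps$chrom[-1L] != dmps$chrom[-nrow(dmps)] |
                   diff(dmps$pos) > maxGap)
  rid <- cumsum(newRegion)
  parts <- split(dmps, rid)
  keepPart <- vapply(parts, function(d) {
    nrow(d) >= minCpgs && max(abs(d$delta_beta)) > minDelta
  }, logical(1))
  parts <- parts[keepPart]
  if (!length(parts)) {
    return(GRanges())
  }
  gr <- GRanges(
    seqnames = vapply(parts, function(d) d$chrom[1L], character(1)),
    ranges = IRanges(
      start = vapply(parts, function(d) min(d$pos), numeric(1)),
      end = vapply(parts, function(d) max(d$pos), numeric(1))
    )
  )
  mcols(gr)$n_cpgs <- unname(vapply(parts, nrow, integer(1)))
  mcols(gr)$max_abs_delta <- unname(vapply(parts, function(d) {
    max(abs(d$delta_beta))
  }, numeric(1)))
  mcols(gr)$cpg_ids <- unname(vapply(parts, function(d) {
    paste(d$cpg_id, collapse = ",")
  }, character(1)))
  names(gr) <- sprintf("DMR%04d", seq_along(gr))
  gr
}

#' Read gene models from a TSV (1-based inclusive coordinates)
#'
#' @param path TSV with columns \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand}.
#' @return data.frame as read (coordinates kept 1-based inclusive).
#' @export
readGeneModels <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% colnames(g))) {
    stop("gene model file must contain: ", paste(need, collapse = ", "))
  }
  if (any(g$start > g$end)) stop("malformed intervals (start > end)")
  g
}

# gene bodies and strand-aware promoters (1500 bp upstream of the TSS,
# clipped at position 1) as GRanges
.geneRanges <- function(genes, promoterWidth = 1500) {
  if (any(genes$start > genes$end)) stop("malformed gene intervals")
  body <- GRanges(genes$chrom,
                  IRanges(genes$start, genes$end),
                  strand = genes$strand)
  names(body) <- genes$gene_id
  prom <- suppressWarnings(
    GenomicRanges::trim(promoters(body, upstream = promoterWidth,
                                  downstream = 0))
  )
  # trim() needs seqlengths for the right end; clip manually at position 1
  GenomicRanges::start(prom) <- pmax(GenomicRanges::start(prom), 1L)
  list(body = body, promoter = prom)
}

#' Map regions to promoters and gene bodies
#'
#' A region is assigned to a gene's promoter (up to \code{promoterWidth} bp
#' upstream of the strand-appropriate TSS, clipped at the chromosome start)
#' and/or gene body iff the overlap is at least \code{minOverlap} bp
#' (default 200). A region may map to multiple genes and features.
#'
#' @param regions \code{GRanges} (e.g. from \code{\link{mergeDmps}}).
#' @param genes data.frame of gene models (1-based inclusive; see
#'   \code{\link{readGeneModels}}).
#' @param minOverlap minimum overlap in bp.
#' @param promoterWidth promoter length upstream of the TSS.
#' @return data.frame: \code{region}, \code{gene_id}, \code{feature}
#'   (promoter/body), \code{overlap} (bp).
#' @export
mapRegionsToGenes <- function(regions, genes, minOverlap = 200,
                              promoterWidth = 1500) {
  rngs <- .geneRanges(genes, promoterWidth)
  if (is.null(names(regions))) {
    names(regions) <- sprintf("R%04d", seq_along(regions))
  }
  one <- function(target, label) {
    ov <- findOverlaps(regions, target, minoverlap = minOverlap,
                       ignore.strand = TRUE)
    if (!length(ov)) {
      return(NULL)
    }
    w <- width(pintersect(regions[queryHits(ov)],
                          target[subjectHits(ov)], ignore.strand = TRUE))
    data.frame(
      region = names(regions)[queryHits(ov)],
      gene_id = names(target)[subjectHits(ov)],
      feature = label, overlap = w, stringsAsFactors = FALSE
    )
  }
  out <- rbind(one(rngs$promoter, "promoter"), one(rngs$body, "body"))
  if (is.null(out)) {
    out <- data.frame(region = character(), gene_id = character(),
                      feature = character(), overlap = integer(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$region, out$gene_id, out$feature), , drop = FALSE]
}

#' Overlap DMR-associated genes with DEGs
#'
#' @param dmrGenes character vector of DMR-associated gene ids.
#' @param degs character vector of differentially expressed gene ids.
#' @return list: \code{overlap} (sorted gene ids), \code{counts}
#'   (n_dmr_genes, n_degs, n_overlap).
#' @export
intersectDmrDeg <- function(dmrGenes, degs) {
  ov <- sort(intersect(unique(dmrGenes), unique(degs)))
  list(overlap = ov,
       counts = c(n_dmr_genes = length(unique(dmrGenes)),
                  n_degs = length(unique(degs)),
                  n_overlap = length(ov)))
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  sets
}

#' Hypergeometric gene-set overrepresentation
#'
#' For each set, tests whether the hit list overlaps the set more than
#' expected when drawing \code{length(hits)} genes uniformly from the
#' universe: upper-tail hypergeometric \code{p = P(X >= k)}. q values are BH
#' across sets; a set is reported when \code{p < pCutoff} and
#' \code{q < qCutoff} (defaults 0.1 / 0.2). Hits and set members outside the
#' universe are pruned (counts in a message), so a custom background (e.g.
#' the post-filtering array design) is respected.
#'
#' @param hits character vector of hit gene ids.
#' @param sets named list of gene sets.
#' @param universe background gene ids.
#' @param pCutoff,qCutoff reporting cutoffs.
#' @return data.frame: set, k (overlap), K (set size), n (hits), N
#'   (universe), p, q, reported.
#' @export
hypergeomEnrichment <- function(hits, sets, universe,
                                pCutoff = 0.1, qCutoff = 0.2) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  hits0 <- unique(hits)
  hits <- intersect(hits0, universe)
  if (length(hits) < length(hits0)) {
    message(length(hits0) - length(hits), " hit(s) outside universe pruned")
  }
  N <- length(universe)
  n <- length(hits)
  res <- do.call(rbind, lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(hits, s))
    K <- length(s)
    p <- if (k == 0L) 1 else stats::phyper(k - 1, K, N - K, n,
                                           lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  }))
  res$q <- bhAdjust(res$p)
  res$reported <- res$p < pCutoff & res$q < qCutoff
  res[order(res$p), , drop = FALSE]
}

#' Write regions as a BED file
#'
#' Converts the internal 1-based closed intervals to BED's 0-based
#' half-open convention on output.
#'
#' @param regions \code{GRanges}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRegionsBED <- function(regions, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1L,
    end = GenomicRanges::end(regions),
    name = if (is.null(names(regions))) {
      sprintf("R%04d", seq_along(regions))
    } else {
      names(regions)
    }
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as GRanges (1-based closed internally)
#'
#' @param path BED file (chrom, start, end, optional name).
#' @return \code{GRanges}.
#' @export
readRegionsBED <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  gr <- GRanges(df[[1L]], IRanges(df[[2L]] + 1L, df[[3L]]))
  if (ncol(df) >= 4L) names(gr) <- df[[4L]]
  gr
}
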