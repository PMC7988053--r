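#' Per-gene DMP counts by region and direction
#'
#' Aggregates an annotated DMP set to one row per gene: counts of unique
#' probes that are TSS-hyper, TSS-hypo, body-hyper, body-hypo, overall
#' hyper/hypo, and the total number of DMPs in or near the gene. A probe
#' annotated to two genes contributes to both genes' rows.
#'
#' @param dmps an annotated [DMPSet-class].
#' @return data.frame with columns `gene`, `comparison`, `n_tss_hyper`,
#'   `n_tss_hypo`, `n_body_hyper`, `n_body_hypo`, `n_hyper`, `n_hypo`,
#'   `n_total`.
#' @export
geneDMPSummary <- function(dmps) {
  if (!isAnnotated(dmps)) stop("annotate the DMP set first")
  rec <- dmpRecords(dmps)
  rec <- rec[!is.na(rec$gene), , drop = FALSE]
  rec <- rec[!duplicated(paste(rec$gene, rec$probe_id)), , drop = FALSE]
  if (!nrow(rec))
    return(data.frame(gene = character(), comparison = character(),
                      n_tss_hyper = integer(), n_tss_hypo = integer(),
                      n_body_hyper = integer(), n_body_hypo = integer(),
                      n_hyper = integer(), n_hypo = integer(),
                      n_total = integer()))
  cnt <- function(cond) {
    v <- tapply(cond, rec$gene, sum)
    as.integer(v[genes])
  }
  genes <- sort(unique(rec$gene))
  out <- data.frame(
    gene = genes,
    comparison = comparisonName(dmps),
    n_tss_hyper = cnt(rec$feature == "TSS" & rec$direction == "hyper"),
    n_tss_hypo = cnt(rec$feature == "TSS" & rec$direction == "hypo"),
    n_body_hyper = cnt(rec$feature == "Body" & rec$direction == "hyper"),
    n_body_hypo = cnt(rec$feature == "Body" & rec$direction == "hypo"),
    n_hyper = cnt(rec$direction == "hyper"),
    n_hypo = cnt(rec$direction == "hypo"),
    n_total = cnt(rep(TRUE, nrow(rec))),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter gene summaries by minimum region DMP counts
#'
#' Convenience subset for the usual "genes with >= 3 TSS DMPs" or ">= 5
#' body DMPs" style selections (counts are direction-agnostic per region).
#'
#' @param summaries output of [geneDMPSummary()].
#' @param minTss,minBody minimum TSS / body DMP counts (0 = no constraint;
#'   both constraints must hold when both are positive).
#' @return the filtered data.frame.
#' @export
filterGeneSummaries <- function(summaries, minTss = 0, minBody = 0) {
  keep <- (summaries$n_tss_hyper + summaries$n_tss_hypo >= minTss) &
    (summaries$n_body_hyper + summaries$n_body_hypo >= minBody)
  out <- summaries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Net hyper:hypo methylation score per gene
#'
#' For genes carrying at least `minDmps` DMPs, scores the balance of
#' hyper- versus hypomethylated probes:
#' \deqn{score = \log_2 \frac{n_{hyper} + 0.5}{n_{hypo} + 0.5}}
#' The 0.5 pseudocount keeps genes with a zero denominator finite and
#' rankable. `net_class` compares the raw counts: `net_hyper` when
#' `n_hyper > n_hypo`, `net_hypo` when the reverse, else `balanced`.
#'
#' @param summaries output of [geneDMPSummary()].
#' @param minDmps minimum total DMPs per gene (default 6, i.e. "more than
#'   5"; set 5 for the inclusive reading).
#' @param pseudocount pseudocount in the score (default 0.5).
#' @return data.frame `gene`, `comparison`, `n_hyper`, `n_hypo`,
#'   `n_total`, `score`, `net_class`, sorted by descending score.
#' @export
netMethylationScore <- function(summaries, minDmps = 6, pseudocount = 0.5) {
  if (minDmps < 1) stop("minDmps must be >= 1")
  s <- summaries[summaries$n_total >= minDmps, , drop = FALSE]
  score <- log2((s$n_hyper + pseudocount) / (s$n_hypo + pseudocount))
  out <- data.frame(gene = s$gene, comparison = s$comparison,
                    n_hyper = s$n_hyper, n_hypo = s$n_hypo,
                    n_total = s$n_total, score = score,
                    net_class = ifelse(s$n_hyper > s$n_hypo, "net_hyper",
                                ifelse(s$n_hypo > s$n_hyper, "net_hypo",
                                       "balanced")),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), ]
  rownames(out) <- NULL
  out
}

## Convert a BED-like region table (0-based half-open, optional direction
## and source columns) to GRanges (1-based closed). A probe at 1-based
## position p falls in [start, end) iff start <= p - 1 < end, which the
## conversion start+1..end preserves under GRanges overlap.
.regionsToGRanges <- function(regions) {
  if (is(regions, "GRanges")) {
    gr <- regions
    if (is.null(gr$direction)) gr$direction <- "none"
    if (is.null(gr$source)) gr$source <- "regions"
    return(gr)
  }
  regions <- as.data.frame(regions)
  if (any(regions$start >= regions$end) || any(regions$start < 0))
    stop("malformed interval: need 0 <= start < end (0-based half-open)")
  gr <- GRanges(regions$chrom, IRanges(regions$start + 1L, regions$end))
  gr$direction <- if (is.null(regions$direction)) "none" else
    as.character(regions$direction)
  gr$source <- if (is.null(regions$source)) "regions" else
    as.character(regions$source)
  gr
}

#' Overlap DMPs with external region sets
#'
#' Counts the DMPs whose CpG position falls inside any of the supplied
#' regions (e.g. differentially methylated CpGs or regions from an external
#' tumour study), split by DMP direction. With `directionMatch = TRUE` a
#' hit additionally requires the region's direction label to equal the
#' DMP's -- the "same methylation trend" comparison.
#'
#' Coordinates: manifest positions are 1-based CpG sites; region tables are
#' BED-style 0-based half-open. A probe at position p hits `[s, e)` iff
#' `s <= p - 1 < e`.
#'
#' @param dmps an annotated [DMPSet-class].
#' @param regions data.frame (`chrom`, `start`, `end`, optional
#'   `direction`, `source`) or GRanges.
#' @param directionMatch require region direction == DMP direction.
#' @return list with `n_query` (unique DMPs), `n_hit`, `n_hyper_hit`,
#'   `n_hypo_hit` (hits by DMP direction) and `per_source` (the same counts
#'   per region source label).
#' @export
overlapWithRegions <- function(dmps, regions, directionMatch = FALSE) {
  if (!isAnnotated(dmps)) stop("annotate the DMP set first")
  rec <- dmpRecords(dmps)
  rec <- rec[!duplicated(rec$probe_id), , drop = FALSE]
  gr <- .regionsToGRanges(regions)
  probes <- GRanges(rec$chrom, IRanges(rec$pos, rec$pos))
  hitOne <- function(sub) {
    if (!directionMatch) return(countOverlaps(probes, sub) > 0L)
    h <- logical(nrow(rec))
    for (d in DIRECTIONS) {
      i <- rec$direction == d
      h[i] <- countOverlaps(probes[i], sub[sub$direction == d]) > 0L
    }
    h
  }
  hit <- hitOne(gr)
  perSource <- do.call(rbind, lapply(unique(gr$source), function(src) {
    h <- hitOne(gr[gr$source == src])
    data.frame(source = src, n_hit = sum(h),
               n_hyper_hit = sum(h & rec$direction == "hyper"),
               n_hypo_hit = sum(h & rec$direction == "hypo"),
               stringsAsFactors = FALSE)
  }))
  list(n_query = nrow(rec), n_hit = sum(hit),
       n_hyper_hit = sum(hit & rec$direction == "hyper"),
       n_hypo_hit = sum(hit & rec$direction == "hypo"),
       per_source = perSource)
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric tail test of query-gene overlap with each
#' user-supplied gene set against a stated universe, BH-adjusted across
#' sets. This is transparent plumbing for user gene sets; note that genes
#' covered by more probes are more likely to enter methylation-derived
#' query lists, a selection bias this test does not correct. The
#' `weights` hook (per-gene probe counts or similar) is exposed for
#' diagnostics: when supplied, the mean query weight per set is reported
#' alongside, but the p value remains the unweighted hypergeometric.
#'
#' @param queryGenes character vector of selected genes (subset of the
#'   universe; genes outside it are dropped with a warning).
#' @param universe all genes that could have been selected.
#' @param geneSets named list of character vectors (e.g. from [readGMT()]).
#' @param weights optional named per-gene weights (diagnostic only).
#' @return data.frame `set`, `n_set`, `n_overlap`, `expected`, `p`, `q`
#'   (and `mean_query_weight` when weights are supplied), sorted by p.
#' @export
geneSetEnrichment <- function(queryGenes, universe, geneSets,
                              weights = NULL) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  queryGenes <- unique(queryGenes)
  out <- setdiff(queryGenes, universe)
  if (length(out)) {
    warning(length(out), " query genes outside the universe were dropped")
    queryGenes <- intersect(queryGenes, universe)
  }
  N <- length(universe); n <- length(queryGenes)
  res <- do.call(rbind, lapply(names(geneSets), function(nm) {
    set <- intersect(unique(geneSets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(queryGenes, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, n_set = K, n_overlap = k,
               expected = n * K / N, p = p, stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  if (!is.null(weights)) {
    res$mean_query_weight <- vapply(names(geneSets), function(nm) {
      g <- intersect(queryGenes, geneSets[[nm]])
      if (length(g)) mean(weights[g], na.rm = TRUE) else NA_real_
    }, numeric(1))
  }
  res <- res[order(res$p, res$set), ]
  rownames(res) <- NULL
  res
}
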