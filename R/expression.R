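## Pull a counts matrix + sample table out of a SummarizedExperiment or a
## plain matrix with a supplied sample sheet.
.countsAndSamples <- function(expr, sampleData = NULL) {
  if (is(expr, "SummarizedExperiment")) {
    list(counts = assay(expr, "counts"),
         samples = as.data.frame(colData(expr)))
  } else {
    if (is.null(sampleData))
      stop("sampleData required when expr is a plain matrix")
    list(counts = as.matrix(expr), samples = as.data.frame(sampleData))
  }
}

#' Call differentially expressed genes by a count chi-squared test
#'
#' For each gene, counts are pooled within the case and reference groups
#' and tested on the 2x2 table (gene counts vs rest-of-library counts) x
#' (case vs ref) with an uncorrected chi-squared statistic -- expectations
#' are proportional to library sizes, so the test asks whether the gene's
#' share of the library differs between states. BH adjustment runs across
#' all tested genes; records with `q < fdrCut` are returned.
#'
#' The log2 fold change is computed from depth-normalized group mean counts
#' with a 0.5 pseudocount; `direction` is `up`/`down` by its sign. Genes
#' with zero counts in every sample are skipped and logged in
#' `attr(result, "skipped")`. A Welch t test on log2 normalized counts is
#' available as an alternative backend for replicated designs.
#'
#' @param expr SummarizedExperiment with assay `"counts"`, or counts matrix
#'   plus `sampleData`.
#' @param case,ref group labels (>= 1 sample each; `"welch"` needs >= 2).
#' @param name comparison name.
#' @param fdrCut FDR threshold (default 0.05).
#' @param method `"chisq"` (default) or `"welch"`.
#' @param sampleData sample sheet with `group` when `expr` is a matrix.
#' @param pseudocount pseudocount for the fold change (default 0.5).
#' @return data.frame of DEG records: `gene`, `comparison`, `log2fc`,
#'   `chi2`, `p`, `q`, `direction`.
#' @export
callDEGs <- function(expr, case, ref, name = paste0(case, "_vs_", ref),
                     fdrCut = 0.05, method = c("chisq", "welch"),
                     sampleData = NULL, pseudocount = 0.5) {
  method <- match.arg(method)
  cs <- .countsAndSamples(expr, sampleData)
  counts <- cs$counts
  grp <- as.character(cs$samples$group)
  i1 <- which(grp == case); i2 <- which(grp == ref)
  if (!length(i1) || !length(i2))
    stop("groups not found in the expression samples")
  if (any(counts < 0)) stop("counts must be non-negative")

  keep <- rowSums(counts[, c(i1, i2), drop = FALSE]) > 0
  skipped <- rownames(counts)[!keep]
  counts <- counts[keep, , drop = FALSE]

  lib <- colSums(counts)
  Tc <- rowSums(counts[, i1, drop = FALSE])
  Tr <- rowSums(counts[, i2, drop = FALSE])
  Lc <- sum(lib[i1]); Lr <- sum(lib[i2])

  if (method == "chisq") {
    ## chi-squared on [[Tc, Lc-Tc], [Tr, Lr-Tr]], uncorrected
    N <- Lc + Lr
    Tg <- Tc + Tr
    e11 <- Lc * Tg / N; e12 <- Lc * (N - Tg) / N
    e21 <- Lr * Tg / N; e22 <- Lr * (N - Tg) / N
    chi2 <- (Tc - e11)^2 / e11 + ((Lc - Tc) - e12)^2 / e12 +
      (Tr - e21)^2 / e21 + ((Lr - Tr) - e22)^2 / e22
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    if (length(i1) < 2L || length(i2) < 2L)
      stop("welch backend needs >= 2 replicates per group")
    meanLib <- mean(lib)
    lc <- log2(sweep(counts, 2, lib / meanLib, "/") + pseudocount)
    chi2 <- rep(NA_real_, nrow(counts))
    p <- vapply(seq_len(nrow(counts)), function(i) {
      x <- lc[i, i1]; y <- lc[i, i2]
      if (stats::sd(x) == 0 && stats::sd(y) == 0)
        return(if (mean(x) == mean(y)) 1 else 0)
      stats::t.test(x, y)$p.value
    }, numeric(1))
  }

  meanLib <- mean(lib)
  nmC <- Tc / Lc * meanLib
  nmR <- Tr / Lr * meanLib
  log2fc <- log2((nmC + pseudocount) / (nmR + pseudocount))
  q <- stats::p.adjust(p, method = "BH")

  pass <- which(q < fdrCut & log2fc != 0)
  out <- data.frame(gene = rownames(counts)[pass],
                    comparison = rep_len(name, length(pass)),
                    log2fc = log2fc[pass], chi2 = chi2[pass],
                    p = p[pass], q = q[pass],
                    direction = ifelse(log2fc[pass] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$gene), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "n_tested") <- nrow(counts)
  out
}

#' Classify methylation-expression scenarios
#'
#' Joins differential expression calls with gene-level DMP summaries (same
#' comparison) and labels each differentially expressed gene with the
#' methylation-expression scenarios it satisfies:
#' \describe{
#'   \item{a}{downregulated with promoter/TSS hypermethylation and no gene
#'     body hypermethylation;}
#'   \item{b}{upregulated with body hypermethylation and no promoter
#'     hypermethylation;}
#'   \item{c}{downregulated with body hypomethylation and no promoter
#'     hypomethylation;}
#'   \item{d}{upregulated with promoter hypomethylation and no body
#'     hypomethylation.}
#' }
#' Scenarios may co-occur (a with c, b with d); a and b (likewise c and d)
#' are mutually exclusive through the opposite expression directions.
#' "No" opposite-region methylation means zero DMPs at the calling
#' thresholds.
#'
#' @param degs DEG records from [callDEGs()].
#' @param summaries gene summaries from [geneDMPSummary()] for the same
#'   comparison.
#' @param minTss,minBody minimum DMP counts for the "with methylation"
#'   side of each rule (defaults 1).
#' @return data.frame `gene`, `comparison`, `direction`, `scenarios`
#'   (letters joined without separator, `""` if none).
#' @export
classifyScenarios <- function(degs, summaries, minTss = 1, minBody = 1) {
  ca <- unique(degs$comparison); cb <- unique(summaries$comparison)
  if (length(ca) == 1L && length(cb) == 1L && !identical(ca, cb))
    stop("DEGs (", ca, ") and summaries (", cb,
         ") come from different comparisons")
  m <- match(degs$gene, summaries$gene)
  g <- function(col) {
    v <- summaries[[col]][m]
    ifelse(is.na(v), 0L, v)
  }
  tssH <- g("n_tss_hyper"); tssL <- g("n_tss_hypo")
  bodH <- g("n_body_hyper"); bodL <- g("n_body_hypo")
  up <- degs$direction == "up"; down <- degs$direction == "down"
  a <- down & tssH >= minTss & bodH == 0L
  b <- up & bodH >= minBody & tssH == 0L
  cc <- down & bodL >= minBody & tssL == 0L
  d <- up & tssL >= minTss & bodL == 0L
  scen <- paste0(ifelse(a, "a", ""), ifelse(b, "b", ""),
                 ifelse(cc, "c", ""), ifelse(d, "d", ""))
  data.frame(gene = degs$gene, comparison = degs$comparison,
             direction = degs$direction, scenarios = scen,
             stringsAsFactors = FALSE)
}
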