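#' Annotate DMP records with manifest information
#'
#' Joins each record to the manifest, adding `chrom`, `pos`, `gene`,
#' `feature` and `cgi_context`. A probe annotated to several genes
#' contributes one record per gene (the expansion count is attached to the
#' records as `attr(, "n_multi_gene_expanded")`); intergenic probes keep
#' `gene = NA`. Unique-probe counts are unaffected: downstream
#' region-composition counting deduplicates by probe id, while gene-level
#' summaries deliberately count per gene.
#'
#' @param dmps a [DMPSet-class].
#' @param manifest the probe manifest.
#' @return the annotated [DMPSet-class] (`isAnnotated()` becomes `TRUE`).
#' @export
annotateDMPs <- function(dmps, manifest) {
  rec <- dmpRecords(dmps)
  idx <- match(rec$probe_id, manifest$probe_id)
  if (anyNA(idx))
    stop("probes not in manifest: ",
         paste(utils::head(rec$probe_id[is.na(idx)], 10L), collapse = ", "))
  geneLists <- strsplit(manifest$genes[idx], ",")
  nGenes <- pmax(1L, lengths(geneLists))
  out <- rec[rep(seq_len(nrow(rec)), nGenes), , drop = FALSE]
  midx <- idx[rep(seq_len(nrow(rec)), nGenes)]
  gene <- unlist(lapply(geneLists, function(g)
    if (length(g)) g else NA_character_), use.names = FALSE)
  gene[gene == ""] <- NA_character_
  out$chrom <- manifest$chrom[midx]
  out$pos <- manifest$pos[midx]
  out$gene <- gene
  out$feature <- manifest$feature[midx]
  out$cgi_context <- manifest$cgi_context[midx]
  rownames(out) <- NULL
  attr(out, "n_multi_gene_expanded") <- nrow(out) - nrow(rec)
  newDMPSet(dmps@comparison, dmps@caseGroup, dmps@refGroup, out,
            dmps@fdrCut, dmps@deltaCut, dmps@nTested, annotated = TRUE)
}

#' Genomic-region composition of a DMP set
#'
#' Counts unique probes per genomic feature class and per CpG-island
#' context, split by methylation direction -- the standard view of where in
#' the genome a comparison's methylation changes fall and whether each
#' region trends hyper- or hypomethylated. A probe annotated to several
#' genes is counted once (feature and context are probe-level properties).
#'
#' @param dmps an annotated [DMPSet-class] (see [annotateDMPs()]).
#' @return list of three data.frames (`feature`, `cgi`, `feature_grouped`;
#'   the grouped variant merges 5'UTR, first exon and 3'UTR into a single
#'   UTR class), each with columns `region`, `n`, `n_hyper`, `n_hypo`,
#'   `fraction` (of unique probes in the set).
#' @export
regionComposition <- function(dmps) {
  if (!isAnnotated(dmps)) stop("annotate the DMP set first")
  rec <- dmpRecords(dmps)
  rec <- rec[!duplicated(rec$probe_id), ]
  compose <- function(cls, levels) {
    f <- factor(cls, levels = levels)
    n <- as.integer(table(f))
    nh <- as.integer(table(f[rec$direction == "hyper"]))
    nl <- as.integer(table(f[rec$direction == "hypo"]))
    data.frame(region = levels, n = n, n_hyper = nh, n_hypo = nl,
               fraction = if (nrow(rec)) n / nrow(rec) else rep(0, length(n)),
               stringsAsFactors = FALSE)
  }
  grouped <- ifelse(rec$feature %in% c("5'UTR", "1stExon", "3'UTR"), "UTR",
                    rec$feature)
  list(feature = compose(rec$feature, FEATURE_CLASSES),
       cgi = compose(rec$cgi_context, CGI_CONTEXTS),
       feature_grouped = compose(grouped, c("TSS", "UTR", "Body", "IGR")))
}
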