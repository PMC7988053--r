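#' @rdname BetaSet-class
#' @export
setMethod("betaValues", "BetaSet", function(x) assay(x, "beta"))

#' @rdname BetaSet-class
#' @export
setMethod("sampleGroups", "BetaSet",
          function(x) as.character(colData(x)$group))

#' @rdname BetaSet-class
#' @export
setMethod("probeManifest", "BetaSet", function(x) {
  rd <- rowData(x)
  if (!ncol(rd)) return(NULL)
  as.data.frame(rd)
})

#' @rdname DMPSet-class
#' @export
setMethod("dmpRecords", "DMPSet", function(x) x@records)

#' @rdname DMPSet-class
#' @export
setMethod("comparisonName", "DMPSet", function(x) x@comparison)

#' @rdname DMPSet-class
#' @export
setMethod("nTested", "DMPSet", function(x) x@nTested)

#' @rdname DMPSet-class
#' @export
setMethod("isAnnotated", "DMPSet", function(x) x@annotated)

#' @rdname DMPSet-class
#' @param object a DMPSet.
#' @export
setMethod("show", "DMPSet", function(object) {
  rec <- object@records
  cat("DMPSet:", object@comparison,
      sprintf("(%s vs %s)\n", object@caseGroup, object@refGroup))
  cat(sprintf("  %d DMPs (%d hyper, %d hypo) of %d probes tested\n",
              nrow(rec), sum(rec$direction == "hyper"),
              sum(rec$direction == "hypo"), object@nTested))
  cat(sprintf("  thresholds: q < %g, |delta beta| >= %g; annotated: %s\n",
              object@fdrCut, object@deltaCut, object@annotated))
})

#' @rdname StudyDesign-class
#' @export
setMethod("comparisonTable", "StudyDesign", function(x) x@comparisons)

#' @rdname StudyDesign-class
#' @param object a StudyDesign.
#' @export
setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", length(object@groups), "groups x",
      object@replicates, "replicates\n")
  cat("  groups:", paste(object@groups, collapse = ", "), "\n")
  cat("  comparisons:", paste(object@comparisons$name, collapse = ", "),
      "\n")
})

#' @rdname CommonDMPSet-class
#' @param object a CommonDMPSet.
#' @export
setMethod("show", "CommonDMPSet", function(object) {
  cat("CommonDMPSet over", length(object@comparisons), "comparisons (mode:",
      object@mode, ")\n")
  n <- nrow(object@probes)
  if (object@mode == "same_direction") {
    cat(sprintf("  %d shared probes: %d hyper, %d hypo\n", n,
                sum(object@probes$direction == "hyper"),
                sum(object@probes$direction == "hypo")))
  } else cat(sprintf("  %d shared probes\n", n))
})

#' @rdname PatientDMRSet-class
#' @export
setMethod("patientId", "PatientDMRSet", function(x) x@patientId)

#' @rdname PatientDMRSet-class
#' @export
setMethod("dmrRegions", "PatientDMRSet", function(x) x@regions)

#' @rdname PatientDMRSet-class
#' @param object a PatientDMRSet.
#' @export
setMethod("show", "PatientDMRSet", function(object) {
  r <- object@regions
  cat(sprintf("PatientDMRSet %s [%s]: %d DMRs (%d hyper, %d hypo)\n",
              object@patientId, object@visitPair, length(r),
              sum(r$direction == "hyper"), sum(r$direction == "hypo")))
})

#' @rdname ResamplingResult-class
#' @param object a ResamplingResult.
#' @export
setMethod("show", "ResamplingResult", function(object) {
  cat(sprintf(paste0("ResamplingResult %s: p_obs = %.4f, p0 = %.4f ",
                     "(%d iters, n = %d)\n  z = %.3f, two-sided p = %.3g\n"),
              object@patientId, object@pObs, object@p0, object@nIter,
              object@n, object@z, object@pValue))
})

#' @rdname SyntheticTruth-class
#' @export
setMethod("plantedDMPs", "SyntheticTruth", function(x) x@plantedDMPs)

#' @rdname SyntheticTruth-class
#' @export
setMethod("plantedDEGs", "SyntheticTruth", function(x) x@plantedDEGs)

#' @rdname SyntheticTruth-class
#' @export
setMethod("patientSignal", "SyntheticTruth", function(x) x@patientSignal)

#' @rdname SyntheticTruth-class
#' @param object a SyntheticTruth.
#' @export
setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:\n")
  cat(sprintf("  planted DMPs: %d across %d comparisons\n",
              nrow(object@plantedDMPs),
              length(unique(object@plantedDMPs$comparison))))
  cat(sprintf("  planted DEGs: %d\n", nrow(object@plantedDEGs)))
  cat(sprintf("  patients with signal fractions: %d\n",
              length(object@patientSignal)))
})

#' Convert a probe manifest to genomic ranges
#'
#' Probes are single CpG positions (1-based); the returned
#' [GenomicRanges::GRanges] has width-1 ranges with the manifest columns as
#' metadata.
#'
#' @param manifest probe manifest data.frame.
#' @return GRanges, one range per probe.
#' @export
manifestGRanges <- function(manifest) {
  gr <- GRanges(manifest$chrom, IRanges(manifest$pos, manifest$pos),
                strand = manifest$strand)
  S4Vectors::mcols(gr) <- manifest[, setdiff(names(manifest),
                                             c("chrom", "pos", "strand")),
                                   drop = FALSE]
  gr
}
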