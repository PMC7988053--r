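#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- assayNames colData rowData rowData<-
#' @importFrom GenomicRanges GRanges findOverlaps countOverlaps
#' @importFrom IRanges IRanges
NULL

FEATURE_CLASSES <- c("TSS", "5'UTR", "1stExon", "Body", "3'UTR", "IGR")
CGI_CONTEXTS <- c("island", "shore", "shelf", "open_sea")
PROBE_FLAGS <- c("snp", "cross_reactive", "multi_hit")
DIRECTIONS <- c("hyper", "hypo")

#' Study design: groups, replication and the comparison scheme
#'
#' A `StudyDesign` names the sample groups (cell lines), the number of
#' replicates per group, and the set of pairwise comparisons (each a named
#' case-vs-reference contrast) that the differential stages will run.
#'
#' @slot groups character vector of group (cell line) names.
#' @slot replicates integer, replicates per group (>= 2 for any group used in
#'   a comparison).
#' @slot comparisons data.frame with columns `name`, `case`, `ref`.
#' @export
setClass("StudyDesign",
  representation(groups = "character", replicates = "integer",
                 comparisons = "data.frame"))

setValidity("StudyDesign", function(object) {
  msg <- NULL
  if (length(object@groups) < 2L)
    msg <- c(msg, "need at least 2 groups")
  if (anyDuplicated(object@groups))
    msg <- c(msg, "group names must be unique")
  if (object@replicates < 2L)
    msg <- c(msg, "need at least 2 replicates per group")
  cmp <- object@comparisons
  if (!all(c("name", "case", "ref") %in% names(cmp)))
    msg <- c(msg, "comparisons must have columns name, case, ref")
  else {
    if (any(cmp$case == cmp$ref))
      msg <- c(msg, "comparison case and ref must differ")
    bad <- setdiff(c(cmp$case, cmp$ref), object@groups)
    if (length(bad))
      msg <- c(msg, paste("unknown comparison groups:",
                          paste(bad, collapse = ", ")))
    if (anyDuplicated(cmp$name))
      msg <- c(msg, "comparison names must be unique")
  }
  if (is.null(msg)) TRUE else msg
})

#' Beta-value matrix with sample metadata
#'
#' A `BetaSet` is a [SummarizedExperiment::SummarizedExperiment] whose single
#' assay `"beta"` holds methylation beta values (probes x samples, each in
#' \[0, 1\]) and whose `colData` carries `group` (cell line) and `replicate`
#' labels. Probe annotation (the manifest) may be attached as `rowData`.
#'
#' Beta values are the methylation fraction estimate
#' \eqn{\beta = M / (U + M + 100)} computed from methylated (M) and
#' unmethylated (U) allele intensities; see [betaFromIntensities()].
#'
#' @export
setClass("BetaSet", contains = "SummarizedExperiment")

setValidity("BetaSet", function(object) {
  msg <- NULL
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    return("assay 'beta' is required")
  b <- assay(object, "beta")
  if (any(!is.finite(b)) || any(b < 0) || any(b > 1))
    msg <- c(msg, "beta values must be finite and in [0, 1]")
  cd <- colData(object)
  if (!all(c("group", "replicate") %in% names(cd)))
    msg <- c(msg, "colData must carry 'group' and 'replicate'")
  if (is.null(msg)) TRUE else msg
})

#' Planted truth for a synthetic study
#'
#' Records what the synthetic-data generator planted so downstream stages can
#' be scored against it: differentially methylated probes per comparison,
#' differentially expressed genes (with their scenario label) per comparison,
#' the per-patient cfDNA signal fraction, and the per-stage seeds.
#'
#' @slot plantedDMPs data.frame: `comparison`, `probe_id`, `direction`
#'   (hyper/hypo), `gene`, `feature`.
#' @slot plantedDEGs data.frame: `comparison`, `gene`, `direction` (up/down),
#'   `scenario` (a--d or NA).
#' @slot patientSignal named numeric in \[0, 1\]: fraction of each patient's
#'   hypermethylated DMRs seeded over planted tNEPC-hyper probe positions.
#' @slot seeds named list of integer seeds, one per generator stage.
#' @export
setClass("SyntheticTruth",
  representation(plantedDMPs = "data.frame", plantedDEGs = "data.frame",
                 patientSignal = "numeric", seeds = "list"))

setValidity("SyntheticTruth", function(object) {
  msg <- NULL
  pd <- object@plantedDMPs
  if (nrow(pd) && !all(pd$direction %in% DIRECTIONS))
    msg <- c(msg, "planted DMP directions must be hyper/hypo")
  pg <- object@plantedDEGs
  if (nrow(pg) && !all(pg$direction %in% c("up", "down")))
    msg <- c(msg, "planted DEG directions must be up/down")
  ps <- object@patientSignal
  if (length(ps) && (any(ps < 0) || any(ps > 1)))
    msg <- c(msg, "patientSignal must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Differentially methylated probe set for one comparison
#'
#' Holds the records that passed the FDR and |delta-beta| thresholds for a
#' single case-vs-reference comparison, plus the thresholds and the number of
#' probes tested (the BH family size). Records carry `probe_id`,
#' `delta_beta` (mean case - mean ref), `t` (moderated t), `p`, `q`
#' (BH-adjusted) and `direction` (hyper if delta_beta > 0, else hypo).
#' [annotateDMPs()] adds `chrom`, `pos`, `gene`, `feature`, `cgi_context`.
#'
#' @slot comparison comparison name.
#' @slot caseGroup,refGroup group labels of the contrast.
#' @slot records data.frame of passing probes (possibly 0 rows).
#' @slot fdrCut,deltaCut thresholds used for the calls.
#' @slot nTested number of probes entering BH adjustment.
#' @slot annotated TRUE once manifest annotation has been joined.
#' @export
setClass("DMPSet",
  representation(comparison = "character", caseGroup = "character",
                 refGroup = "character", records = "data.frame",
                 fdrCut = "numeric", deltaCut = "numeric",
                 nTested = "integer", annotated = "logical"),
  prototype(annotated = FALSE))

setValidity("DMPSet", function(object) {
  msg <- NULL
  rec <- object@records
  need <- c("probe_id", "delta_beta", "t", "p", "q", "direction")
  if (!all(need %in% names(rec)))
    msg <- c(msg, paste("records need columns:", paste(need, collapse = ", ")))
  else if (nrow(rec)) {
    if (!all(rec$direction %in% DIRECTIONS))
      msg <- c(msg, "directions must be hyper/hypo")
    disagree <- (rec$delta_beta > 0) != (rec$direction == "hyper")
    if (any(disagree))
      msg <- c(msg, "direction must match the sign of delta_beta")
    if (any(rec$q < 0 | rec$q > 1))
      msg <- c(msg, "q values must lie in [0, 1]")
  }
  if (is.null(msg)) TRUE else msg
})

#' Probes shared across several comparisons
#'
#' Result of [commonDMPs()]: the probe-id intersection of two or more DMP
#' sets. In `same_direction` mode only probes whose call direction agrees in
#' every member comparison are retained and `probes$direction` holds that
#' resolved direction; in `any` mode per-comparison directions are kept as
#' one column per comparison.
#'
#' @slot comparisons names of the member comparisons.
#' @slot probes data.frame keyed by `probe_id`.
#' @slot mode `"same_direction"` or `"any"`.
#' @export
setClass("CommonDMPSet",
  representation(comparisons = "character", probes = "data.frame",
                 mode = "character"))

setValidity("CommonDMPSet", function(object) {
  if (!object@mode %in% c("same_direction", "any"))
    return("mode must be 'same_direction' or 'any'")
  if (object@mode == "same_direction" && nrow(object@probes) &&
      !all(object@probes$direction %in% DIRECTIONS))
    return("resolved directions must be hyper/hypo")
  TRUE
})

#' Per-patient cell-free DNA differentially methylated regions
#'
#' Direction-labelled genomic intervals called between two study visits in a
#' patient's cfDNA (e.g. pre-treatment visit A vs on-treatment visit B).
#' `direction` means hyper- or hypomethylated at visit A relative to B.
#' Intervals are stored as a [GenomicRanges::GRanges] (1-based, closed);
#' the on-disk interchange format is BED-like 0-based half-open, converted by
#' the package readers/writers.
#'
#' @slot patientId patient identifier.
#' @slot visitPair label of the visit contrast, e.g. `"A_vs_B"`.
#' @slot regions GRanges with metadata column `direction` in hyper/hypo.
#' @export
setClass("PatientDMRSet",
  representation(patientId = "character", visitPair = "character",
                 regions = "GRanges"))

setValidity("PatientDMRSet", function(object) {
  r <- object@regions
  if (!"direction" %in% names(S4Vectors::mcols(r)))
    return("regions need a 'direction' metadata column")
  if (length(r) && !all(r$direction %in% DIRECTIONS))
    return("DMR directions must be hyper/hypo")
  TRUE
})

#' Probe-resampling null result for one query set against one patient
#'
#' Compares the fraction of query DMPs falling inside a patient's cfDNA DMRs
#' (`pObs`) with the mean fraction over random probe draws of the same size
#' from the post-filter manifest (`p0`), via the one-proportion z statistic
#' \eqn{z = (p_{obs} - p_0) / \sqrt{p_0 (1 - p_0) / n}} with a two-sided
#' normal p value.
#'
#' @slot patientId patient identifier.
#' @slot pObs observed in-DMR fraction of the query DMPs.
#' @slot p0 mean in-DMR fraction over the resamples.
#' @slot nIter number of resampling iterations.
#' @slot n number of query DMPs (the z-test denominator n).
#' @slot z,pValue the test statistic and two-sided p.
#' @export
setClass("ResamplingResult",
  representation(patientId = "character", pObs = "numeric", p0 = "numeric",
                 nIter = "integer", n = "integer", z = "numeric",
                 pValue = "numeric"))

setValidity("ResamplingResult", function(object) {
  msg <- NULL
  if (object@pObs < 0 || object@pObs > 1 || object@p0 < 0 || object@p0 > 1)
    msg <- c(msg, "pObs and p0 must lie in [0, 1]")
  if (object@nIter < 1L)
    msg <- c(msg, "nIter must be >= 1")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (is.null(msg)) TRUE else msg
})
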