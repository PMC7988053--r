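#' Construct a StudyDesign
#'
#' @param groups character vector of group (cell line) names.
#' @param replicates replicates per group (default 3, as for a triplicated
#'   array experiment).
#' @param comparisons data.frame with columns `name`, `case`, `ref`; if
#'   `NULL`, every group is compared against the first (reference) group.
#' @return a [StudyDesign-class] object.
#' @examples
#' studyDesign(c("LN", "CRPC"), replicates = 3)
#' @export
studyDesign <- function(groups, replicates = 3L, comparisons = NULL) {
  if (is.null(comparisons)) {
    others <- setdiff(groups, groups[1L])
    comparisons <- data.frame(
      name = paste0(others, "_vs_", groups[1L]),
      case = others, ref = rep(groups[1L], length(others)),
      stringsAsFactors = FALSE)
  }
  new("StudyDesign", groups = as.character(groups),
      replicates = as.integer(replicates), comparisons = comparisons)
}

#' The default staged-progression design
#'
#' Five cell lines in triplicate emulating a castration-sensitive parental
#' line (LN), a vehicle-control castration-resistant line (CRPC16D), an
#' AR-driven adenocarcinoma enzalutamide-resistant line (ENZR49F) and two
#' treatment-induced neuroendocrine lines (NE42D, NE42F). The comparison
#' scheme covers the three progression questions: every line vs the parental
#' line, every resistant line vs the control CRPC line, and the two
#' neuroendocrine lines vs the adenocarcinoma resistant line.
#'
#' @param replicates replicates per group (default 3).
#' @return a [StudyDesign-class].
#' @export
progressionDesign <- function(replicates = 3L) {
  groups <- c("LN", "CRPC16D", "ENZR49F", "NE42D", "NE42F")
  cmp <- rbind(
    data.frame(name = paste0(groups[-1L], "_vs_LN"),
               case = groups[-1L], ref = "LN"),
    data.frame(name = paste0(c("ENZR49F", "NE42D", "NE42F"), "_vs_CRPC16D"),
               case = c("ENZR49F", "NE42D", "NE42F"), ref = "CRPC16D"),
    data.frame(name = paste0(c("NE42D", "NE42F"), "_vs_ENZR49F"),
               case = c("NE42D", "NE42F"), ref = "ENZR49F"))
  studyDesign(groups, replicates, cmp)
}

#' Construct a BetaSet
#'
#' @param beta numeric matrix of beta values in \[0, 1\], probes as rows
#'   (rownames = probe ids), samples as columns.
#' @param sampleData data.frame with one row per sample carrying at least
#'   `group` and `replicate`.
#' @param manifest optional probe manifest data.frame (see
#'   [simulateManifest()] for the column contract); matched to the beta rows
#'   by `probe_id` and stored as `rowData`.
#' @return a [BetaSet-class].
#' @export
BetaSet <- function(beta, sampleData, manifest = NULL) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)))
    stop("beta matrix must have probe ids as rownames")
  rd <- NULL
  if (!is.null(manifest)) {
    manifest <- as.data.frame(manifest)
    idx <- match(rownames(beta), manifest$probe_id)
    if (anyNA(idx))
      stop("beta matrix probes missing from manifest: ",
           paste(utils::head(rownames(beta)[is.na(idx)], 5L), collapse = ", "))
    rd <- S4Vectors::DataFrame(manifest[idx, , drop = FALSE])
    rownames(rd) <- rownames(beta)
  }
  se <- SummarizedExperiment(
    assays = list(beta = beta),
    colData = S4Vectors::DataFrame(sampleData, row.names = colnames(beta)))
  if (!is.null(rd)) rowData(se) <- rd
  new("BetaSet", se)
}

#' Construct a PatientDMRSet
#'
#' @param patientId patient identifier.
#' @param chrom,start,end interval coordinates, BED convention: 0-based
#'   half-open `[start, end)`.
#' @param direction per-interval methylation direction, `"hyper"` or
#'   `"hypo"` (at visit A relative to visit B).
#' @param visitPair label of the visit contrast (default `"A_vs_B"`).
#' @return a [PatientDMRSet-class].
#' @export
PatientDMRSet <- function(patientId, chrom, start, end, direction,
                          visitPair = "A_vs_B") {
  if (any(start >= end))
    stop("malformed interval: start must be < end (0-based half-open)")
  gr <- GRanges(chrom, IRanges(start + 1L, end))
  gr$direction <- as.character(direction)
  new("PatientDMRSet", patientId = as.character(patientId),
      visitPair = visitPair, regions = gr)
}

newDMPSet <- function(comparison, caseGroup, refGroup, records, fdrCut,
                      deltaCut, nTested, annotated = FALSE) {
  new("DMPSet", comparison = comparison, caseGroup = caseGroup,
      refGroup = refGroup, records = records, fdrCut = fdrCut,
      deltaCut = deltaCut, nTested = as.integer(nTested),
      annotated = annotated)
}

#' Build a DMPSet directly from records
#'
#' Mainly for loading externally produced DMP tables (e.g. published
#' supplementary tables) into the set-algebra stage. `direction` is derived
#' from the sign of `delta_beta` when absent.
#'
#' @param records data.frame with at least `probe_id` and `delta_beta`;
#'   `t`, `p`, `q` default to NA when missing.
#' @param comparison,caseGroup,refGroup labels.
#' @param fdrCut,deltaCut the thresholds the records are understood to have
#'   passed already.
#' @param nTested BH family size, if known.
#' @return a [DMPSet-class].
#' @export
DMPSet <- function(records, comparison, caseGroup = NA_character_,
                   refGroup = NA_character_, fdrCut = 0.01, deltaCut = 0.2,
                   nTested = nrow(records)) {
  records <- as.data.frame(records)
  for (col in c("t", "p", "q"))
    if (is.null(records[[col]])) records[[col]] <- NA_real_
  if (is.null(records$direction))
    records$direction <- ifelse(records$delta_beta > 0, "hyper", "hypo")
  newDMPSet(comparison, caseGroup, refGroup, records, fdrCut, deltaCut,
            nTested)
}
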