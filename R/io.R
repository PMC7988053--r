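## All interchange files are TSV with fixed column orders; intervals are
## BED-style 0-based half-open on disk and GRanges (1-based) in memory.

.writeTSV <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

.readTSV <- function(file, ...) {
  utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE,
                    ...)
}

#' Read / write a probe manifest
#'
#' TSV with columns `probe_id`, `chrom`, `pos`, `strand`, `genes`,
#' `feature`, `cgi_context`, `flags` (`genes` and `flags` comma-joined,
#' empty string when absent).
#'
#' @param file path.
#' @return data.frame manifest.
#' @export
readManifest <- function(file) {
  m <- .readTSV(file, colClasses = c(probe_id = "character",
                                     chrom = "character",
                                     genes = "character",
                                     flags = "character"))
  m$genes[is.na(m$genes)] <- ""
  m$flags[is.na(m$flags)] <- ""
  m
}

#' @rdname readManifest
#' @param manifest manifest data.frame.
#' @export
writeManifest <- function(manifest, file) {
  .writeTSV(manifest[, c("probe_id", "chrom", "pos", "strand", "genes",
                         "feature", "cgi_context", "flags")], file)
}

#' Read / write a beta matrix with its sample sheet
#'
#' The beta TSV has probes as rows (first column `probe_id`) and sample ids
#' as remaining column names; the sample sheet TSV has columns `sample_id`,
#' `group`, `replicate`.
#'
#' @param file beta TSV path.
#' @param sampleFile sample sheet TSV path.
#' @param manifest optional manifest to attach as rowData.
#' @return a [BetaSet-class].
#' @export
readBetaMatrix <- function(file, sampleFile, manifest = NULL) {
  df <- .readTSV(file, colClasses = c(probe_id = "character"))
  b <- as.matrix(df[, -1, drop = FALSE])
  rownames(b) <- df$probe_id
  samples <- .readTSV(sampleFile, colClasses = c(sample_id = "character",
                                                 group = "character"))
  b <- b[, samples$sample_id, drop = FALSE]
  BetaSet(b, samples, manifest)
}

#' @rdname readBetaMatrix
#' @param x a [BetaSet-class].
#' @export
writeBetaMatrix <- function(x, file, sampleFile) {
  b <- betaValues(x)
  .writeTSV(data.frame(probe_id = rownames(b), b, check.names = FALSE),
            file)
  .writeTSV(as.data.frame(colData(x))[, c("sample_id", "group",
                                          "replicate")], sampleFile)
}

#' Read / write DMP records
#'
#' Fixed column order `probe_id`, `comparison`, `delta_beta`, `t`, `p`,
#' `q`, `direction` (annotation columns `chrom`, `pos`, `gene`, `feature`,
#' `cgi_context` appended when present).
#'
#' @param dmps a [DMPSet-class].
#' @param file path.
#' @export
writeDMPs <- function(dmps, file) {
  rec <- dmpRecords(dmps)
  rec$comparison <- comparisonName(dmps)
  base <- c("probe_id", "comparison", "delta_beta", "t", "p", "q",
            "direction")
  ann <- intersect(c("chrom", "pos", "gene", "feature", "cgi_context"),
                   names(rec))
  .writeTSV(rec[, c(base, ann)], file)
}

#' @rdname writeDMPs
#' @param caseGroup,refGroup,fdrCut,deltaCut,nTested metadata not stored in
#'   the TSV, re-supplied on read.
#' @return `readDMPs`: a [DMPSet-class].
#' @export
readDMPs <- function(file, caseGroup = NA_character_,
                     refGroup = NA_character_, fdrCut = 0.01,
                     deltaCut = 0.2, nTested = NULL) {
  rec <- .readTSV(file, colClasses = c(probe_id = "character"))
  comparison <- if (nrow(rec)) rec$comparison[1L] else "unknown"
  annotated <- all(c("chrom", "pos", "feature") %in% names(rec))
  rec$comparison <- NULL
  if (is.null(nTested)) nTested <- nrow(rec)
  newDMPSet(comparison, caseGroup, refGroup, rec, fdrCut, deltaCut,
            nTested, annotated = annotated)
}

#' Read a BED-like region table
#'
#' Columns `chrom`, `start`, `end` (0-based half-open) with optional
#' `direction` and `source`; header optional for the 3/4-column form.
#'
#' @param file path.
#' @param source label applied when the file has no source column.
#' @return data.frame ready for [overlapWithRegions()].
#' @export
readRegions <- function(file, source = basename(file)) {
  first <- readLines(file, n = 1L)
  hasHeader <- grepl("chrom", first)
  df <- utils::read.delim(file, header = hasHeader,
                          stringsAsFactors = FALSE)
  if (!hasHeader) {
    names(df) <- c("chrom", "start", "end", "direction",
                   "source")[seq_len(ncol(df))]
  }
  if (is.null(df$direction)) df$direction <- "none"
  if (is.null(df$source)) df$source <- source
  if (any(df$start >= df$end))
    stop("malformed interval: start must be < end")
  df
}

#' Read / write per-patient cfDNA DMR sets
#'
#' TSV columns `chrom`, `start`, `end` (0-based half-open), `direction`,
#' `patient_id`, `visit_pair`.
#'
#' @param file path.
#' @return list of [PatientDMRSet-class], one per patient.
#' @export
readPatientDMRs <- function(file) {
  df <- .readTSV(file, colClasses = c(chrom = "character",
                                      patient_id = "character"))
  lapply(split(df, df$patient_id), function(d)
    PatientDMRSet(d$patient_id[1L], d$chrom, d$start, d$end, d$direction,
                  visitPair = d$visit_pair[1L]))
}

#' @rdname readPatientDMRs
#' @param patients list of [PatientDMRSet-class].
#' @export
writePatientDMRs <- function(patients, file) {
  rows <- lapply(patients, function(p) {
    r <- dmrRegions(p)
    data.frame(chrom = as.character(GenomicRanges::seqnames(r)),
               start = GenomicRanges::start(r) - 1L,
               end = GenomicRanges::end(r),
               direction = r$direction, patient_id = patientId(p),
               visit_pair = p@visitPair, stringsAsFactors = FALSE)
  })
  .writeTSV(do.call(rbind, rows), file)
}

#' Read / write patient outcomes
#'
#' TSV columns `patient_id`, `ttp_days`.
#'
#' @param file path.
#' @return data.frame.
#' @export
readOutcomes <- function(file) {
  df <- .readTSV(file, colClasses = c(patient_id = "character"))
  if (any(df$ttp_days <= 0)) stop("ttp_days must be positive")
  df
}

#' @rdname readOutcomes
#' @param outcomes data.frame `patient_id`, `ttp_days`.
#' @export
writeOutcomes <- function(outcomes, file) {
  .writeTSV(outcomes[, c("patient_id", "ttp_days")], file)
}

#' Read / write an expression count matrix with its sample sheet
#'
#' @param file counts TSV, genes as rows (first column `gene`).
#' @param sampleFile sample sheet TSV (`sample_id`, `group`, `replicate`).
#' @return SummarizedExperiment with assay `"counts"`.
#' @export
readExpression <- function(file, sampleFile) {
  df <- .readTSV(file, colClasses = c(gene = "character"))
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene
  samples <- .readTSV(sampleFile, colClasses = c(sample_id = "character",
                                                 group = "character"))
  counts <- counts[, samples$sample_id, drop = FALSE]
  SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
}

#' @rdname readExpression
#' @param expr SummarizedExperiment with assay `"counts"`.
#' @export
writeExpression <- function(expr, file, sampleFile) {
  counts <- assay(expr, "counts")
  .writeTSV(data.frame(gene = rownames(counts), counts,
                       check.names = FALSE), file)
  .writeTSV(as.data.frame(colData(expr))[, c("sample_id", "group",
                                             "replicate")], sampleFile)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes.
#'
#' @param file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[`, character(1), 1L))
}

#' Write / read a synthetic truth table as JSON
#'
#' @param truth a [SyntheticTruth-class].
#' @param file path.
#' @export
writeTruth <- function(truth, file) {
  jsonlite::write_json(
    list(planted_dmps = plantedDMPs(truth),
         planted_degs = plantedDEGs(truth),
         patient_signal = as.list(patientSignal(truth)),
         seeds = truth@seeds),
    file, auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname writeTruth
#' @return `readTruth`: a [SyntheticTruth-class].
#' @export
readTruth <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  asDf <- function(d, cols) {
    if (is.null(d) || !length(d)) {
      out <- as.data.frame(stats::setNames(
        rep(list(character(0)), length(cols)), cols))
      return(out)
    }
    as.data.frame(d, stringsAsFactors = FALSE)
  }
  new("SyntheticTruth",
      plantedDMPs = asDf(x$planted_dmps,
                         c("comparison", "probe_id", "direction", "gene",
                           "feature")),
      plantedDEGs = asDf(x$planted_degs,
                         c("comparison", "gene", "direction", "scenario")),
      patientSignal = if (length(x$patient_signal))
        unlist(x$patient_signal) else numeric(),
      seeds = lapply(x$seeds, as.integer))
}
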