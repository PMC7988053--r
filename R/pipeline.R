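#' Run the full staged-methylation pipeline
#'
#' Orchestrates probe filtering, per-comparison DMP calling, comparison-set
#' algebra, genomic annotation and composition, gene-level scoring,
#' differential expression with scenario classification, and the cfDNA
#' biomarker stage, writing every table to a fresh run directory together
#' with a machine-readable run manifest (package version, seeds, thresholds
#' and input file hashes). Stages whose inputs are absent are skipped with
#' a logged notice; the run fails fast on a missing declared input file.
#'
#' The run directory is write-once: an existing non-empty directory is
#' refused, and no stage mutates an upstream artifact.
#'
#' @param config nested list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{simulate}{list(n_probes, n_genes, n_planted, delta,
#'       n_per_scenario, n_patients) -- generate all inputs synthetically;
#'       omit to use `inputs`.}
#'     \item{inputs}{list of file paths: beta, samples, manifest, expr,
#'       expr_samples, dmrs, outcomes, regions, gmt (all optional except
#'       beta/samples/manifest).}
#'     \item{thresholds}{list(fdr = 0.01, delta = 0.2, expr_fdr = 0.05,
#'       min_dmps = 6, iters = 1000).}
#'     \item{seed}{root integer seed, split across the stochastic stages.}
#'   }
#' @param outDir run directory to create.
#' @return (invisibly) the run manifest list; side effect: the populated
#'   run directory.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read a YAML config")
    config <- yaml::read_yaml(config)
  }
  if (dir.exists(outDir) && length(list.files(outDir, all.files = TRUE,
                                              no.. = TRUE)))
    stop("run directory exists and is not empty: ", outDir)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  th <- utils::modifyList(
    list(fdr = 0.01, delta = 0.2, expr_fdr = 0.05, min_dmps = 6,
         iters = 1000),
    if (is.null(config$thresholds)) list() else config$thresholds)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  stageSeeds <- as.list(sample.int(1e8, 4L))
  names(stageSeeds) <- c("manifest", "beta", "expression", "cohort")

  log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    message(msg)
    log <<- c(log, msg)
  }
  inputHashes <- list()

  ## ---- inputs -----------------------------------------------------------
  expr <- NULL; patients <- NULL; outcomes <- NULL; regions <- NULL
  gmt <- NULL; truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- utils::modifyList(
      list(n_probes = 20000, n_genes = 1500, n_planted = 2000, delta = 0.3,
           n_per_scenario = 50, n_patients = 20), config$simulate)
    note("simulating inputs (", sim$n_probes, " probes, ", sim$n_genes,
         " genes)")
    design <- progressionDesign()
    manifest <- simulateManifest(sim$n_probes, sim$n_genes,
                                 seed = stageSeeds$manifest)
    bs <- simulateBetaSet(manifest, design, nPlanted = sim$n_planted,
                          delta = sim$delta, seed = stageSeeds$beta)
    beta <- bs$betaSet; truth <- bs$truth
    ex <- simulateExpression(truth, manifest, design,
                             nPerScenario = sim$n_per_scenario,
                             seed = stageSeeds$expression)
    expr <- ex$expression; truth <- ex$truth
    co <- simulateCohort(truth, manifest, nPatients = sim$n_patients,
                         seed = stageSeeds$cohort)
    patients <- co$patients; outcomes <- co$outcomes; truth <- co$truth
    writeManifest(manifest, file.path(outDir, "manifest.tsv"))
    writeBetaMatrix(beta, file.path(outDir, "beta.tsv"),
                    file.path(outDir, "samples.tsv"))
    writeExpression(expr, file.path(outDir, "expression.tsv"),
                    file.path(outDir, "expression_samples.tsv"))
    writePatientDMRs(patients, file.path(outDir, "patient_dmrs.tsv"))
    writeOutcomes(outcomes, file.path(outDir, "outcomes.tsv"))
    writeTruth(truth, file.path(outDir, "truth.json"))
  } else {
    ins <- config$inputs
    need <- c("beta", "samples", "manifest")
    for (f in need)
      if (is.null(ins[[f]])) stop("config$inputs$", f, " is required")
    all_in <- unlist(ins)
    missing <- all_in[!file.exists(all_in)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
    inputHashes <- as.list(tools::md5sum(all_in))
    manifest <- readManifest(ins$manifest)
    beta <- readBetaMatrix(ins$beta, ins$samples, manifest)
    design <- studyDesign(unique(sampleGroups(beta)))
    if (!is.null(ins$expr))
      expr <- readExpression(ins$expr, ins$expr_samples)
    if (!is.null(ins$dmrs)) patients <- readPatientDMRs(ins$dmrs)
    if (!is.null(ins$outcomes)) outcomes <- readOutcomes(ins$outcomes)
    if (!is.null(ins$regions)) regions <- readRegions(ins$regions)
    if (!is.null(ins$gmt)) gmt <- readGMT(ins$gmt)
  }

  ## ---- filter + DMPs ----------------------------------------------------
  filtered <- filterProbes(beta, manifest = manifest)
  note("filtered ", metadata(filtered)$filter_log$n_removed,
       " flagged probes, ", metadata(filtered)$filter_log$n_kept, " kept")
  dmpSets <- callDMPsAll(filtered, design, fdrCut = th$fdr,
                         deltaCut = th$delta)
  annSets <- lapply(dmpSets, annotateDMPs, manifest = manifest)
  for (nm in names(annSets))
    writeDMPs(annSets[[nm]], file.path(outDir, paste0("dmps_", nm, ".tsv")))
  note("called DMPs for ", length(dmpSets), " comparisons")

  ## ---- set algebra ------------------------------------------------------
  cmp <- comparisonTable(design)
  byRef <- split(cmp$name, cmp$ref)
  commons <- list()
  for (ref in names(byRef)) {
    nms <- byRef[[ref]]
    if (length(nms) < 2L) next
    cs <- commonDMPs(dmpSets[nms], mode = "same_direction")
    commons[[paste0("vs_", ref)]] <- cs
    counts <- directionCounts(cs)
    .writeTSV(cs@probes,
              file.path(outDir, paste0("common_vs_", ref, ".tsv")))
    note("common DMPs vs ", ref, ": ", counts["hyper"], " hyper, ",
         counts["hypo"], " hypo")
  }
  if (length(commons) >= 2L) {
    sw <- directionSwitches(commons[[1L]], commons[[2L]])
    jsonlite::write_json(
      list(a = names(commons)[1L], b = names(commons)[2L],
           total = sw$total, table = as.data.frame(as.table(sw$table))),
      file.path(outDir, "direction_switches.json"), auto_unbox = TRUE,
      digits = NA)
  }

  ## ---- annotation composition + gene scores ----------------------------
  summaries <- list()
  for (nm in names(annSets)) {
    comp <- regionComposition(annSets[[nm]])
    .writeTSV(comp$feature,
              file.path(outDir, paste0("composition_feature_", nm, ".tsv")))
    .writeTSV(comp$cgi,
              file.path(outDir, paste0("composition_cgi_", nm, ".tsv")))
    summaries[[nm]] <- geneDMPSummary(annSets[[nm]])
    scores <- netMethylationScore(summaries[[nm]], minDmps = th$min_dmps)
    .writeTSV(scores, file.path(outDir, paste0("gene_scores_", nm, ".tsv")))
  }
  if (!is.null(regions)) {
    for (nm in names(annSets)) {
      ov <- overlapWithRegions(annSets[[nm]], regions,
                               directionMatch = TRUE)
      .writeTSV(ov$per_source,
                file.path(outDir, paste0("region_overlap_", nm, ".tsv")))
    }
  }

  ## ---- expression + scenarios ------------------------------------------
  if (!is.null(expr)) {
    exprGroups <- unique(as.character(colData(expr)$group))
    for (i in seq_len(nrow(cmp))) {
      if (!all(c(cmp$case[i], cmp$ref[i]) %in% exprGroups)) next
      degs <- callDEGs(expr, cmp$case[i], cmp$ref[i], cmp$name[i],
                       fdrCut = th$expr_fdr)
      .writeTSV(degs, file.path(outDir, paste0("degs_", cmp$name[i],
                                               ".tsv")))
      if (!is.null(summaries[[cmp$name[i]]])) {
        sc <- classifyScenarios(degs, summaries[[cmp$name[i]]])
        .writeTSV(sc, file.path(outDir, paste0("scenarios_", cmp$name[i],
                                               ".tsv")))
      }
    }
    note("expression stage complete")
  } else note("no expression input; scenario stage skipped")

  ## ---- cfDNA biomarker --------------------------------------------------
  if (!is.null(patients) && !is.null(outcomes)) {
    neCmp <- grep("_vs_CRPC", names(annSets), value = TRUE)
    neCmp <- grep("^NE", neCmp, value = TRUE)
    qNm <- if (length(neCmp)) neCmp[1L] else names(annSets)[1L]
    rec <- dmpRecords(annSets[[qNm]])
    query <- rec[rec$direction == "hyper", , drop = FALSE]
    bio <- cfdnaBiomarker(query, patients, outcomes,
                          manifest = probeManifest(filtered),
                          nIter = th$iters, seed = seed)
    .writeTSV(bio$perPatient, file.path(outDir, "cfdna_per_patient.tsv"))
    jsonlite::write_json(
      list(query_comparison = qNm, rho = bio$correlation$rho,
           p = bio$correlation$p, n = bio$correlation$n),
      file.path(outDir, "cfdna_cohort.json"), auto_unbox = TRUE,
      digits = NA)
    note("cfDNA biomarker: rho = ", round(bio$correlation$rho, 3),
         ", p = ", signif(bio$correlation$p, 3))
  } else note("no cfDNA cohort input; biomarker stage skipped")

  ## ---- gene-set plumbing -----------------------------------------------
  if (!is.null(gmt) && length(summaries)) {
    s1 <- summaries[[1L]]
    universe <- unique(unlist(lapply(summaries, `[[`, "gene")))
    enr <- geneSetEnrichment(s1$gene, universe, gmt)
    .writeTSV(enr, file.path(outDir, "gene_set_enrichment.tsv"))
  }

  runManifest <- list(
    package = "methylProgression",
    version = as.character(utils::packageVersion("methylProgression")),
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, stage_seeds = stageSeeds, thresholds = th,
    input_hashes = inputHashes, log = log)
  jsonlite::write_json(runManifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(runManifest)
}
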