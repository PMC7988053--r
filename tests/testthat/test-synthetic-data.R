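test_that("minimal manifest is valid", {
  m <- simulateManifest(1, 1, seed = 1)
  expect_equal(nrow(m), 1L)
  expect_true(m$feature %in% c("TSS", "5'UTR", "1stExon", "Body", "3'UTR",
                               "IGR"))
  expect_true(m$cgi_context %in% c("island", "shore", "shelf", "open_sea"))
  expect_gte(m$pos, 1L)
})

test_that("manifest invariants hold on a full-size scan", {
  m <- simulateManifest(20000, 1200, seed = 7)
  expect_equal(nrow(m), 20000L)
  # unique probe ids and unique positions per chromosome
  expect_false(anyDuplicated(m$probe_id) > 0)
  expect_false(anyDuplicated(paste(m$chrom, m$pos)) > 0)
  expect_true(all(m$pos >= 1))
  # every non-IGR probe names an existing gene; IGR probes name none
  geneUniverse <- unique(m$genes[m$genes != ""])
  expect_true(all(m$genes[m$feature != "IGR"] %in% geneUniverse))
  expect_true(all(m$genes[m$feature == "IGR"] == ""))
  expect_true(all(m$feature[m$genes == ""] == "IGR"))
  # categorical labels are all valid
  expect_true(all(m$feature %in% c("TSS", "5'UTR", "1stExon", "Body",
                                   "3'UTR", "IGR")))
  expect_true(all(m$cgi_context %in% c("island", "shore", "shelf",
                                       "open_sea")))
  # roughly 3% of probes flagged
  flagFrac <- mean(m$flags != "")
  expect_gt(flagFrac, 0.01)
  expect_lt(flagFrac, 0.06)
  # skewed per-gene coverage: about half of genes carry only 1-2 probes
  perGene <- table(m$genes[m$genes != ""])
  fracLight <- mean(perGene <= 2)
  expect_gt(fracLight, 0.3)
  expect_lt(fracLight, 0.7)
  expect_equal(length(perGene), 1200L)
})

test_that("generators are deterministic given the seed", {
  m1 <- simulateManifest(2000, 150, seed = 42)
  m2 <- simulateManifest(2000, 150, seed = 42)
  expect_identical(m1, m2)
  d <- progressionDesign()
  b1 <- simulateBetaSet(m1, d, nPlanted = 100, seed = 5)
  b2 <- simulateBetaSet(m1, d, nPlanted = 100, seed = 5)
  expect_identical(betaValues(b1$betaSet), betaValues(b2$betaSet))
  expect_identical(plantedDMPs(b1$truth), plantedDMPs(b2$truth))
  e1 <- suppressWarnings(
    simulateExpression(b1$truth, m1, d, nPerScenario = 10, seed = 3))
  e2 <- suppressWarnings(
    simulateExpression(b2$truth, m1, d, nPerScenario = 10, seed = 3))
  expect_identical(SummarizedExperiment::assay(e1$expression, "counts"),
                   SummarizedExperiment::assay(e2$expression, "counts"))
  c1 <- simulateCohort(e1$truth, m1, nPatients = 5, seed = 9)
  c2 <- simulateCohort(e2$truth, m1, nPatients = 5, seed = 9)
  expect_identical(c1$outcomes, c2$outcomes)
  expect_identical(c1$ratios, c2$ratios)
})

test_that("generator argument errors are raised", {
  expect_error(simulateManifest(0, 1), "positive")
  expect_error(simulateManifest(10, 0), "positive")
  expect_error(simulateManifest(5, 10), "nProbes >= nGenes")
  m <- simulateManifest(200, 20, seed = 1)
  d <- progressionDesign()
  expect_error(simulateBetaSet(m, d, delta = 0), "delta")
  expect_error(simulateBetaSet(m, d, delta = -0.1), "delta")
  expect_error(studyDesign(c("A", "B"), replicates = 1), "replicates")
  tr <- simulateBetaSet(m, d, nPlanted = 10, seed = 1)$truth
  expect_error(simulateCohort(tr, m, nPatients = 2), "3 patients")
})

test_that("beta values stay strictly inside the unit interval", {
  st <- sharedStudy()
  b <- betaValues(st$betaSet)
  expect_true(all(b > 0 & b < 1))
})

test_that("planted truth is consistent with the manifest", {
  st <- sharedStudy()
  pd <- plantedDMPs(st$truth)
  expect_true(all(pd$probe_id %in% st$manifest$probe_id))
  expect_true(all(pd$direction %in% c("hyper", "hypo")))
  expect_setequal(unique(pd$comparison),
                  comparisonTable(st$design)$name)
})

test_that("null design produces an empty truth table and rare calls", {
  m <- simulateManifest(5000, 400, seed = 3)
  d <- studyDesign(c("LN", "CRPC16D"))
  bs <- simulateBetaSet(m, d, nPlanted = 0, seed = 8)
  expect_equal(nrow(plantedDMPs(bs$truth)), 0L)
  dmp <- callDMPs(bs$betaSet, "CRPC16D", "LN")
  # nominal FDR 0.01 with no true effects: positives should be very rare
  rate <- nrow(dmpRecords(dmp)) / nTested(dmp)
  expect_lte(rate, 0.01 + 3 * sqrt(0.01 * 0.99 / nTested(dmp)))
})

test_that("expression counts are non-negative integers", {
  st <- sharedStudy()
  ex <- simulateExpression(st$truth, st$manifest, st$design,
                           nPerScenario = 20, seed = 4)
  counts <- SummarizedExperiment::assay(ex$expression, "counts")
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
  expect_equal(sort(unique(plantedDEGs(ex$truth)$scenario)),
               c("a", "b", "c", "d"))
})

test_that("zero scenario genes yields an empty DEG truth and a quiet caller", {
  st <- sharedStudy()
  ex <- simulateExpression(st$truth, st$manifest, st$design,
                           nPerScenario = 0, seed = 4)
  expect_equal(nrow(plantedDEGs(ex$truth)), 0L)
  degs <- callDEGs(ex$expression, "NE42D", "CRPC16D")
  # with no planted expression effects the caller should find few genes
  expect_lte(nrow(degs), ceiling(0.02 * attr(degs, "n_tested")))
})

test_that("scenario demand beyond the gene pool is an error", {
  m <- simulateManifest(300, 30, seed = 1)
  d <- progressionDesign()
  tr <- simulateBetaSet(m, d, nPlanted = 50, seed = 1)$truth
  expect_error(simulateExpression(tr, m, d, nPerScenario = 100),
               "exceeds")
})

test_that("noise-free ratio-driven cohort gives exactly rho = -1", {
  st <- sharedStudy()
  co <- simulateCohort(st$truth, st$manifest, nPatients = 10,
                       ttpNoiseSd = 0, ttpDriver = "ratio", seed = 2)
  ct <- correlateTTP(co$ratios, co$outcomes)
  expect_equal(unname(ct$rho), -1, tolerance = 1e-12)
})

test_that("zero planted signal gives an uninformative cohort", {
  st <- sharedStudy()
  co <- simulateCohort(st$truth, st$manifest, nPatients = 20,
                       signal = rep(0, 20), seed = 6)
  expect_true(all(patientSignal(co$truth) == 0))
  ct <- correlateTTP(co$ratios, co$outcomes)
  expect_lt(abs(ct$rho), 0.5)
  # seeded overlap absent: the resampling z for one patient is unremarkable
  q <- plantedDMPs(st$truth)
  q <- q[q$comparison == "NE42D_vs_CRPC16D" & q$direction == "hyper", ]
  q <- merge(q["probe_id"], st$manifest, by = "probe_id")
  rs <- resamplingNull(q, st$manifest, co$patients[[1]], nIter = 300,
                       seed = 3)
  expect_lt(abs(rs@z), 4)
})

test_that("cohort DMR geometry respects the configured ranges", {
  st <- sharedStudy()
  co <- simulateCohort(st$truth, st$manifest, nPatients = 4,
                       nDmrRange = c(50, 80), widthRange = c(100, 500),
                       seed = 13)
  for (p in co$patients) {
    r <- dmrRegions(p)
    expect_true(length(r) >= 50 && length(r) <= 80)
    expect_true(all(GenomicRanges::width(r) >= 100 &
                      GenomicRanges::width(r) <= 501))
    expect_true(all(r$direction %in% c("hyper", "hypo")))
  }
  expect_true(all(co$outcomes$ttp_days > 0))
})
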