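mkAnnotated <- function(genes, features, directions,
                        comparison = "A_vs_B") {
  n <- length(genes)
  ids <- sprintf("p%03d", seq_len(n))
  man <- mkManifest(ids, pos = seq_len(n) * 10, genes = genes,
                    feature = features)
  annotateDMPs(mkDMPSet(ids, directions, comparison = comparison), man)
}

test_that("gene summaries enumerate region-direction counts", {
  ann <- mkAnnotated(genes = c("G1", "G1", "G1", "G2"),
                     features = c("TSS", "TSS", "Body", "TSS"),
                     directions = c("hyper", "hyper", "hypo", "hypo"))
  s <- geneDMPSummary(ann)
  g1 <- s[s$gene == "G1", ]
  expect_equal(g1$n_tss_hyper, 2L)
  expect_equal(g1$n_tss_hypo, 0L)
  expect_equal(g1$n_body_hypo, 1L)
  expect_equal(g1$n_total, 3L)
  # the >= 3 TSS filter excludes G1 (2 TSS DMPs) and G2 (1)
  expect_equal(nrow(filterGeneSummaries(s, minTss = 3)), 0L)
  expect_equal(filterGeneSummaries(s, minTss = 2)$gene, "G1")
})

test_that("probes annotated to two genes count for both genes", {
  man <- mkManifest(c("p1", "p2"), pos = c(5, 15),
                    genes = c("G1,G2", "G1"),
                    feature = c("TSS", "Body"))
  ann <- annotateDMPs(mkDMPSet(c("p1", "p2"), c("hyper", "hyper")), man)
  s <- geneDMPSummary(ann)
  expect_equal(s$n_tss_hyper[s$gene == "G1"], 1L)
  expect_equal(s$n_tss_hyper[s$gene == "G2"], 1L)
  expect_equal(s$n_total[s$gene == "G1"], 2L)
})

test_that("planted TSS-heavy genes pass the TSS filter", {
  st <- sharedStudy()
  pd <- plantedDMPs(st$truth)
  pd <- pd[pd$comparison == "NE42D_vs_LN", ]
  perGene <- table(pd$gene[pd$feature == "TSS" & pd$direction == "hyper"])
  target <- names(perGene[perGene >= 3])
  if (length(target)) {
    ann <- annotateDMPs(callDMPs(st$betaSet, "NE42D", "LN"), st$manifest)
    s <- filterGeneSummaries(geneDMPSummary(ann), minTss = 3)
    expect_gt(mean(target %in% s$gene), 0.8)
  } else skip("no gene with 3+ planted TSS probes in this fixture")
})

test_that("net methylation score evaluates the pseudocounted log ratio", {
  s <- data.frame(gene = c("G1", "G2", "G3"), comparison = "x",
                  n_tss_hyper = 0L, n_tss_hypo = 0L, n_body_hyper = 0L,
                  n_body_hypo = 0L,
                  n_hyper = c(8L, 3L, 6L), n_hypo = c(1L, 3L, 0L),
                  n_total = c(9L, 6L, 6L))
  sc <- netMethylationScore(s, minDmps = 6)
  expect_equal(sc$score[sc$gene == "G1"], log2(8.5 / 1.5))
  expect_equal(sc$net_class[sc$gene == "G1"], "net_hyper")
  expect_equal(sc$score[sc$gene == "G2"], 0)
  expect_equal(sc$net_class[sc$gene == "G2"], "balanced")
  expect_equal(sc$score[sc$gene == "G3"], log2(13))
  expect_true(is.finite(sc$score[sc$gene == "G3"]))
  # the >= threshold excludes genes below it
  s$n_total <- c(9L, 5L, 6L)
  expect_false("G2" %in% netMethylationScore(s, minDmps = 6)$gene)
  expect_true("G2" %in% netMethylationScore(s, minDmps = 5)$gene)
  expect_error(netMethylationScore(s, minDmps = 0), ">= 1")
})

test_that("the score is antisymmetric under swapping hyper and hypo", {
  set.seed(20)
  s <- data.frame(gene = sprintf("G%02d", 1:20), comparison = "x",
                  n_tss_hyper = 0L, n_tss_hypo = 0L, n_body_hyper = 0L,
                  n_body_hypo = 0L,
                  n_hyper = rpois(20, 6), n_hypo = rpois(20, 6))
  s$n_total <- s$n_hyper + s$n_hypo
  sw <- s
  sw$n_hyper <- s$n_hypo; sw$n_hypo <- s$n_hyper
  a <- netMethylationScore(s, minDmps = 1)
  b <- netMethylationScore(sw, minDmps = 1)
  m <- match(a$gene, b$gene)
  expect_equal(a$score, -b$score[m])
})

test_that("region overlap respects half-open boundaries", {
  man <- mkManifest("p1", pos = 100)
  ann <- annotateDMPs(mkDMPSet("p1", "hyper"), man)
  hit <- overlapWithRegions(ann, data.frame(chrom = "chr1", start = 99,
                                            end = 100))
  expect_equal(hit$n_hit, 1L)
  miss <- overlapWithRegions(ann, data.frame(chrom = "chr1", start = 100,
                                             end = 200))
  expect_equal(miss$n_hit, 0L)
  expect_error(overlapWithRegions(ann, data.frame(chrom = "chr1",
                                                  start = 5, end = 5)),
               "malformed")
})

test_that("direction matching restricts hits to same-trend regions", {
  man <- mkManifest(c("p1", "p2"), pos = c(50, 150))
  ann <- annotateDMPs(mkDMPSet(c("p1", "p2"), c("hyper", "hypo")), man)
  regions <- data.frame(chrom = "chr1", start = c(0, 100),
                        end = c(100, 200),
                        direction = c("hypo", "hypo"))
  loose <- overlapWithRegions(ann, regions)
  expect_equal(loose$n_hit, 2L)
  strict <- overlapWithRegions(ann, regions, directionMatch = TRUE)
  expect_equal(strict$n_hit, 1L)
  expect_equal(strict$n_hypo_hit, 1L)
  expect_equal(strict$n_hyper_hit, 0L)
})

test_that("overlap counts equal the brute-force scan on random instances", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(20:80, 1); m <- sample(5:30, 1)
    chrom <- sample(paste0("chr", 1:3), n, replace = TRUE)
    pos <- sample(1:5000, n)
    man <- mkManifest(sprintf("p%03d", 1:n), chrom = chrom, pos = pos)
    dirs <- sample(c("hyper", "hypo"), n, replace = TRUE)
    ann <- annotateDMPs(mkDMPSet(sprintf("p%03d", 1:n), dirs), man)
    st <- sample(0:4900, m)
    regions <- data.frame(chrom = sample(paste0("chr", 1:3), m, TRUE),
                          start = st,
                          end = st + sample(1:400, m, replace = TRUE))
    got <- overlapWithRegions(ann, regions)
    oracle <- bruteProbeInRegion(chrom, pos, regions)
    expect_identical(got$n_hit, sum(oracle))
    expect_identical(got$n_hyper_hit, sum(oracle & dirs == "hyper"))
    expect_identical(got$n_hypo_hit, sum(oracle & dirs == "hypo"))
  }
})

test_that("overlap is invariant to region order and adjacent splits", {
  set.seed(22)
  n <- 50
  man <- mkManifest(sprintf("p%02d", 1:n), pos = sample(1:2000, n))
  ann <- annotateDMPs(mkDMPSet(sprintf("p%02d", 1:n),
                               sample(c("hyper", "hypo"), n, TRUE)), man)
  regions <- data.frame(chrom = "chr1", start = c(0, 500, 1200),
                        end = c(400, 900, 1800))
  a <- overlapWithRegions(ann, regions)
  b <- overlapWithRegions(ann, regions[c(3, 1, 2), ])
  expect_equal(a$n_hit, b$n_hit)
  # split [500, 900) into [500, 700) + [700, 900)
  split <- data.frame(chrom = "chr1", start = c(0, 500, 700, 1200),
                      end = c(400, 700, 900, 1800))
  expect_equal(overlapWithRegions(ann, split)$n_hit, a$n_hit)
})

test_that("hypergeometric enrichment matches exact tail probabilities", {
  # 4-gene universe, 2-gene set, 2-gene query, overlap 2: p = 1/6
  res <- geneSetEnrichment(c("g1", "g2"), c("g1", "g2", "g3", "g4"),
                           list(S = c("g1", "g2")))
  expect_equal(res$p, 1 / 6)
  # query = set = universe: only one configuration, p = 1
  res2 <- geneSetEnrichment(c("g1", "g2"), c("g1", "g2"),
                            list(S = c("g1", "g2")))
  expect_equal(res2$p, 1)
  # zero overlap with large expected overlap: one-sided p near 1
  res3 <- geneSetEnrichment(paste0("a", 1:10),
                            c(paste0("a", 1:10), paste0("b", 1:10)),
                            list(S = paste0("b", 1:10)))
  expect_gt(res3$p, 0.99)
  expect_error(geneSetEnrichment("g1", character(0), list(S = "g1")),
               "empty universe")
})
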