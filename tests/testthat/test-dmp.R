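test_that("beta formula matches hand-evaluated intensities", {
  expect_equal(betaFromIntensities(0, 0), 0)
  expect_equal(betaFromIntensities(100, 0), 0.5)
  expect_equal(betaFromIntensities(900, 0), 0.9)
  expect_equal(betaFromIntensities(c(0, 100, 900), c(0, 0, 0)),
               c(0, 0.5, 0.9))
  # beta stays below 1 even at huge methylated intensity
  expect_lt(betaFromIntensities(1e9, 0), 1)
  expect_error(betaFromIntensities(-1, 5), "non-negative")
  expect_error(betaFromIntensities(5, -1), "non-negative")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bhAdjust(c(0.001, 0.02, 0.03, 0.5)),
               c(0.004, 0.04, 0.04, 0.5))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_identical(bhAdjust(numeric(0)), numeric(0))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH q values dominate p and preserve ranks", {
  set.seed(1)
  for (i in 1:20) {
    p <- runif(50)^sample(1:3, 1)
    q <- bhAdjust(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    # monotone non-decreasing in sorted p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("probe filtering removes flags and detection failures by reason", {
  ids <- sprintf("p%02d", 1:10)
  man <- mkManifest(ids, flags = c("snp", "snp", "snp,cross_reactive",
                                   rep("", 7)))
  mat <- matrix(0.5, 10, 4, dimnames = list(ids, NULL))
  bs <- mkBetaSet(mat, c("A", "A", "B", "B"), man)
  det <- matrix(0.001, 10, 4, dimnames = list(ids, colnames(betaValues(bs))))
  det["p05", 2] <- 0.5   # fails in one sample
  det["p06", 4] <- 0.02
  out <- filterProbes(bs, detectionP = det)
  expect_equal(nrow(betaValues(out)), 5L)
  log <- S4Vectors::metadata(out)$filter_log
  # p03 carries two flags: removed once, logged under both reasons
  expect_true("p03" %in% log$by_reason$snp)
  expect_true("p03" %in% log$by_reason$cross_reactive)
  expect_equal(log$n_removed, 5L)
  expect_setequal(log$by_reason$low_detection, c("p05", "p06"))
  # without detection table and with no flags: identity
  man2 <- mkManifest(ids)
  bs2 <- mkBetaSet(mat, c("A", "A", "B", "B"), man2)
  out2 <- filterProbes(bs2)
  expect_equal(rownames(betaValues(out2)), ids)
  # failing-fraction rule keeps a probe failing only 1 of 4 samples
  out3 <- filterProbes(bs, detectionP = det, maxFailFraction = 0.3)
  expect_false("p05" %in% S4Vectors::metadata(out3)$filter_log$by_reason$low_detection)
})

test_that("identical groups give an empty DMP set", {
  ids <- sprintf("p%03d", 1:50)
  set.seed(2)
  half <- matrix(runif(50 * 3), 50, 3)
  mat <- cbind(half, half)
  rownames(mat) <- ids
  bs <- mkBetaSet(mat, rep(c("A", "B"), each = 3))
  dmp <- callDMPs(bs, "A", "B")
  expect_equal(nrow(dmpRecords(dmp)), 0L)
  expect_equal(nTested(dmp), 50L)
})

test_that("delta threshold is a hard boundary regardless of significance", {
  set.seed(3)
  n <- 400
  ids <- sprintf("p%03d", 1:n)
  base <- matrix(runif(n * 6, 0.4, 0.6), n, 6, dimnames = list(ids, NULL))
  # probe 1: shift 0.19 (below cutoff), probe 2: shift 0.25 (above);
  # tiny replicate noise so both are overwhelmingly significant
  noise <- matrix(rnorm(2 * 6, 0, 0.004), 2, 6)
  base[1, ] <- 0.40 + c(0.19, 0.19, 0.19, 0, 0, 0) + noise[1, ]
  base[2, ] <- 0.40 + c(0.25, 0.25, 0.25, 0, 0, 0) + noise[2, ]
  bs <- mkBetaSet(base, rep(c("A", "B"), each = 3))
  dmp <- callDMPs(bs, "A", "B")
  rec <- dmpRecords(dmp)
  expect_false("p001" %in% rec$probe_id)
  expect_true("p002" %in% rec$probe_id)
  expect_equal(rec$direction[rec$probe_id == "p002"], "hyper")
})

test_that("swapping case and ref negates deltas and flips directions", {
  st <- sharedStudy()
  a <- callDMPs(st$betaSet, "NE42D", "CRPC16D")
  b <- callDMPs(st$betaSet, "CRPC16D", "NE42D")
  ra <- dmpRecords(a); rb <- dmpRecords(b)
  expect_setequal(ra$probe_id, rb$probe_id)
  m <- match(ra$probe_id, rb$probe_id)
  expect_equal(ra$delta_beta, -rb$delta_beta[m])
  expect_equal(ra$q, rb$q[m])
  flip <- c(hyper = "hypo", hypo = "hyper")
  expect_equal(unname(flip[ra$direction]), rb$direction[m])
})

test_that("zero-variance probes are reported as non-significant, not NaN", {
  ids <- sprintf("p%02d", 1:20)
  set.seed(4)
  mat <- matrix(runif(20 * 4), 20, 4, dimnames = list(ids, NULL))
  mat[1, ] <- 0.5  # constant everywhere: delta 0, variance 0
  bs <- mkBetaSet(mat, rep(c("A", "B"), each = 2))
  dmp <- callDMPs(bs, "A", "B")
  expect_false("p01" %in% dmpRecords(dmp)$probe_id)
  # welch backend tolerates it too
  dmp2 <- callDMPs(bs, "A", "B", method = "welch")
  expect_false("p01" %in% dmpRecords(dmp2)$probe_id)
})

test_that("fewer than two replicates is an error", {
  ids <- c("p1", "p2")
  mat <- matrix(0.5, 2, 3, dimnames = list(ids, NULL))
  bs <- mkBetaSet(mat, c("A", "A", "B"))
  expect_error(callDMPs(bs, "A", "B"), ">= 2 replicates")
})

test_that("moderated t has the stated limiting behaviour", {
  set.seed(5)
  n <- 300
  ids <- sprintf("p%03d", 1:n)
  mat <- matrix(plogis(rnorm(n * 6, 0, 1)), n, 6,
                dimnames = list(ids, NULL))
  bs <- mkBetaSet(mat, rep(c("A", "B"), each = 3))
  b <- betaValues(bs)
  i1 <- 1:3; i2 <- 4:6
  delta <- rowMeans(b[, i1]) - rowMeans(b[, i2])
  v1 <- apply(b[, i1], 1, var); v2 <- apply(b[, i2], 1, var)
  s2 <- (2 * v1 + 2 * v2) / 4
  # prior df 0: ordinary pooled two-sample t
  d0 <- callDMPs(bs, "A", "B", priorDf = 0, fdrCut = 1.1, deltaCut = 0)
  tPooled <- delta / sqrt(s2 * (1 / 3 + 1 / 3))
  rec <- dmpRecords(d0)
  expect_equal(rec$t[match(ids, rec$probe_id)], unname(tPooled),
               tolerance = 1e-10)
  # prior df Inf with a fixed prior variance: every probe shares it
  dInf <- callDMPs(bs, "A", "B", priorDf = Inf, priorVar = 0.02,
                   fdrCut = 1.1, deltaCut = 0)
  rec <- dmpRecords(dInf)
  tShared <- delta / sqrt(0.02 * (2 / 3))
  expect_equal(rec$t[match(ids, rec$probe_id)], unname(tShared),
               tolerance = 1e-10)
})

test_that("variance shrinkage agrees with the limma empirical Bayes fit", {
  library(limma)
  set.seed(6)
  n <- 2000
  s2 <- rchisq(n, 4) / 4 * 0.01
  fit <- methylProgression:::.squeezeVariances(s2, 4)
  sq <- limma::squeezeVar(s2, df = 4)
  expect_equal(fit$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(fit$s02, sq$var.prior, tolerance = 1e-6)
  expect_equal(fit$s2post, sq$var.post, tolerance = 1e-8)
})

test_that("moderated t matches a limma fit on beta values", {
  library(limma)
  set.seed(7)
  n <- 500
  ids <- sprintf("p%03d", 1:n)
  mat <- matrix(plogis(rnorm(n * 6, 0, 1.2)), n, 6,
                dimnames = list(ids, NULL))
  mat[1:40, 1:3] <- pmin(mat[1:40, 1:3] + 0.3, 0.99)
  bs <- mkBetaSet(mat, rep(c("A", "B"), each = 3))
  mine <- dmpRecords(callDMPs(bs, "A", "B", fdrCut = 1.1, deltaCut = 0))
  design <- cbind(Intercept = 1, A = rep(c(1, 0), each = 3))
  lf <- limma::eBayes(limma::lmFit(mat, design))
  tl <- lf$t[, "A"]
  m <- match(ids, mine$probe_id)
  expect_equal(mine$t[m], unname(tl), tolerance = 1e-8)
  expect_equal(mine$p[m], unname(lf$p.value[, "A"]), tolerance = 1e-8)
})

test_that("Ward clustering separates groups and keeps replicates together", {
  # separable two-group case: labels equal groups up to permutation
  set.seed(8)
  g1 <- matrix(rnorm(50 * 3, 0.2, 0.01), 50, 3)
  g2 <- matrix(rnorm(50 * 3, 0.8, 0.01), 50, 3)
  mat <- cbind(g1, g2)
  rownames(mat) <- sprintf("p%02d", 1:50)
  bs <- mkBetaSet(mat, rep(c("A", "B"), each = 3))
  cl <- clusterSamples(bs)
  expect_s3_class(cl$tree, "hclust")
  expect_equal(length(unique(cl$labels[1:3])), 1L)
  expect_equal(length(unique(cl$labels[4:6])), 1L)
  expect_false(cl$labels[1] == cl$labels[4])
  # replicate triples of the synthetic study are monophyletic at k = groups
  st <- sharedStudy()
  cls <- clusterSamples(st$betaSet)
  grp <- sampleGroups(st$betaSet)
  purity <- tapply(cls$labels, grp, function(v) length(unique(v)))
  expect_true(all(purity == 1L))
  expect_equal(length(unique(cls$labels)), 5L)
})

test_that("duplicate samples merge at height zero", {
  mat <- matrix(runif(30), 10, 3, dimnames = list(sprintf("p%02d", 1:10),
                                                  NULL))
  mat[, 2] <- mat[, 1]
  bs <- mkBetaSet(mat, c("A", "A", "B"))
  cl <- clusterSamples(bs, k = 2)
  expect_equal(min(cl$tree$height), 0)
})

test_that("probe subset disjoint from the matrix is an error", {
  mat <- matrix(runif(20), 10, 2,
                dimnames = list(sprintf("p%02d", 1:10), NULL))
  bs <- mkBetaSet(mat, c("A", "B"))
  expect_error(clusterSamples(bs, probeSubset = c("x1", "x2")), "disjoint")
})

test_that("top-DMP ranking is by min q with deterministic tie-breaks", {
  s1 <- mkDMPSet(c("p1", "p2", "p3"), c("hyper", "hypo", "hyper"),
                 delta_beta = c(0.30, -0.25, 0.40),
                 q = c(1e-8, 1e-3, 1e-3), comparison = "X_vs_Z")
  s2 <- mkDMPSet(c("p2", "p4"), c("hypo", "hyper"),
                 delta_beta = c(-0.50, 0.22), q = c(5e-3, 2e-2),
                 comparison = "Y_vs_Z")
  # n larger than the pool returns everything, best first
  ord <- topDMPOrder(list(s1, s2), n = 1000)
  expect_equal(length(ord), 4L)
  expect_equal(ord[1], "p1")
  # p2's min q (1e-3) ties p3; p2 wins on larger |delta| (0.5 vs 0.4)
  expect_equal(ord[2], "p2")
  expect_equal(ord[3], "p3")
  expect_equal(topDMPOrder(list(s1, s2), n = 1), "p1")
  expect_error(topDMPOrder(list(s1), n = 0), "positive")
})

test_that("identity normalization hook leaves data unchanged", {
  st <- sharedStudy()
  expect_identical(betaValues(normalizeBeta(st$betaSet)),
                   betaValues(st$betaSet))
  sq <- normalizeBeta(st$betaSet, fun = function(v) v^2)
  expect_equal(betaValues(sq), betaValues(st$betaSet)^2)
  expect_error(normalizeBeta(st$betaSet, fun = function(v) v * 2),
               "range")
})
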