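#' Beta value from array intensities
#'
#' The methylation fraction estimate used throughout the package:
#' \deqn{\beta = M / (U + M + 100)}
#' where \eqn{M} and \eqn{U} are the methylated and unmethylated allele
#' intensities and the constant 100 regularises low-intensity probes.
#'
#' @param methylated,unmethylated non-negative intensities (vectorised).
#' @return beta values in \[0, 1).
#' @examples
#' betaFromIntensities(100, 0)  # 0.5
#' @export
betaFromIntensities <- function(methylated, unmethylated) {
  if (any(methylated < 0) || any(unmethylated < 0))
    stop("intensities must be non-negative")
  methylated / (unmethylated + methylated + 100)
}

#' Filter probes by exclusion flags and detection p values
#'
#' Removes probes that carry any exclusion flag (SNP-related,
#' cross-reactive, multi-hit) in the manifest, and -- when a detection
#' p-value table is supplied -- probes whose detection p exceeds `pCut` in
#' more than `maxFailFraction` of samples (the default 0 removes a probe if
#' any sample fails, the strictest rule).
#'
#' @param x a [BetaSet-class] carrying its manifest as `rowData` (or pass
#'   `manifest`).
#' @param detectionP optional numeric matrix of per-probe, per-sample
#'   detection p values, rows matched to probes by rowname.
#' @param pCut detection p threshold (default 0.01).
#' @param maxFailFraction largest tolerated fraction of failing samples per
#'   probe (default 0: any failure removes the probe).
#' @param manifest optional manifest data.frame overriding the `rowData`.
#' @return the surviving [BetaSet-class]; the removal log is attached as
#'   `metadata(x)$filter_log`, a list with per-reason probe id vectors (a
#'   probe flagged for two reasons appears under both) and a summary
#'   data.frame. An empty result triggers a warning, not an error.
#' @export
filterProbes <- function(x, detectionP = NULL, pCut = 0.01,
                         maxFailFraction = 0, manifest = NULL) {
  if (is.null(manifest)) manifest <- probeManifest(x)
  if (is.null(manifest) || is.null(manifest$flags))
    stop("no manifest with a 'flags' column available")
  ids <- rownames(betaValues(x))
  mrow <- match(ids, manifest$probe_id)
  if (anyNA(mrow))
    stop("probes absent from manifest: ",
         paste(utils::head(ids[is.na(mrow)], 5L), collapse = ", "))
  flags <- manifest$flags[mrow]

  byReason <- lapply(stats::setNames(nm = PROBE_FLAGS), function(f) {
    ids[vapply(strsplit(flags, ","), function(v) f %in% v, logical(1))]
  })
  drop <- unique(unlist(byReason, use.names = FALSE))

  if (!is.null(detectionP)) {
    dp <- as.matrix(detectionP)[ids, , drop = FALSE]
    failFrac <- rowMeans(dp > pCut)
    det <- ids[failFrac > maxFailFraction]
    byReason$low_detection <- det
    drop <- unique(c(drop, det))
  } else byReason$low_detection <- character(0)

  keep <- setdiff(ids, drop)
  if (!length(keep))
    warning("all probes removed by filtering")
  out <- x[match(keep, ids), ]
  metadata(out)$filter_log <- list(
    by_reason = byReason,
    summary = data.frame(reason = names(byReason),
                         n = vapply(byReason, length, integer(1)),
                         row.names = NULL),
    n_removed = length(drop), n_kept = length(keep))
  out
}

#' Identity (or user-supplied) normalization hook
#'
#' The pipeline's normalization step. The default is the identity: the
#' simulated data carry no probe-type intensity bias, so no quantile or
#' type-II correction is applied. A user-supplied per-sample transform can
#' be plugged in; the result is validated back into \[0, 1\].
#'
#' @param x a [BetaSet-class].
#' @param fun optional function applied to each sample's beta column;
#'   must return values in \[0, 1\].
#' @return a [BetaSet-class].
#' @export
normalizeBeta <- function(x, fun = NULL) {
  if (is.null(fun)) return(x)
  b <- betaValues(x)
  for (j in seq_len(ncol(b))) b[, j] <- fun(b[, j])
  if (any(b < 0 | b > 1)) stop("normalization left the [0, 1] range")
  assays(x)$beta <- b
  x
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false discovery rate adjustment
#' (\eqn{q_{(i)} = \min_{j \ge i} m \, p_{(j)} / j}, capped at 1),
#' delegated to [stats::p.adjust()].
#'
#' @param p p values in \[0, 1\].
#' @return q values, same order as the input.
#' @examples
#' bhAdjust(c(0.001, 0.02, 0.03, 0.5))  # 0.004 0.040 0.040 0.500
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

rowVarsFast <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

## Empirical-Bayes variance shrinkage: method-of-moments fit of a scaled
## inverse-chi-square prior on the per-probe variances (on the log scale),
## then posterior (squeezed) variances. Probes with zero sample variance are
## shrunk toward the prior but excluded from the moment fit.
.squeezeVariances <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L)
    return(list(d0 = 0, s02 = mean(s2), s2post = s2))
  z <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  m <- mean(z)
  v <- stats::var(z) - trigamma(df / 2)
  if (is.na(v) || v <= 0) {
    # no excess dispersion beyond sampling noise: infinite prior df, and
    # the common variance is the plain average
    d0 <- Inf
    s02 <- mean(s2[ok])
  } else {
    d0 <- 2 * .trigammaInverse(v)
    s02 <- exp(m + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02, s2post = .posteriorVar(s2, df, d0, s02))
}

.posteriorVar <- function(s2, df, d0, s02) {
  if (!is.finite(d0)) rep(s02, length(s2))
  else if (d0 == 0) s2
  else (d0 * s02 + df * s2) / (d0 + df)
}

## Newton solve of trigamma(x) = y for x > 0.
.trigammaInverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Call differentially methylated probes for one comparison
#'
#' Per probe, computes the group-mean beta difference
#' \eqn{\Delta\beta = \bar\beta_{case} - \bar\beta_{ref}} and a moderated t
#' statistic with empirical-Bayes shrunken pooled variance (prior estimated
#' across probes by method of moments; see Details of the package
#' vignette). Two-sided p values use the t distribution with
#' prior-augmented degrees of freedom; Benjamini-Hochberg adjustment runs
#' across all tested probes. Records passing `q < fdrCut` and
#' `|delta beta| >= deltaCut` are returned, with direction `hyper` when
#' the case group is more methylated.
#'
#' A probe with zero variance in both groups and zero delta is reported as
#' non-significant, never NaN.
#'
#' @param x a (filtered) [BetaSet-class].
#' @param case,ref group labels to contrast (each needs >= 2 replicates).
#' @param name comparison name (default `"<case>_vs_<ref>"`).
#' @param fdrCut,deltaCut call thresholds (defaults 0.01 and 0.2).
#' @param method `"moderated"` (empirical-Bayes pooled t, default) or
#'   `"welch"` (plain Welch t, no shrinkage).
#' @param priorDf,priorVar optional overrides of the estimated prior degrees
#'   of freedom / prior variance (moderated method only); `priorDf = 0`
#'   recovers the ordinary pooled t, `priorDf = Inf` gives every probe the
#'   prior variance.
#' @return a [DMPSet-class]; `nTested()` on the result gives the BH family
#'   size (all probes tested), `dmpRecords()` the passing records.
#' @export
callDMPs <- function(x, case, ref, name = paste0(case, "_vs_", ref),
                     fdrCut = 0.01, deltaCut = 0.2,
                     method = c("moderated", "welch"),
                     priorDf = NULL, priorVar = NULL) {
  method <- match.arg(method)
  g <- sampleGroups(x)
  i1 <- which(g == case); i2 <- which(g == ref)
  if (length(i1) < 2L || length(i2) < 2L)
    stop("both groups need >= 2 replicates (", case, ": ", length(i1),
         ", ", ref, ": ", length(i2), ")")
  b <- betaValues(x)
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(b[, i1, drop = FALSE])
  m2 <- rowMeans(b[, i2, drop = FALSE])
  delta <- m1 - m2
  v1 <- rowVarsFast(b[, i1, drop = FALSE])
  v2 <- rowVarsFast(b[, i2, drop = FALSE])

  if (method == "moderated") {
    df <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    if (is.null(priorDf)) {
      fit <- .squeezeVariances(s2, df)
    } else {
      s02 <- if (is.null(priorVar)) {
        est <- .squeezeVariances(s2, df); est$s02
      } else priorVar
      fit <- list(d0 = priorDf, s02 = s02,
                  s2post = .posteriorVar(s2, df, priorDf, s02))
    }
    se <- sqrt(fit$s2post * (1 / n1 + 1 / n2))
    # posterior df, capped at the pooled residual df across probes (the
    # prior cannot carry more information than the data that built it)
    dfTotal <- min(df + fit$d0, length(delta) * df)
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    num <- (v1 / n1 + v2 / n2)^2
    den <- (v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)
    dfTotal <- ifelse(den > 0, num / den, n1 + n2 - 2)
  }

  t <- delta / se
  zeroSe <- !is.finite(t)
  t[zeroSe & delta == 0] <- 0
  t[zeroSe & delta != 0] <- sign(delta[zeroSe & delta != 0]) * Inf
  if (length(dfTotal) == 1L) dfTotal <- rep(dfTotal, length(t))
  p <- 2 * stats::pt(-abs(t), df = dfTotal)
  p[t == 0 & zeroSe] <- 1
  q <- stats::p.adjust(p, method = "BH")

  pass <- which(q < fdrCut & abs(delta) >= deltaCut)
  rec <- data.frame(probe_id = rownames(b)[pass], delta_beta = delta[pass],
                    t = t[pass], p = p[pass], q = q[pass],
                    direction = ifelse(delta[pass] > 0, "hyper", "hypo"),
                    stringsAsFactors = FALSE)
  rec <- rec[order(rec$q, -abs(rec$delta_beta), rec$probe_id), ]
  rownames(rec) <- NULL
  newDMPSet(name, case, ref, rec, fdrCut, deltaCut, nrow(b))
}

#' Call DMPs for every comparison of a design
#'
#' @param x a [BetaSet-class].
#' @param design a [StudyDesign-class].
#' @param ... passed to [callDMPs()].
#' @return named list of [DMPSet-class], one per comparison.
#' @export
callDMPsAll <- function(x, design, ...) {
  cmp <- comparisonTable(design)
  out <- vector("list", nrow(cmp))
  names(out) <- cmp$name
  for (i in seq_len(nrow(cmp)))
    out[[i]] <- callDMPs(x, cmp$case[i], cmp$ref[i], cmp$name[i], ...)
  out
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering of the samples with Ward linkage
#' (`hclust(method = "ward.D2")`) on Euclidean distances over the chosen
#' probes -- the standard unsupervised view of replicate coherence and
#' between-line divergence.
#'
#' @param x a [BetaSet-class] with >= 2 samples.
#' @param probeSubset optional probe ids to cluster on (e.g. top DMPs);
#'   must intersect the matrix.
#' @param k number of flat clusters to cut (default: number of groups).
#' @return list with `tree` (an [stats::hclust]) and `labels` (named flat
#'   cluster labels from [stats::cutree()]).
#' @export
clusterSamples <- function(x, probeSubset = NULL, k = NULL) {
  b <- betaValues(x)
  if (ncol(b) < 2L) stop("need at least 2 samples")
  if (!is.null(probeSubset)) {
    sel <- intersect(probeSubset, rownames(b))
    if (!length(sel)) stop("probe subset disjoint from the matrix")
    b <- b[sel, , drop = FALSE]
  }
  tree <- stats::hclust(stats::dist(t(b)), method = "ward.D2")
  if (is.null(k)) k <- length(unique(sampleGroups(x)))
  labels <- stats::cutree(tree, k = k)
  list(tree = tree, labels = labels)
}

#' Rank probes across comparisons for heatmap display
#'
#' Ranks the union of called probes by their minimum q across the supplied
#' DMP sets, breaking ties by the largest |delta beta| and then by probe id
#' (deterministic output), and returns the top `n` -- the usual "top 1000
#' DMPs" heatmap ordering.
#'
#' @param dmpSets list of [DMPSet-class] objects with a non-empty union.
#' @param n how many probes to return (default 1000).
#' @return character vector of probe ids, best first.
#' @export
topDMPOrder <- function(dmpSets, n = 1000) {
  if (n <= 0) stop("n must be positive")
  if (inherits(dmpSets, "DMPSet")) dmpSets <- list(dmpSets)
  rec <- do.call(rbind, lapply(dmpSets, function(s)
    dmpRecords(s)[, c("probe_id", "delta_beta", "q")]))
  if (is.null(rec) || !nrow(rec)) stop("union of DMP sets is empty")
  minQ <- vapply(split(rec$q, rec$probe_id), min, numeric(1))
  maxD <- vapply(split(abs(rec$delta_beta), rec$probe_id), max, numeric(1))
  ids <- names(minQ)
  ord <- order(minQ, -maxD, ids)
  utils::head(ids[ord], n)
}
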