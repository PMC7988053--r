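#' Simulate a toy methylation-array probe manifest
#'
#' Lays `nProbes` CpG probes on a toy genome (default 3 chromosomes of 10 Mb)
#' with `nGenes` annotated genes. Each gene receives a promoter/TSS window
#' (0--1500 bp upstream of its start), 5'UTR, first exon, body and 3'UTR
#' spans; probes are assigned to these feature classes or to intergenic
#' space (IGR). CpG-island context is derived from island placement: probes
#' inside an island are `island`, within 2 kb `shore`, within 2--4 kb
#' `shelf`, and `open_sea` beyond. About `flagRate` of probes carry
#' exclusion flags (SNP-related, cross-reactive or multi-hit), emulating the
#' standard array blacklists.
#'
#' Per-gene probe counts are deliberately skewed: roughly half of the genes
#' carry only 1--2 probes, mirroring how unevenly an array samples the
#' genome's ~28 million CpG sites across genes.
#'
#' @param nProbes,nGenes number of probes and genes (`nProbes >= nGenes >= 1`).
#' @param seed integer seed; identical seeds give identical manifests.
#' @param nChrom,chromLength toy genome geometry.
#' @param geneProbeFraction target fraction of probes annotated to a gene.
#' @param flagRate fraction of probes carrying at least one exclusion flag.
#' @param islandGeneFraction fraction of gene promoters covered by a CpG
#'   island.
#' @return data.frame with columns `probe_id`, `chrom`, `pos` (1-based CpG
#'   coordinate), `strand`, `genes` (comma-joined symbols, `""` for IGR),
#'   `feature`, `cgi_context`, `flags` (comma-joined, `""` if none). The
#'   chromosome lengths are attached as `attr(, "chromLengths")`.
#' @examples
#' m <- simulateManifest(500, 40, seed = 1)
#' table(m$feature)
#' @export
simulateManifest <- function(nProbes, nGenes, seed = 1L, nChrom = 3L,
                             chromLength = 1e7, geneProbeFraction = 0.75,
                             flagRate = 0.03, islandGeneFraction = 0.6) {
  if (length(nProbes) != 1L || length(nGenes) != 1L ||
      !is.finite(nProbes) || !is.finite(nGenes) ||
      nProbes < 1 || nGenes < 1)
    stop("nProbes and nGenes must be positive counts")
  if (nProbes < nGenes)
    stop("need nProbes >= nGenes")
  nProbes <- as.integer(nProbes); nGenes <- as.integer(nGenes)
  set.seed(as.integer(seed))

  chroms <- paste0("chr", seq_len(nChrom))
  chromLengths <- stats::setNames(rep(chromLength, nChrom), chroms)

  ## -- gene geometry: non-overlapping slots per chromosome ----------------
  geneChrom <- rep_len(chroms, nGenes)
  geneId <- sprintf("GENE%05d", seq_len(nGenes))
  geneStart <- integer(nGenes); geneEnd <- integer(nGenes)
  for (ch in chroms) {
    idx <- which(geneChrom == ch)
    ng <- length(idx)
    if (!ng) next
    slot <- (chromLength - 4000) / ng
    if (slot < 5500)
      stop("toy genome too small for ", nGenes, " genes; increase ",
           "chromLength or nChrom")
    maxLen <- min(8000, slot - 3500)
    len <- 2000 + round(stats::runif(ng) * (maxLen - 2000))
    off <- round(stats::runif(ng) * (slot - len - 2600))
    geneStart[idx] <- as.integer(2000 + (seq_len(ng) - 1L) * slot + off)
    geneEnd[idx] <- as.integer(geneStart[idx] + len)
  }

  ## -- per-gene probe counts: skewed, ~half the genes get only 1-2 --------
  nGeneProbes <- min(nProbes, max(nGenes, round(geneProbeFraction * nProbes)))
  counts <- .skewedGeneCounts(nGenes, nGeneProbes)

  ## -- gene probe features and positions ----------------------------------
  featProb <- c(TSS = 0.30, `5'UTR` = 0.10, `1stExon` = 0.10,
                Body = 0.40, `3'UTR` = 0.10)
  gIdx <- rep(seq_len(nGenes), counts)
  feat <- sample(names(featProb), length(gIdx), replace = TRUE,
                 prob = featProb)
  s <- geneStart[gIdx]; e <- geneEnd[gIdx]
  lo <- ifelse(feat == "TSS", s - 1500L,
        ifelse(feat == "5'UTR", s,
        ifelse(feat == "1stExon", s + 200L,
        ifelse(feat == "Body", s + 600L, e - 199L))))
  hi <- ifelse(feat == "TSS", s - 1L,
        ifelse(feat == "5'UTR", s + 199L,
        ifelse(feat == "1stExon", s + 599L,
        ifelse(feat == "Body", e - 200L, e))))
  gpPos <- lo + as.integer(floor(stats::runif(length(gIdx)) * (hi - lo + 1L)))

  genePart <- data.frame(chrom = geneChrom[gIdx], pos = gpPos,
                         genes = geneId[gIdx], feature = feat,
                         stringsAsFactors = FALSE)

  ## -- intergenic probes: rejection-sample outside gene neighbourhoods ----
  nIGR <- nProbes - nrow(genePart)
  igrPart <- NULL
  if (nIGR > 0) {
    occupied <- GRanges(geneChrom,
                        IRanges(pmax(1L, geneStart - 2000L), geneEnd + 500L))
    got <- data.frame(chrom = character(), pos = integer())
    while (nrow(got) < nIGR) {
      m <- 2L * (nIGR - nrow(got)) + 10L
      cch <- sample(chroms, m, replace = TRUE)
      cpos <- 1L + as.integer(floor(stats::runif(m) * (chromLength - 1)))
      cand <- GRanges(cch, IRanges(cpos, cpos))
      keep <- countOverlaps(cand, occupied) == 0L
      got <- rbind(got, data.frame(chrom = cch[keep], pos = cpos[keep]))
    }
    got <- got[seq_len(nIGR), ]
    igrPart <- data.frame(chrom = got$chrom, pos = got$pos, genes = "",
                          feature = "IGR", stringsAsFactors = FALSE)
  }

  man <- rbind(genePart, igrPart)

  ## -- enforce unique positions per chromosome ----------------------------
  for (ch in chroms) {
    i <- which(man$chrom == ch)
    p <- man$pos[i]
    while (anyDuplicated(p)) {
      d <- duplicated(p)
      p[d] <- pmin(p[d] + 1L, as.integer(chromLength))
      if (all(p[d] == chromLength)) p[d] <- p[d] - sample(1e5, sum(d))
    }
    man$pos[i] <- p
  }
  man <- man[order(match(man$chrom, chroms), man$pos), ]
  rownames(man) <- NULL

  ## -- CpG islands and context --------------------------------------------
  islGene <- which(stats::runif(nGenes) < islandGeneFraction)
  isl <- GRanges(geneChrom[islGene],
                 IRanges(pmax(1L, geneStart[islGene] - 800L),
                         geneStart[islGene] + 400L))
  nExtra <- max(1L, round(0.2 * nGenes))
  exCh <- sample(chroms, nExtra, replace = TRUE)
  exSt <- 1L + as.integer(floor(stats::runif(nExtra) * (chromLength - 1100)))
  isl <- c(isl, GRanges(exCh, IRanges(exSt, exSt + 999L)))
  probeGR <- GRanges(man$chrom, IRanges(man$pos, man$pos))
  inIsl <- countOverlaps(probeGR, isl) > 0L
  nh <- GenomicRanges::distanceToNearest(probeGR, isl)
  d <- rep(Inf, nrow(man))
  d[S4Vectors::queryHits(nh)] <- S4Vectors::mcols(nh)$distance
  man$cgi_context <- ifelse(inIsl, "island",
                     ifelse(d <= 2000, "shore",
                     ifelse(d <= 4000, "shelf", "open_sea")))

  ## -- exclusion flags -----------------------------------------------------
  man$flags <- ""
  nFlag <- round(flagRate * nProbes)
  if (nFlag > 0) {
    fi <- sample(nProbes, nFlag)
    f1 <- sample(PROBE_FLAGS, nFlag, replace = TRUE)
    man$flags[fi] <- f1
    dbl <- fi[stats::runif(nFlag) < 0.1]
    for (j in dbl) {
      extra <- sample(setdiff(PROBE_FLAGS, man$flags[j]), 1L)
      man$flags[j] <- paste(man$flags[j], extra, sep = ",")
    }
  }

  man$probe_id <- sprintf("cg%08d", seq_len(nProbes))
  man$strand <- sample(c("+", "-"), nProbes, replace = TRUE)
  man <- man[, c("probe_id", "chrom", "pos", "strand", "genes", "feature",
                 "cgi_context", "flags")]
  attr(man, "chromLengths") <- chromLengths
  man
}

## Draw per-gene probe counts summing exactly to `total`, with about half of
## the genes at 1-2 probes and the rest on a heavy-tailed distribution.
.skewedGeneCounts <- function(nGenes, total) {
  stopifnot(total >= nGenes)
  if (nGenes == 1L) return(total)
  counts <- integer(nGenes)
  nLight <- floor(nGenes / 2)
  lightIdx <- sample(nGenes, nLight)
  counts[lightIdx] <- sample(1:2, nLight, replace = TRUE)
  heavyIdx <- setdiff(seq_len(nGenes), lightIdx)
  rem <- total - sum(counts)
  nh <- length(heavyIdx)
  if (rem < nh) {
    counts[heavyIdx] <- 1L
    over <- sum(counts) - total
    while (over > 0L) {
      j <- which(counts > 1L)[1L]
      counts[j] <- counts[j] - 1L
      over <- over - 1L
    }
    return(counts)
  }
  base <- 3L + stats::rnbinom(nh, size = 1.2, mu = max(rem / nh - 3, 0.5))
  base <- pmax(base, 3L)
  base <- pmax(3L, as.integer(round(base * rem / sum(base))))
  diffTot <- rem - sum(base)
  while (diffTot != 0L) {
    j <- sample.int(nh, 1L)
    if (diffTot > 0L) {
      base[j] <- base[j] + 1L; diffTot <- diffTot - 1L
    } else if (base[j] > 1L) {
      base[j] <- base[j] - 1L; diffTot <- diffTot + 1L
    }
  }
  counts[heavyIdx] <- base
  counts
}

#' Simulate a beta-value matrix with planted differential methylation
#'
#' Baseline beta values per probe are drawn from a bimodal distribution on
#' (0, 1) (mixture of mostly-unmethylated and mostly-methylated probes, as on
#' a real array). For every non-reference group, `nPlanted` probes are
#' planted with a group-mean shift of +/- `delta` on the beta scale; planting
#' is gene/feature-coherent (a planted gene gets all of its TSS probes, or
#' all of its body probes, shifted in one direction, with a fraction of
#' solitary IGR probes), so that downstream gene-level and scenario stages
#' have recoverable structure. Replicate noise is drawn on the logit scale
#' and mapped back to (0, 1), keeping every value strictly inside the unit
#' interval.
#'
#' @param manifest manifest from [simulateManifest()].
#' @param design a [StudyDesign-class]; the first group is the unplanted
#'   reference state.
#' @param nPlanted planted probes per non-reference group (0 for a null
#'   matrix).
#' @param delta planted group-mean beta shift (> 0; default 0.3, comfortably
#'   above the 0.2 call threshold).
#' @param sdLogit replicate noise standard deviation on the logit scale
#'   (default 0.12, a beta-scale replicate sd of about 0.03 at mid-range,
#'   typical of cell-line triplicates on methylation arrays).
#' @param igrFraction fraction of planting draws that take a solitary IGR
#'   probe instead of a gene feature block.
#' @param seed integer seed.
#' @return list with `betaSet` (a [BetaSet-class]) and `truth` (a
#'   [SyntheticTruth-class] whose `plantedDMPs` table gives, for every
#'   comparison in the design, the probes whose group means differ by at
#'   least `delta`, with their direction).
#' @export
simulateBetaSet <- function(manifest, design, nPlanted = 2000, delta = 0.3,
                            sdLogit = 0.12, igrFraction = 0.15, seed = 1L) {
  if (delta <= 0) stop("delta must be > 0")
  if (design@replicates < 2L) stop("need >= 2 replicates per group")
  set.seed(as.integer(seed))
  nP <- nrow(manifest)
  groups <- design@groups
  R <- design@replicates

  low <- stats::runif(nP) < 0.55
  base <- ifelse(low, stats::rbeta(nP, 2, 8), stats::rbeta(nP, 8, 2))

  offsets <- matrix(0, nP, length(groups),
                    dimnames = list(manifest$probe_id, groups))
  plantMeta <- NULL
  if (nPlanted > 0) {
    pool <- .genePlantingPool(manifest)
    for (g in groups[-1L]) {
      sel <- .selectPlanted(manifest, pool, nPlanted, igrFraction)
      offsets[sel$idx, g] <- ifelse(sel$direction == "hyper", delta, -delta)
    }
  }

  planted <- rowSums(offsets != 0) > 0
  if (any(planted)) {
    hasH <- rowSums(offsets > 0) > 0
    hasL <- rowSums(offsets < 0) > 0
    hOnly <- planted & hasH & !hasL
    lOnly <- planted & hasL & !hasH
    mixed <- planted & hasH & hasL
    base[hOnly] <- stats::runif(sum(hOnly), 0.25, 0.45)
    base[lOnly] <- stats::runif(sum(lOnly), 0.55, 0.75)
    base[mixed] <- stats::runif(sum(mixed), 0.35, 0.62)
  }

  mu <- pmin(pmax(base + offsets, 0.02), 0.98)
  beta <- matrix(0, nP, length(groups) * R)
  cn <- character(ncol(beta))
  k <- 0L
  for (gi in seq_along(groups)) for (r in seq_len(R)) {
    k <- k + 1L
    x <- stats::plogis(stats::qlogis(mu[, gi]) + stats::rnorm(nP, 0, sdLogit))
    beta[, k] <- pmin(pmax(x, 1e-6), 1 - 1e-6)
    cn[k] <- paste0(groups[gi], "_R", r)
  }
  rownames(beta) <- manifest$probe_id
  colnames(beta) <- cn
  sampleData <- data.frame(
    sample_id = cn,
    group = rep(groups, each = R),
    replicate = rep(seq_len(R), times = length(groups)),
    stringsAsFactors = FALSE)

  cmp <- design@comparisons
  tr <- vector("list", nrow(cmp))
  for (i in seq_len(nrow(cmp))) {
    diffs <- offsets[, cmp$case[i]] - offsets[, cmp$ref[i]]
    sel <- which(abs(diffs) >= delta - 1e-9)
    if (!length(sel)) next
    tr[[i]] <- data.frame(
      comparison = cmp$name[i],
      probe_id = manifest$probe_id[sel],
      direction = ifelse(diffs[sel] > 0, "hyper", "hypo"),
      gene = ifelse(manifest$genes[sel] == "", NA_character_,
                    manifest$genes[sel]),
      feature = manifest$feature[sel],
      stringsAsFactors = FALSE)
  }
  plantedDMPs <- do.call(rbind, tr[!vapply(tr, is.null, logical(1))])
  if (is.null(plantedDMPs))
    plantedDMPs <- data.frame(comparison = character(),
                              probe_id = character(),
                              direction = character(), gene = character(),
                              feature = character())
  truth <- new("SyntheticTruth", plantedDMPs = plantedDMPs,
               plantedDEGs = data.frame(comparison = character(),
                                        gene = character(),
                                        direction = character(),
                                        scenario = character()),
               patientSignal = numeric(),
               seeds = list(beta = as.integer(seed)))
  list(betaSet = BetaSet(beta, sampleData, manifest), truth = truth)
}

.genePlantingPool <- function(manifest) {
  gi <- which(manifest$genes != "" & manifest$feature %in% c("TSS", "Body"))
  key <- paste(manifest$genes[gi], manifest$feature[gi], sep = "\r")
  blocks <- split(gi, key)
  igr <- which(manifest$feature == "IGR")
  list(blocks = blocks, igr = igr)
}

.selectPlanted <- function(manifest, pool, nPlanted, igrFraction) {
  blockOrder <- sample(length(pool$blocks))
  igrOrder <- sample(pool$igr)
  idx <- integer(0); dirs <- character(0)
  bi <- 0L; ii <- 0L
  while (length(idx) < nPlanted) {
    useIGR <- length(igrOrder) > ii && stats::runif(1) < igrFraction
    if (!useIGR && bi >= length(blockOrder)) useIGR <- TRUE
    if (useIGR && ii >= length(igrOrder)) useIGR <- FALSE
    if (useIGR) {
      ii <- ii + 1L
      take <- igrOrder[ii]
    } else {
      if (bi >= length(blockOrder))
        stop("not enough probes to plant ", nPlanted, " effects")
      bi <- bi + 1L
      take <- pool$blocks[[blockOrder[bi]]]
    }
    d <- sample(DIRECTIONS, 1L)
    idx <- c(idx, take)
    dirs <- c(dirs, rep(d, length(take)))
  }
  keep <- !duplicated(idx)
  idx <- idx[keep]; dirs <- dirs[keep]
  if (length(idx) > nPlanted) {
    idx <- idx[seq_len(nPlanted)]; dirs <- dirs[seq_len(nPlanted)]
  }
  data.frame(idx = idx, direction = dirs)
}

#' Simulate an expression count matrix coupled to planted methylation
#'
#' Gene-level counts are drawn from a negative binomial with lognormal gene
#' means and mildly variable library sizes. For one chosen comparison, genes
#' whose planted methylation pattern matches one of the four
#' methylation-expression scenarios are assigned to it and their expression
#' shifted in the case group:
#' \describe{
#'   \item{a}{promoter/TSS hypermethylated, no body hypermethylation:
#'     expression down `foldChange`-fold.}
#'   \item{b}{body hypermethylated, no promoter hypermethylation: up.}
#'   \item{c}{body hypomethylated, no promoter hypomethylation: down.}
#'   \item{d}{promoter hypomethylated, no body hypomethylation: up.}
#' }
#'
#' @param truth a [SyntheticTruth-class] from [simulateBetaSet()].
#' @param manifest the matching manifest.
#' @param design the [StudyDesign-class] used for the beta matrix.
#' @param comparison which comparison's planted pattern drives the
#'   scenarios; defaults to the first neuroendocrine-vs-CRPC comparison in
#'   the truth table, else the first comparison.
#' @param nPerScenario planted genes per scenario (0 for a null matrix).
#' @param foldChange expression fold shift for scenario genes (default 4).
#' @param meanLog,sdLog lognormal parameters of baseline gene means.
#' @param dispersion negative-binomial `size`; the default `Inf` gives
#'   Poisson counts across replicates (the sampling model the chi-squared
#'   count test assumes); finite values add biological overdispersion.
#' @param libSdLog lognormal sd of per-sample library size factors.
#' @param seed integer seed.
#' @return list with `expression` (a
#'   [SummarizedExperiment::SummarizedExperiment] with assay `"counts"`) and
#'   `truth` (input truth extended with `plantedDEGs`: gene, direction and
#'   scenario per planted gene).
#' @export
simulateExpression <- function(truth, manifest, design, comparison = NULL,
                               nPerScenario = 100, foldChange = 4,
                               meanLog = 4.5, sdLog = 1, dispersion = Inf,
                               libSdLog = 0.1, seed = 1L) {
  set.seed(as.integer(seed))
  genes <- sort(unique(manifest$genes[manifest$genes != ""]))
  if (4 * nPerScenario > length(genes))
    stop("scenario demand (4 x ", nPerScenario,
         ") exceeds the number of annotated genes")
  pd <- plantedDMPs(truth)
  comparison <- .pickComparison(pd, design, comparison)

  plantedDEGs <- data.frame(comparison = character(), gene = character(),
                            direction = character(), scenario = character())
  scen <- character(0); scGene <- character(0)
  if (nPerScenario > 0 && nrow(pd)) {
    sub <- pd[pd$comparison == comparison & !is.na(pd$gene), ]
    has <- function(f, d) unique(sub$gene[sub$feature == f &
                                          sub$direction == d])
    tssH <- has("TSS", "hyper"); tssL <- has("TSS", "hypo")
    bodH <- has("Body", "hyper"); bodL <- has("Body", "hypo")
    pools <- list(
      a = setdiff(tssH, bodH), b = setdiff(bodH, tssH),
      c = setdiff(bodL, tssL), d = setdiff(tssL, bodL))
    used <- character(0)
    for (s in sample(names(pools))) {
      avail <- setdiff(pools[[s]], used)
      take <- utils::head(sample(avail), nPerScenario)
      if (length(take) < nPerScenario)
        warning("only ", length(take), " candidate genes for scenario ", s)
      used <- c(used, take)
      scGene <- c(scGene, take)
      scen <- c(scen, rep(s, length(take)))
    }
    dirs <- ifelse(scen %in% c("a", "c"), "down", "up")
    plantedDEGs <- data.frame(comparison = comparison, gene = scGene,
                              direction = dirs, scenario = scen,
                              stringsAsFactors = FALSE)
  }

  groups <- design@groups; R <- design@replicates
  nS <- length(groups) * R
  sampleId <- paste0(rep(groups, each = R), "_R",
                     rep(seq_len(R), times = length(groups)))
  grp <- rep(groups, each = R)
  lib <- stats::rlnorm(nS, 0, libSdLog)
  geneMean <- stats::rlnorm(length(genes), meanLog, sdLog)
  names(geneMean) <- genes

  caseGroup <- design@comparisons$case[design@comparisons$name == comparison]
  eff <- matrix(1, length(genes), nS, dimnames = list(genes, sampleId))
  if (length(scGene)) {
    fold <- ifelse(scen %in% c("a", "c"), 1 / foldChange, foldChange)
    eff[scGene, grp == caseGroup] <- fold
  }
  mu <- (geneMean * eff) %*% diag(lib)
  draws <- if (is.finite(dispersion))
    stats::rnbinom(length(mu), size = dispersion, mu = mu)
  else stats::rpois(length(mu), lambda = mu)
  counts <- matrix(draws, nrow(mu), ncol(mu),
                   dimnames = list(genes, sampleId))
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(sample_id = sampleId, group = grp,
                                   replicate = rep(seq_len(R),
                                                   times = length(groups)),
                                   row.names = sampleId))
  truth@plantedDEGs <- plantedDEGs
  truth@seeds <- c(truth@seeds, list(expression = as.integer(seed)))
  list(expression = se, truth = truth)
}

.pickComparison <- function(pd, design, comparison) {
  cmps <- design@comparisons$name
  if (!is.null(comparison)) {
    if (!comparison %in% cmps) stop("unknown comparison: ", comparison)
    return(comparison)
  }
  pref <- grep("^NE.*_vs_CRPC", cmps, value = TRUE)
  if (length(pref)) pref[1L] else cmps[1L]
}

#' Simulate a cfDNA patient cohort with graded planted signal
#'
#' Each patient receives 200--2000 cell-free DNA differentially methylated
#' regions (DMRs, 100--2000 bp) labelled hyper- or hypomethylated (visit A
#' relative to visit B). A patient-specific fraction `signal[i]` of the
#' hypermethylated DMRs is seeded to contain a planted neuroendocrine-state
#' hypermethylated probe position, so the patient's hyper:hypo DMP-overlap
#' ratio grows with the planted signal. Time to clinical progression (TTP,
#' days) decreases with the signal.
#'
#' Two TTP constructions are available. The default, `"signal"`, draws TTP
#' from the planted signal fraction itself (the disease burden), so a cohort
#' with zero planted signal has TTP exactly independent of the realized
#' overlap ratio -- the correct null for calibration. `"ratio"` makes TTP a
#' strictly decreasing function of the realized overlap ratio, so with
#' `ttpNoiseSd = 0` the Spearman correlation between ratio and TTP is -1 by
#' construction.
#'
#' @param truth a [SyntheticTruth-class] carrying planted DMPs.
#' @param manifest the matching manifest.
#' @param nPatients cohort size (>= 3; Spearman correlation is undefined
#'   below that).
#' @param signal numeric vector of per-patient seeded fractions in \[0, 1\];
#'   default a decreasing grade from 0.9 to 0.05.
#' @param comparison which comparison's planted hyper probes act as the
#'   tNEPC query signature (defaults as in [simulateExpression()]).
#' @param nDmrRange,widthRange per-patient DMR count and width ranges.
#' @param hyperFraction range of the per-patient fraction of DMRs labelled
#'   hyper.
#' @param ttpScale,ttpSlope,ttpNoiseSd TTP construction for the `"signal"`
#'   driver: `ttp = ttpScale - ttpSlope * signal + noise` (days), floored at
#'   1. The linear response keeps adjacent patients' expected TTP spacing
#'   comparable across the whole signal grade.
#' @param ttpDriver `"signal"` (default) or `"ratio"`; see Details.
#' @param pseudocount pseudocount used for the realized hyper:hypo ratio.
#' @param seed integer seed.
#' @return list with `patients` (list of [PatientDMRSet-class]), `outcomes`
#'   (data.frame `patient_id`, `ttp_days`), `ratios` (realized per-patient
#'   overlap counts and ratio against the planted query), and `truth` with
#'   `patientSignal` filled in.
#' @export
simulateCohort <- function(truth, manifest, nPatients = 20, signal = NULL,
                           comparison = NULL, nDmrRange = c(200, 2000),
                           widthRange = c(100, 2000),
                           hyperFraction = c(0.4, 0.6), ttpScale = 500,
                           ttpSlope = 450, ttpNoiseSd = 30,
                           ttpDriver = c("signal", "ratio"),
                           pseudocount = 0.5, seed = 1L) {
  if (nPatients < 3L)
    stop("need at least 3 patients (correlation undefined below)")
  ttpDriver <- match.arg(ttpDriver)
  set.seed(as.integer(seed))
  if (is.null(signal)) signal <- seq(0.9, 0.05, length.out = nPatients)
  if (length(signal) != nPatients || any(signal < 0) || any(signal > 1))
    stop("signal must be a length-", nPatients, " vector in [0, 1]")

  pd <- plantedDMPs(truth)
  if (nrow(pd)) {
    cmps <- unique(pd$comparison)
    if (is.null(comparison)) {
      pref <- grep("^NE.*_vs_CRPC", cmps, value = TRUE)
      comparison <- if (length(pref)) pref[1L] else cmps[1L]
    }
    qp <- pd[pd$comparison == comparison & pd$direction == "hyper", ]
  } else qp <- pd
  qIdx <- match(qp$probe_id, manifest$probe_id)
  qPos <- manifest$pos[qIdx]; qChrom <- manifest$chrom[qIdx]
  if (any(signal > 0) && !length(qPos))
    stop("no planted hypermethylated probes available to seed signal")
  queryGR <- GRanges(qChrom, IRanges(qPos, qPos))

  cl <- attr(manifest, "chromLengths")
  if (is.null(cl)) {
    cl <- tapply(manifest$pos, manifest$chrom, max) + 10000
    cl <- stats::setNames(as.numeric(cl), names(cl))
  }
  chroms <- names(cl)

  patients <- vector("list", nPatients)
  ids <- sprintf("P%02d", seq_len(nPatients))
  ratios <- data.frame(patient_id = ids, n_hyper_hit = 0L, n_hypo_hit = 0L,
                       n_dmr = 0L, ratio = NA_real_)
  ttp <- numeric(nPatients)
  for (i in seq_len(nPatients)) {
    nD <- sample(seq(nDmrRange[1], nDmrRange[2]), 1L)
    hf <- stats::runif(1, hyperFraction[1], hyperFraction[2])
    nH <- round(nD * hf); nL <- nD - nH
    w <- round(stats::runif(nD, widthRange[1], widthRange[2]))
    nSeed <- if (length(qPos)) round(signal[i] * nH) else 0L

    st <- integer(nD); ch <- character(nD)
    if (nSeed > 0) {
      pick <- sample(length(qPos), nSeed, replace = nSeed > length(qPos))
      off <- floor(stats::runif(nSeed) * w[seq_len(nSeed)])
      st[seq_len(nSeed)] <- pmax(0L, as.integer(qPos[pick] - 1L - off))
      ch[seq_len(nSeed)] <- qChrom[pick]
    }
    rnd <- setdiff(seq_len(nD), seq_len(nSeed))
    ch[rnd] <- sample(chroms, length(rnd), replace = TRUE,
                      prob = cl / sum(cl))
    st[rnd] <- as.integer(floor(stats::runif(length(rnd)) *
                                (cl[ch[rnd]] - w[rnd])))
    dir <- c(rep("hyper", nH), rep("hypo", nL))
    patients[[i]] <- PatientDMRSet(ids[i], ch, st, st + w, dir)

    hit <- .dmrHitCounts(queryGR, patients[[i]])
    ratios$n_hyper_hit[i] <- hit["hyper"]
    ratios$n_hypo_hit[i] <- hit["hypo"]
    ratios$n_dmr[i] <- nD
    ratios$ratio[i] <- (hit["hyper"] + pseudocount) /
      (hit["hypo"] + pseudocount)

    base <- if (ttpDriver == "signal") {
      max(1, ttpScale - ttpSlope * signal[i])
    } else {
      ttpScale / (1 + ratios$ratio[i])  # strictly decreasing, always > 0
    }
    noise <- if (ttpNoiseSd > 0) stats::rnorm(1, 0, ttpNoiseSd) else 0
    ttp[i] <- max(base + noise, base / 2, 0.5)
  }
  outcomes <- data.frame(patient_id = ids, ttp_days = ttp,
                         stringsAsFactors = FALSE)
  truth@patientSignal <- stats::setNames(signal, ids)
  truth@seeds <- c(truth@seeds, list(cohort = as.integer(seed)))
  list(patients = patients, outcomes = outcomes, ratios = ratios,
       truth = truth)
}

## Shared overlap core: how many of a patient's DMRs contain >= 1 query
## position, split by the DMR's direction label.
.dmrHitCounts <- function(queryGR, patient) {
  r <- dmrRegions(patient)
  if (!length(r) || !length(queryGR))
    return(c(hyper = 0L, hypo = 0L))
  hit <- countOverlaps(r, queryGR) > 0L
  c(hyper = sum(hit & r$direction == "hyper"),
    hypo = sum(hit & r$direction == "hypo"))
}
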