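#' Count a patient's DMRs hit by query DMPs
#'
#' A cfDNA DMR is a hit when at least one query DMP position falls inside
#' it; each DMR is counted at most once, and hits are tallied by the DMR's
#' direction label (hyper- or hypomethylated at visit A vs B), not the
#' DMP's. Coordinate conventions follow [overlapWithRegions()].
#'
#' @param dmps an annotated [DMPSet-class] (or data.frame with `probe_id`,
#'   `chrom`, `pos`), typically a hypermethylated query signature.
#' @param patient a [PatientDMRSet-class].
#' @return list with `patient_id`, `n_hyper_hit`, `n_hypo_hit`,
#'   `n_dmr_hyper`, `n_dmr_hypo`, `n_query` and `empty` (TRUE when the
#'   patient has no DMRs; counts are then 0/0 and a warning is raised).
#' @export
overlapDMPsDMRs <- function(dmps, patient) {
  rec <- if (is(dmps, "DMPSet")) {
    if (!isAnnotated(dmps)) stop("annotate the DMP set first")
    dmpRecords(dmps)
  } else as.data.frame(dmps)
  rec <- rec[!duplicated(rec$probe_id), , drop = FALSE]
  r <- dmrRegions(patient)
  if (!length(r)) {
    warning("patient ", patientId(patient), " has no DMRs")
    return(list(patient_id = patientId(patient), n_hyper_hit = 0L,
                n_hypo_hit = 0L, n_dmr_hyper = 0L, n_dmr_hypo = 0L,
                n_query = nrow(rec), empty = TRUE))
  }
  q <- GRanges(rec$chrom, IRanges(rec$pos, rec$pos))
  hit <- countOverlaps(r, q) > 0L
  list(patient_id = patientId(patient),
       n_hyper_hit = sum(hit & r$direction == "hyper"),
       n_hypo_hit = sum(hit & r$direction == "hypo"),
       n_dmr_hyper = sum(r$direction == "hyper"),
       n_dmr_hypo = sum(r$direction == "hypo"),
       n_query = nrow(rec), empty = FALSE)
}

#' Hyper:hypo DMR overlap ratio
#'
#' The per-patient biomarker: the ratio of hypermethylated to
#' hypomethylated cfDNA DMRs containing at least one query DMP,
#' \eqn{(n_{hyper} + pc) / (n_{hypo} + pc)}. The pseudocount (default 0.5)
#' keeps patients with a zero denominator defined; `pseudocount = 0` gives
#' the raw ratio. In strict mode, zero-denominator patients return `NA`
#' instead (to be excluded, and logged, by the correlation step).
#'
#' @param counts output of [overlapDMPsDMRs()], or a numeric vector
#'   `c(n_hyper_hit, n_hypo_hit)`.
#' @param pseudocount pseudocount (default 0.5).
#' @param strict drop (NA) instead of regularising zero denominators.
#' @return the ratio (> 0, or NA in strict mode).
#' @examples
#' ratioStatistic(c(10, 5), pseudocount = 0)  # 2
#' ratioStatistic(c(7, 0))                    # 15
#' @export
ratioStatistic <- function(counts, pseudocount = 0.5, strict = FALSE) {
  if (is.list(counts)) counts <- c(counts$n_hyper_hit, counts$n_hypo_hit)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (strict && counts[2] == 0) return(NA_real_)
  (counts[1] + pseudocount) / (counts[2] + pseudocount)
}

#' Spearman correlation of overlap ratios with time to progression
#'
#' Rank correlation (average ranks for ties, two-sided p from the t
#' approximation) between the per-patient hyper:hypo overlap ratio and time
#' to clinical progression. Patients missing either value are excluded and
#' reported.
#'
#' @param ratios data.frame with `patient_id` and `ratio`.
#' @param outcomes data.frame with `patient_id` and `ttp_days` (or `ttp`).
#' @return list with `rho`, `p`, `n` and `excluded` (patient ids dropped).
#' @export
correlateTTP <- function(ratios, outcomes) {
  ttpCol <- if ("ttp_days" %in% names(outcomes)) "ttp_days" else "ttp"
  m <- merge(ratios[, c("patient_id", "ratio")],
             outcomes[, c("patient_id", ttpCol)], by = "patient_id")
  ok <- stats::complete.cases(m)
  excluded <- union(setdiff(union(ratios$patient_id, outcomes$patient_id),
                            m$patient_id),
                    m$patient_id[!ok])
  m <- m[ok, ]
  if (nrow(m) < 3L)
    stop("need >= 3 patients with both ratio and TTP (have ", nrow(m), ")")
  ct <- suppressWarnings(stats::cor.test(m$ratio, m[[ttpCol]],
                                         method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(m),
       excluded = excluded)
}

#' One-proportion z statistic
#'
#' \deqn{z = (\hat p - p_0) / \sqrt{p_0 (1 - p_0) / n}}
#'
#' @param pObs observed proportion.
#' @param p0 null proportion.
#' @param n sample size.
#' @return the z statistic.
#' @examples
#' oneProportionZ(0.3, 0.2, 100)  # 2.5
#' @export
oneProportionZ <- function(pObs, p0, n) {
  (pObs - p0) / sqrt(p0 * (1 - p0) / n)
}

#' Probe-resampling null for DMP-DMR overlap
#'
#' Is the observed overlap between a query DMP signature and a patient's
#' cfDNA DMRs more than chance expects from the array's probe placement?
#' The observed statistic is the fraction of the k query DMPs falling
#' inside any of the patient's DMRs. Per iteration, k probes are drawn
#' uniformly without replacement from the post-filter manifest and their
#' in-DMR fraction recorded; the null proportion p0 is the mean over
#' `nIter` iterations, and the one-proportion z-test (two-sided) compares
#' the observed fraction against it.
#'
#' @param queryDmps annotated [DMPSet-class] (or data.frame with
#'   `probe_id`); all query probes must be present in the manifest.
#' @param manifest the post-filter probe manifest to resample from.
#' @param patient a [PatientDMRSet-class].
#' @param nIter resampling iterations (default 10000).
#' @param seed integer seed; results are deterministic given the seed.
#' @return a [ResamplingResult-class].
#' @export
resamplingNull <- function(queryDmps, manifest, patient, nIter = 10000,
                           seed = 1L) {
  rec <- if (is(queryDmps, "DMPSet")) dmpRecords(queryDmps) else
    as.data.frame(queryDmps)
  ids <- unique(rec$probe_id)
  if (!length(ids)) stop("empty query set")
  idx <- match(ids, manifest$probe_id)
  if (anyNA(idx))
    stop("query probes missing from manifest: ",
         paste(utils::head(ids[is.na(idx)], 5L), collapse = ", "))
  k <- length(ids)
  N <- nrow(manifest)
  if (k > N) stop("query larger than the manifest")

  r <- dmrRegions(patient)
  probeGR <- GRanges(manifest$chrom, IRanges(manifest$pos, manifest$pos))
  member <- countOverlaps(probeGR, r) > 0L
  pObs <- mean(member[idx])

  set.seed(as.integer(seed))
  useHash <- k <= N / 2
  draws <- vapply(seq_len(nIter), function(i)
    sum(member[sample.int(N, k, useHash = useHash)]), numeric(1))
  p0 <- mean(draws) / k

  if (p0 <= 0 || p0 >= 1) {
    z <- if (pObs == p0) 0 else sign(pObs - p0) * Inf
  } else {
    z <- oneProportionZ(pObs, p0, k)
  }
  pv <- 2 * stats::pnorm(-abs(z))
  pv <- min(1, max(pv, .Machine$double.xmin))
  new("ResamplingResult", patientId = patientId(patient), pObs = pObs,
      p0 = p0, nIter = as.integer(nIter), n = as.integer(k), z = z,
      pValue = pv)
}

#' Run the cfDNA biomarker stage over a cohort
#'
#' For each patient: DMR overlap counts against the query signature, the
#' hyper:hypo ratio, and (optionally) the probe-resampling z-test; then the
#' Spearman correlation of ratios with time to progression. Per-patient
#' z-test p values are reported raw, with a BH-adjusted column alongside
#' for transparency.
#'
#' @param queryDmps annotated query [DMPSet-class] (or data.frame).
#' @param patients list of [PatientDMRSet-class].
#' @param outcomes data.frame `patient_id`, `ttp_days`.
#' @param manifest post-filter manifest (needed for the resampling test;
#'   omit with `nIter = 0` to skip it).
#' @param nIter resampling iterations per patient (0 skips the test).
#' @param pseudocount ratio pseudocount.
#' @param seed root seed; per-patient seeds are derived from it.
#' @return list with `perPatient` (data.frame: overlap counts, ratio, and
#'   z-test columns when run) and `correlation` (the [correlateTTP()]
#'   result).
#' @export
cfdnaBiomarker <- function(queryDmps, patients, outcomes, manifest = NULL,
                           nIter = 0, pseudocount = 0.5, seed = 1L) {
  rows <- vector("list", length(patients))
  set.seed(as.integer(seed))
  subSeeds <- sample.int(.Machine$integer.max - 1L, length(patients))
  for (i in seq_along(patients)) {
    cnt <- overlapDMPsDMRs(queryDmps, patients[[i]])
    row <- data.frame(patient_id = cnt$patient_id,
                      n_hyper_hit = cnt$n_hyper_hit,
                      n_hypo_hit = cnt$n_hypo_hit,
                      ratio = ratioStatistic(cnt, pseudocount),
                      stringsAsFactors = FALSE)
    if (nIter > 0) {
      if (is.null(manifest))
        stop("manifest required for the resampling test")
      rs <- resamplingNull(queryDmps, manifest, patients[[i]],
                           nIter = nIter, seed = subSeeds[i])
      row$p_obs <- rs@pObs; row$p0 <- rs@p0
      row$z <- rs@z; row$p_resampling <- rs@pValue
    }
    rows[[i]] <- row
  }
  perPatient <- do.call(rbind, rows)
  if (!is.null(perPatient$p_resampling))
    perPatient$q_resampling <- stats::p.adjust(perPatient$p_resampling,
                                               method = "BH")
  corr <- correlateTTP(perPatient, outcomes)
  list(perPatient = perPatient, correlation = corr)
}
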