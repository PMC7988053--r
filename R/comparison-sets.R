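#' Probes shared by every comparison
#'
#' Intersects two or more DMP sets by probe id. A "common" probe must have
#' passed the call thresholds in every member comparison (no pooling of p
#' values). In `same_direction` mode a probe is retained only if its call
#' direction is identical in all sets -- the natural definition for "shared
#' hypermethylated / hypomethylated" counts; `any` keeps every shared probe
#' and records the per-comparison directions.
#'
#' @param sets list of >= 2 [DMPSet-class] objects.
#' @param mode `"same_direction"` (default) or `"any"`.
#' @return a [CommonDMPSet-class]; see [directionCounts()] for the
#'   hyper/hypo split.
#' @export
commonDMPs <- function(sets, mode = c("same_direction", "any")) {
  mode <- match.arg(mode)
  if (length(sets) < 2L) stop("need at least 2 DMP sets")
  dirTabs <- lapply(sets, .probeDirections)
  nm <- vapply(sets, comparisonName, character(1))
  ids <- Reduce(intersect, lapply(dirTabs, names))
  if (mode == "same_direction") {
    if (length(ids)) {
      dmat <- vapply(dirTabs, function(d) d[ids], character(length(ids)))
      if (length(ids) == 1L) dmat <- matrix(dmat, nrow = 1L)
      agree <- apply(dmat, 1L, function(r) all(r == r[1L]))
      probes <- data.frame(probe_id = ids[agree],
                           direction = dmat[agree, 1L],
                           stringsAsFactors = FALSE)
    } else {
      probes <- data.frame(probe_id = character(), direction = character())
    }
  } else {
    probes <- data.frame(probe_id = ids, stringsAsFactors = FALSE)
    for (j in seq_along(dirTabs))
      probes[[paste0("direction_", nm[j])]] <-
        if (length(ids)) unname(dirTabs[[j]][ids]) else character(0)
  }
  rownames(probes) <- NULL
  new("CommonDMPSet", comparisons = nm, probes = probes, mode = mode)
}

## probe id -> direction map, deduplicated (annotation may expand records
## per gene; direction is a per-probe property).
.probeDirections <- function(x) {
  if (is(x, "DMPSet")) {
    rec <- dmpRecords(x)
    rec <- rec[!duplicated(rec$probe_id), ]
    stats::setNames(rec$direction, rec$probe_id)
  } else if (is(x, "CommonDMPSet")) {
    if (x@mode != "same_direction")
      stop("direction unresolved in 'any' mode; rebuild the common set ",
           "with mode = \"same_direction\"")
    stats::setNames(x@probes$direction, x@probes$probe_id)
  } else stop("expected a DMPSet or CommonDMPSet")
}

#' Hyper/hypo counts of a probe set
#'
#' @param x a [DMPSet-class] or a same-direction [CommonDMPSet-class].
#' @return named integer vector `c(hyper = , hypo = )` over unique probes.
#' @export
directionCounts <- function(x) {
  d <- .probeDirections(x)
  c(hyper = sum(d == "hyper"), hypo = sum(d == "hypo"))
}

#' Direction-switch quadrants between two probe sets
#'
#' For probes present in both sets, tabulates the pair of directions into
#' the 2x2 quadrant table (hyper/hyper, hyper/hypo, hypo/hyper, hypo/hypo):
#' the diagonal holds probes keeping the same methylation trend across two
#' stages, the off-diagonal those switching directionality.
#'
#' @param a,b [DMPSet-class] or same-direction [CommonDMPSet-class]
#'   objects, each with a single resolved direction per probe.
#' @return list with `table` (2x2 matrix, rows = direction in `a`,
#'   columns = direction in `b`), `total` (overlap size) and `probes`
#'   (data.frame of the shared probes and both directions).
#' @export
directionSwitches <- function(a, b) {
  da <- .probeDirections(a)
  db <- .probeDirections(b)
  ids <- intersect(names(da), names(db))
  tab <- table(factor(da[ids], levels = DIRECTIONS),
               factor(db[ids], levels = DIRECTIONS))
  tab <- matrix(as.integer(tab), 2L, 2L,
                dimnames = list(a = DIRECTIONS, b = DIRECTIONS))
  list(table = tab, total = length(ids),
       probes = data.frame(probe_id = ids,
                           direction_a = unname(da[ids]),
                           direction_b = unname(db[ids]),
                           stringsAsFactors = FALSE))
}

#' Delta-beta concordance of two comparisons
#'
#' Pearson correlation of the per-probe delta-beta values over the probes
#' shared by two DMP sets -- the usual check that probes called in two
#' related comparisons move coherently.
#'
#' @param a,b [DMPSet-class] objects sharing >= 3 probes.
#' @return list with `r`, `p` and `n`.
#' @export
deltaConcordance <- function(a, b) {
  ra <- dmpRecords(a); ra <- ra[!duplicated(ra$probe_id), ]
  rb <- dmpRecords(b); rb <- rb[!duplicated(rb$probe_id), ]
  ids <- intersect(ra$probe_id, rb$probe_id)
  if (length(ids) < 3L)
    stop("need >= 3 shared probes (have ", length(ids), ")")
  da <- ra$delta_beta[match(ids, ra$probe_id)]
  db <- rb$delta_beta[match(ids, rb$probe_id)]
  ct <- stats::cor.test(da, db, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ids))
}
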