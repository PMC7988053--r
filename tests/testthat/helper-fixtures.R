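# Shared in-code fixtures: tiny manifests, beta sets and DMP sets built
# from explicit values, plus brute-force interval oracles.

mkManifest <- function(probe_id, chrom = "chr1", pos = seq_along(probe_id),
                       strand = "+", genes = "", feature = "IGR",
                       cgi_context = "open_sea", flags = "") {
  data.frame(probe_id = probe_id, chrom = chrom, pos = pos, strand = strand,
             genes = genes, feature = feature, cgi_context = cgi_context,
             flags = flags, stringsAsFactors = FALSE)
}

mkBetaSet <- function(mat, groups, manifest = NULL) {
  reps <- stats::ave(seq_along(groups), groups, FUN = seq_along)
  colnames(mat) <- paste0(groups, "_R", reps)
  sd <- data.frame(sample_id = colnames(mat), group = groups,
                   replicate = reps, stringsAsFactors = FALSE)
  BetaSet(mat, sd, manifest)
}

mkDMPSet <- function(probe_id, direction, delta_beta = NULL, q = 1e-4,
                     comparison = "A_vs_B", nTested = length(probe_id)) {
  if (is.null(delta_beta))
    delta_beta <- ifelse(direction == "hyper", 0.3, -0.3)
  DMPSet(data.frame(probe_id = probe_id, delta_beta = delta_beta,
                    t = 5, p = q, q = q, direction = direction,
                    stringsAsFactors = FALSE),
         comparison = comparison, nTested = nTested)
}

# O(n*m) double-loop oracle: for each probe (1-based pos), is it inside any
# region ([start, end), 0-based half-open)?
bruteProbeInRegion <- function(chrom, pos, regions) {
  vapply(seq_along(pos), function(i) {
    any(regions$chrom == chrom[i] &
          regions$start <= pos[i] - 1 & pos[i] - 1 < regions$end)
  }, logical(1))
}

# O(n*m) oracle: for each region, does it contain >= 1 probe?
bruteRegionHasProbe <- function(regions, chrom, pos) {
  vapply(seq_len(nrow(regions)), function(j) {
    any(chrom == regions$chrom[j] &
          regions$start[j] <= pos - 1 & pos - 1 < regions$end[j])
  }, logical(1))
}

# A small annotated study shared by several test files (cached per session).
sharedStudy <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    m <- simulateManifest(6000, 500, seed = 7)
    d <- progressionDesign()
    bs <- simulateBetaSet(m, d, nPlanted = 600, seed = 11)
    cache <<- list(manifest = m, design = d, betaSet = bs$betaSet,
                   truth = bs$truth)
    cache
  }
})
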