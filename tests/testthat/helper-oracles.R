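# Independent oracles, deliberately naive and kept apart from the package's
# own code paths.

# type-7 quantile by direct sort-and-interpolate
q7_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  hi_val <- if (lo + 2 > n) x[n] else x[lo + 2]
  x[lo + 1] + (h - lo) * (hi_val - x[lo + 1])
}

# exact Poisson upper tail by summing the pmf
pois_tail_oracle <- function(k, lambda, upper = 10000) {
  if (k <= 0) return(1)
  sum(dpois(k:upper, lambda))
}

# a tiny hand-constructible plate: wells laid out one column per plex set
# block, counts supplied explicitly
make_test_plate <- function(counts, columns, plex_sets, roles,
                            probe_classes) {
  wells <- data.frame(
    well = rownames(counts), column = columns,
    row = stats::ave(columns, columns, FUN = seq_along),
    plex_set = plex_sets, sample_role = roles, stringsAsFactors = FALSE)
  probes <- data.frame(probe_id = colnames(counts), class = probe_classes,
                       stringsAsFactors = FALSE)
  PlateFile("test", wells, probes, counts)
}

# GRanges builder for peak fixtures (1-based starts as GRanges expects)
make_peaks <- function(chrom, start1, end, id,
                       unstim = NULL, cytoA = NULL, cytoB = NULL,
                       combo = NULL) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start1, end = end))
  meta <- S4Vectors::DataFrame(id = id)
  if (!is.null(unstim)) meta$signal_unstim <- unstim
  if (!is.null(cytoA)) meta$signal_cytoA <- cytoA
  if (!is.null(cytoB)) meta$signal_cytoB <- cytoB
  if (!is.null(combo)) meta$signal_combo <- combo
  S4Vectors::mcols(gr) <- meta
  gr
}
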