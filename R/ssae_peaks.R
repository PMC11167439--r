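#' One-sided depth-scaled Poisson enrichment test
#'
#' Reconstruction of the differential-accessibility test used for tag-count
#' comparisons: the comparator count is scaled to the target's sequencing
#' depth, `lambda = count_comparator * depth_target / depth_comparator`,
#' the fold change is `count_target / lambda`, and the p-value is the exact
#' Poisson upper tail `P(X >= count_target)` for `X ~ Poisson(lambda)`.
#' When both counts are zero the pair is uninformative and `(fold = 1,
#' p = 1)` is returned with `undefined = TRUE`.
#'
#' @param count_target,count_comparator non-negative counts (vectorized).
#' @param depth_target,depth_comparator positive library depths.
#' @param eps floor for the scaled comparator when it is zero but the
#'   target is not, keeping the fold finite.
#' @return list with vectors `fold`, `p`, `undefined`.
#' @export
poisson_enrichment_test <- function(count_target, count_comparator,
                                    depth_target = 1, depth_comparator = 1,
                                    eps = 0.5) {
  if (any(count_target < 0) || any(count_comparator < 0))
    stop_value("counts must be >= 0")
  if (any(depth_target <= 0) || any(depth_comparator <= 0))
    stop_value("depths must be > 0")
  lambda <- count_comparator * depth_target / depth_comparator
  undefined <- count_target == 0 & count_comparator == 0
  fold <- count_target / pmax(lambda, eps)
  # P(X >= k) = P(X > k - 1); exact for k = 0 too (upper tail = 1)
  p <- ppois(count_target - 1, lambda, lower.tail = FALSE)
  fold[undefined] <- 1
  p[undefined] <- 1
  list(fold = fold, p = p, undefined = undefined)
}

get_signal <- function(peaks, condition) {
  col <- paste0("signal_", condition)
  meta <- S4Vectors::mcols(peaks)
  if (!col %in% names(meta))
    stop_config(paste0("peaks lack signal column for condition ", condition))
  meta[[col]]
}

#' Differential peak calling between two conditions
#'
#' Runs [poisson_enrichment_test()] on every peak for
#' `target_condition` vs `comparator_condition` and applies the fold and
#' p-value gates: a peak passes iff `fold >= F` and `p < p_max`.
#'
#' @param peaks `GRanges` with `signal_<condition>` columns (counts) and an
#'   `id` column.
#' @param target_condition,comparator_condition condition names.
#' @param depths named vector of per-condition depths (defaults to equal).
#' @param F minimum fold enrichment (default 1.5).
#' @param p_max p-value cutoff, strict (default 1e-4).
#' @return data.frame: `id`, `fold`, `p`, `passes`.
#' @export
call_differential <- function(peaks, target_condition, comparator_condition,
                              depths = NULL, F = 1.5, p_max = 1e-4) {
  tgt <- get_signal(peaks, target_condition)
  cmp <- get_signal(peaks, comparator_condition)
  if (is.null(depths))
    depths <- setNames(c(1, 1), c(target_condition, comparator_condition))
  res <- poisson_enrichment_test(tgt, cmp, depths[[target_condition]],
                                 depths[[comparator_condition]])
  data.frame(id = peaks$id, fold = res$fold, p = res$p,
             passes = res$fold >= F & res$p < p_max,
             stringsAsFactors = FALSE)
}

#' Three-way intersection defining synergy-specific accessible elements
#'
#' An element of the costimulated peak universe is synergy-specific when it
#' passes the differential gate in all three pairwise comparisons
#' (costimulation vs unstimulated, vs stimulus A, vs stimulus B).
#'
#' @param peaks the costimulated-condition peak universe (`GRanges`).
#' @param calls_vs_unstim,calls_vs_A,calls_vs_B [call_differential()]
#'   results over exactly that universe.
#' @return `GRanges` subset of `peaks` (the unclassified SSAE set), with
#'   `n_input` and per-comparison pass counts in `metadata`.
#' @export
intersect_ssae <- function(peaks, calls_vs_unstim, calls_vs_A, calls_vs_B) {
  calls <- list(calls_vs_unstim, calls_vs_A, calls_vs_B)
  for (cl in calls) {
    if (!setequal(cl$id, peaks$id))
      stop_config("differential calls must cover the same peak universe")
  }
  pass_ids <- Reduce(intersect, lapply(calls, function(cl) cl$id[cl$passes]))
  out <- peaks[peaks$id %in% pass_ids]
  S4Vectors::metadata(out) <- list(
    n_input = length(peaks),
    n_pass = setNames(vapply(calls, function(cl) sum(cl$passes), 0L),
                      c("vs_unstim", "vs_A", "vs_B")),
    n_ssae = length(out))
  out
}

#' Classify SSAEs as enhanced or de novo
#'
#' An SSAE is *de novo* when it overlaps no called peak in either
#' single-stimulus peak set (half-open, >= 1 bp overlap) — accessibility
#' absent without costimulation — and *enhanced* otherwise (present but
#' weaker). With `require_signal_increase = TRUE`, an overlap only counts
#' as "present" if its single-condition signal is positive.
#'
#' @param ssae `GRanges` from [intersect_ssae()].
#' @param peaks_A,peaks_B `GRanges` of peaks called accessible in each
#'   single-stimulus condition.
#' @param require_signal_increase stricter enhanced definition (default
#'   FALSE: presence/absence only).
#' @return `ssae` with an added `class` column (`"enhanced"`/`"de_novo"`).
#' @export
classify_enhanced_denovo <- function(ssae, peaks_A, peaks_B,
                                     require_signal_increase = FALSE) {
  present <- function(single) {
    if (!length(single)) return(rep(FALSE, length(ssae)))
    if (require_signal_increase) {
      sig_cols <- grep("^signal_(cytoA|cytoB)$",
                       names(S4Vectors::mcols(single)), value = TRUE)
      if (length(sig_cols)) {
        keep <- rowSums(as.matrix(S4Vectors::mcols(single)[sig_cols])) > 0
        single <- single[keep]
      }
    }
    IRanges::overlapsAny(ssae, single, minoverlap = 1L)
  }
  hit <- present(peaks_A) | present(peaks_B)
  ssae$class <- ifelse(hit, "enhanced", "de_novo")
  ssae
}

#' Flag genes with an SSAE near their transcriptional start site
#'
#' A gene is flagged when any SSAE midpoint lies within `window` bases of
#' its TSS on the same chromosome, boundary inclusive. Midpoints are taken
#' on the 0-based half-open coordinate scale.
#'
#' @param ssae `GRanges` of SSAEs.
#' @param gene_tss data.frame with `gene`, `chrom`, `tss` (0-based
#'   position).
#' @param window distance in bp (default 500 kb).
#' @return list with `table` (data.frame `gene`, `has_ssae`, distance to
#'   the nearest SSAE midpoint) and `fraction` flagged.
#' @export
tss_proximity <- function(ssae, gene_tss, window = 500000) {
  stopifnot(all(c("gene", "chrom", "tss") %in% names(gene_tss)))
  mid <- bed_midpoint(ssae)
  chr <- as.character(GenomicRanges::seqnames(ssae))
  dist <- vapply(seq_len(nrow(gene_tss)), function(i) {
    on_chr <- chr == gene_tss$chrom[i]
    if (!any(on_chr)) return(Inf)
    min(abs(mid[on_chr] - gene_tss$tss[i]))
  }, 0)
  has <- dist <= window
  list(table = data.frame(gene = gene_tss$gene, has_ssae = has,
                          nearest_ssae_distance = dist,
                          stringsAsFactors = FALSE),
       fraction = mean(has))
}

#' Rank peaks by costimulated signal
#'
#' Descending by `log2(signal_combo)` with a stable (chrom, start)
#' tie-break; the log transform is monotone, so ranks equal those of the
#' raw signal.
#'
#' @param ssae `GRanges` with a `signal_combo` column.
#' @return data.frame: `rank`, `id`, `chrom`, `start`, `end`,
#'   `log2_signal`.
#' @export
rank_by_signal <- function(ssae) {
  sig <- get_signal(ssae, "combo")
  chrom <- as.character(GenomicRanges::seqnames(ssae))
  start0 <- GenomicRanges::start(ssae) - 1L
  ord <- order(-sig, chrom, start0)
  data.frame(rank = seq_along(ord), id = ssae$id[ord], chrom = chrom[ord],
             start = start0[ord], end = GenomicRanges::end(ssae)[ord],
             log2_signal = log2(sig[ord]),
             stringsAsFactors = FALSE)
}

#' Full SSAE workflow on a peak landscape
#'
#' Convenience wrapper: calls the three pairwise differentials on the
#' costimulated peak universe, intersects them, and classifies survivors.
#'
#' @param peaks costimulated peak universe with all four signal columns.
#' @param peaks_A,peaks_B single-stimulus called peak sets.
#' @param depths named per-condition depth vector (default equal).
#' @param F,p_max gates passed to [call_differential()].
#' @return classified SSAE `GRanges` (see [classify_enhanced_denovo()]).
#' @export
ssae_workflow <- function(peaks, peaks_A, peaks_B, depths = NULL,
                          F = 1.5, p_max = 1e-4) {
  if (is.null(depths)) depths <- setNames(rep(1, 4), SYN_CONDITIONS)
  calls <- lapply(c("unstim", "cytoA", "cytoB"), function(cc) {
    call_differential(peaks, "combo", cc, depths = depths, F = F, p_max = p_max)
  })
  ssae <- intersect_ssae(peaks, calls[[1]], calls[[2]], calls[[3]])
  classify_enhanced_denovo(ssae, peaks_A, peaks_B)
}
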