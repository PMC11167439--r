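#' Per-gene log2 fold change between two conditions
#'
#' Naive mean-ratio estimator:
#' `log2((mean_treat + pseudocount) / (mean_ref + pseudocount))`, suitable
#' for synthetic counts; real studies can supply shrunken fold changes from
#' a dedicated differential-expression fit via [contrast_table()] instead.
#'
#' @param counts a [CountMatrix].
#' @param condition_pair length-2 character, `c(treatment, reference)`.
#' @param pseudocount non-negative offset added to both means; must be > 0
#'   if any reference mean is zero.
#' @return named numeric vector of per-gene log2 fold changes.
#' @export
compute_log2fc <- function(counts, condition_pair, pseudocount = 1) {
  stopifnot(inherits(counts, "CountMatrix"), length(condition_pair) == 2)
  if (pseudocount < 0) stop_value("pseudocount must be >= 0")
  sel <- lapply(condition_pair, function(cc) {
    idx <- which(counts$condition == cc)
    if (!length(idx)) stop_config(paste0("no samples with condition ", cc))
    idx
  })
  m_treat <- rowMeans(counts$counts[, sel[[1]], drop = FALSE])
  m_ref <- rowMeans(counts$counts[, sel[[2]], drop = FALSE])
  if (pseudocount == 0 && any(m_ref == 0))
    stop_value("zero reference mean requires pseudocount > 0")
  log2((m_treat + pseudocount) / (m_ref + pseudocount))
}

#' Build a contrast table from counts
#'
#' Computes the three log2 fold changes against the unstimulated reference
#' (combination, stimulus A, stimulus B) plus a per-gene FDR-adjusted
#' p-value for the combination-vs-unstimulated contrast (Welch t test on
#' log2(count + pseudocount), BH-corrected), which the differential-
#' expression gate of [call_synergy_genes()] consumes.
#'
#' @param counts a [CountMatrix] with all four conditions.
#' @param pseudocount passed to [compute_log2fc()] and the log transform.
#' @param compute_padj also compute `padj_combo` (default TRUE; needs >= 2
#'   replicates in combo and unstim).
#' @return data.frame with `gene`, `log2FC_combo`, `log2FC_A`, `log2FC_B`
#'   and optionally `padj_combo`.
#' @export
contrast_table <- function(counts, pseudocount = 1, compute_padj = TRUE) {
  tab <- data.frame(
    gene = rownames(counts$counts),
    log2FC_combo = compute_log2fc(counts, c("combo", "unstim"), pseudocount),
    log2FC_A = compute_log2fc(counts, c("cytoA", "unstim"), pseudocount),
    log2FC_B = compute_log2fc(counts, c("cytoB", "unstim"), pseudocount),
    stringsAsFactors = FALSE, row.names = NULL)
  if (compute_padj) {
    x <- log2(counts$counts[, counts$condition == "combo", drop = FALSE] + pseudocount)
    y <- log2(counts$counts[, counts$condition == "unstim", drop = FALSE] + pseudocount)
    if (ncol(x) < 2 || ncol(y) < 2)
      stop_config("padj needs >=2 replicates in combo and unstim")
    p <- vapply(seq_len(nrow(x)), function(i) {
      if (sd(x[i, ]) == 0 && sd(y[i, ]) == 0)
        return(if (mean(x[i, ]) == mean(y[i, ])) 1 else 0)
      t.test(x[i, ], y[i, ])$p.value
    }, 0)
    tab$padj_combo <- p.adjust(p, method = "BH")
  }
  tab
}

#' Expected-additivity difference statistic
#'
#' For each gene, `D = log2FC_combo - (log2FC_A + log2FC_B)`: the departure
#' of the combined stimulation from the sum of the single-stimulus log2
#' fold changes. `D = 0` means exact additivity (multiplicativity on the
#' count scale); large positive `D` marks synergistic induction.
#'
#' @param contrasts data.frame with columns `log2FC_combo`, `log2FC_A`,
#'   `log2FC_B` (e.g. from [contrast_table()]).
#' @return numeric vector `D`, one value per row.
#' @export
synergy_difference <- function(contrasts) {
  need <- c("log2FC_combo", "log2FC_A", "log2FC_B")
  if (!all(need %in% names(contrasts)))
    stop_value(paste0("contrasts must contain ", paste(need, collapse = ", ")))
  with(contrasts, log2FC_combo - (log2FC_A + log2FC_B))
}

#' Linear-interpolation (type 7) sample quantile
#'
#' The default quantile definition of the R statistical environment:
#' with sorted values `x[0..n-1]`, `h = (n-1)p` and the result is
#' `x[floor(h)] + (h - floor(h)) * (x[floor(h)+1] - x[floor(h)])`.
#'
#' @param values non-empty finite numeric vector.
#' @param p probability in `[0, 1]` (vectorized).
#' @return quantile value(s).
#' @export
quantile_linear <- function(values, p) {
  if (!length(values)) stop_value("empty input")
  if (any(!is.finite(values))) stop_value("values must be finite")
  if (any(p < 0 | p > 1)) stop_value("p must lie in [0, 1]")
  unname(quantile(values, probs = p, type = 7, names = FALSE))
}

#' IQR-based outlier classification of difference values
#'
#' Classifies each value as a positive outlier if it strictly exceeds
#' `Q3 + k * IQR`, negative if strictly below `Q1 - k * IQR`, using type-7
#' quantiles. The strict inequalities mean an all-equal vector (IQR 0)
#' yields no outliers.
#'
#' @param d numeric vector of difference values (>= 4 finite values).
#' @param k IQR multiplier (default 1.5, the standard fence).
#' @return list of class `SynergyCallTable`: `calls` (data.frame with `D`
#'   and `outlier_class` in {"positive","negative","none"}) and `cutoffs`
#'   (Q1, Q3, IQR, upper_cut, lower_cut, k).
#' @export
iqr_outliers <- function(d, k = 1.5) {
  if (sum(is.finite(d)) < 4)
    stop_value("need >= 4 finite values for quantile-based outlier calling")
  q1 <- quantile_linear(d, 0.25)
  q3 <- quantile_linear(d, 0.75)
  iqr <- IQR(d, type = 7)
  upper <- q3 + k * iqr
  lower <- q1 - k * iqr
  cls <- ifelse(d > upper, "positive", ifelse(d < lower, "negative", "none"))
  structure(list(
    calls = data.frame(D = d, outlier_class = cls, stringsAsFactors = FALSE),
    cutoffs = c(Q1 = q1, Q3 = q3, IQR = iqr, upper_cut = upper,
                lower_cut = lower, k = k)),
    class = "SynergyCallTable")
}

#' @export
print.SynergyCallTable <- function(x, ...) {
  n <- table(factor(x$calls$outlier_class, c("positive", "negative", "none")))
  cat(sprintf("SynergyCallTable: %d genes (%d positive, %d negative outliers)\n",
              nrow(x$calls), n[["positive"]], n[["negative"]]))
  cat(sprintf("  cutoffs: Q1=%.4g Q3=%.4g IQR=%.4g upper=%.4g lower=%.4g (k=%.3g)\n",
              x$cutoffs[["Q1"]], x$cutoffs[["Q3"]], x$cutoffs[["IQR"]],
              x$cutoffs[["upper_cut"]], x$cutoffs[["lower_cut"]],
              x$cutoffs[["k"]]))
  invisible(x)
}

#' Call synergy genes with a differential-expression gate
#'
#' Restricts the outlier universe to genes differentially expressed in the
#' combination-vs-unstimulated contrast (`|fold change| >= fc_threshold`
#' and `padj <= padj_threshold`), then runs [iqr_outliers()] on the
#' difference statistic within that universe. Genes outside the gate get
#' class `"none"` and `in_universe = FALSE`. Setting `fc_threshold = 1` and
#' `padj_threshold = 1` relaxes the gate to all genes.
#'
#' @param contrasts contrast table (see [contrast_table()]); must carry
#'   `padj_combo` unless the padj gate is fully relaxed
#'   (`padj_threshold >= 1`).
#' @param d optional difference vector; computed via [synergy_difference()]
#'   when missing.
#' @param fc_threshold minimum absolute fold change (linear scale,
#'   default 2).
#' @param padj_threshold maximum FDR-adjusted p (default 0.05).
#' @param k IQR multiplier (default 1.5).
#' @param gate_all_contrasts if TRUE, the fold-change gate is also applied
#'   to the two single-stimulus contrasts (off by default: the gate is
#'   defined on the combination contrast).
#' @return list of class `SynergyGeneCalls`: `table` (data.frame `gene`,
#'   `D`, `in_universe`, `outlier_class`) and `cutoffs` from the gated
#'   universe.
#' @export
call_synergy_genes <- function(contrasts, d = NULL, fc_threshold = 2,
                               padj_threshold = 0.05, k = 1.5,
                               gate_all_contrasts = FALSE) {
  if (is.null(d)) d <- synergy_difference(contrasts)
  stopifnot(length(d) == nrow(contrasts))
  use_padj <- padj_threshold < 1
  if (use_padj && is.null(contrasts$padj_combo))
    stop_config("padj gate requested but contrasts lack padj_combo")
  gate <- abs(contrasts$log2FC_combo) >= log2(fc_threshold)
  if (gate_all_contrasts) {
    gate <- gate & abs(contrasts$log2FC_A) >= log2(fc_threshold) &
      abs(contrasts$log2FC_B) >= log2(fc_threshold)
  }
  if (use_padj) gate <- gate & contrasts$padj_combo <= padj_threshold
  if (sum(gate) < 4)
    stop_value("fewer than 4 genes pass the DE gate; outlier calling ill-posed")
  sub <- iqr_outliers(d[gate], k = k)
  cls <- rep("none", length(d))
  cls[gate] <- sub$calls$outlier_class
  gene <- if (!is.null(contrasts$gene)) contrasts$gene else seq_along(d)
  structure(list(
    table = data.frame(gene = gene, D = d, in_universe = gate,
                       outlier_class = cls, stringsAsFactors = FALSE),
    cutoffs = sub$cutoffs),
    class = "SynergyGeneCalls")
}

#' @export
print.SynergyGeneCalls <- function(x, ...) {
  cat(sprintf("SynergyGeneCalls: %d genes, %d in DE-gated universe, %d positive, %d negative\n",
              nrow(x$table), sum(x$table$in_universe),
              sum(x$table$outlier_class == "positive"),
              sum(x$table$outlier_class == "negative")))
  invisible(x)
}
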