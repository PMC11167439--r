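#' Synthetic data generators with known ground truth
#'
#' Every analysis in the package has a paired generator that emulates the
#' statistical structure the analysis assumes, so parameter recovery can be
#' tested against planted truth. All generators are pure functions of their
#' parameters and `seed` (the RNG state is restored on exit).
#'
#' @name synth-generators
NULL

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop_value("seed must be a single finite number")
}

#' Simulate condition-structured expression counts with planted synergy
#'
#' Emulates a four-condition bulk expression experiment (unstimulated, two
#' single stimuli, their combination) with a handful of replicates per
#' condition. Per-gene true log2 fold changes for the single stimuli are
#' drawn independently; the combination's true log2FC is their sum plus a
#' planted departure `D` from additivity: `+synergy_shift` for positive
#' outliers, `-synergy_shift` for negative ones, 0 for additive genes.
#' Counts are negative binomial with mean
#' `baseline * 2^log2FC` and variance `mu + dispersion * mu^2`.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_reps_per_condition replicates per condition (default 4, the
#'   usual design for this kind of experiment).
#' @param baseline_mean_range range for log-uniform baseline means.
#' @param dispersion NB dispersion (> 0).
#' @param n_synergy_pos,n_synergy_neg number of planted positive / negative
#'   outlier genes; their sum must be `< n_genes`.
#' @param synergy_shift planted |D| in log2 units (default 4).
#' @param lfc_sd sd of the per-gene single-stimulus true log2FCs.
#' @param seed RNG seed.
#' @return list with `counts` (a [CountMatrix]) and `truth` (data.frame:
#'   `gene`, `lfc_A`, `lfc_B`, `lfc_combo`, `D_true`, `label`).
#' @export
simulate_expression_counts <- function(n_genes = 2000,
                                       n_reps_per_condition = 4,
                                       baseline_mean_range = c(20, 2000),
                                       dispersion = 0.05,
                                       n_synergy_pos = 30,
                                       n_synergy_neg = 10,
                                       synergy_shift = 4,
                                       lfc_sd = 1,
                                       seed = 1) {
  check_seed(seed)
  if (n_genes < 1 || n_synergy_pos < 0 || n_synergy_neg < 0 ||
      n_synergy_pos + n_synergy_neg >= n_genes)
    stop_value("need n_synergy_pos + n_synergy_neg < n_genes")
  if (dispersion <= 0) stop_value("dispersion must be > 0")
  withr::with_seed(seed, {
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    baseline <- exp(runif(n_genes, log(baseline_mean_range[1]),
                          log(baseline_mean_range[2])))
    lfc_A <- rnorm(n_genes, 0, lfc_sd)
    lfc_B <- rnorm(n_genes, 0, lfc_sd)
    D <- rep(0, n_genes)
    D[seq_len(n_synergy_pos)] <- synergy_shift
    D[n_synergy_pos + seq_len(n_synergy_neg)] <- -synergy_shift
    label <- ifelse(D > 0, "positive_outlier",
                    ifelse(D < 0, "negative_outlier", "additive"))
    lfc_combo <- lfc_A + lfc_B + D
    mu <- cbind(unstim = baseline,
                cytoA = baseline * 2^lfc_A,
                cytoB = baseline * 2^lfc_B,
                combo = baseline * 2^lfc_combo)
    nrep <- n_reps_per_condition
    cond <- rep(SYN_CONDITIONS, each = nrep)
    samples <- paste0(cond, "_", rep(seq_len(nrep), times = 4))
    counts <- matrix(0, n_genes, length(samples),
                     dimnames = list(genes, samples))
    for (i in seq_along(samples)) {
      counts[, i] <- rnbinom(n_genes, mu = mu[, cond[i]], size = 1 / dispersion)
    }
    truth <- data.frame(gene = genes, lfc_A = lfc_A, lfc_B = lfc_B,
                        lfc_combo = lfc_combo, D_true = D, label = label,
                        stringsAsFactors = FALSE)
    list(counts = CountMatrix(counts, setNames(cond, samples)), truth = truth)
  })
}

#' Simulate a counted-hybridization plate with planted factors
#'
#' Builds a plate whose observed counts are
#' `truth x lane_factor(column) x plex_factor(gene, plex set) x
#' content_factor(well) x lognormal noise`. Plex sets occupy contiguous
#' column blocks; the last column of each block carries the shared
#' calibration sample. Positive-control probes see lane and content factors
#' but no plex factor (they are spiked into every plex); housekeepers have
#' constant true abundance across wells, as the normalization assumes.
#'
#' @param n_columns plate columns (default 12, an 8-row 96-well plate).
#' @param n_plex_sets number of plex sets; must divide `n_columns`.
#' @param lane_factor_sd,plex_factor_sd,content_factor_sd lognormal sds of
#'   the planted factors (0 disables a factor).
#' @param noise_cv multiplicative measurement noise CV (lognormal, mean 1).
#' @param true_abundances named vector of endogenous true counts; defaults
#'   to 12 genes log-spaced over 30..30000, the dynamic range a counted
#'   chemokine panel spans.
#' @param n_rows wells per column.
#' @param seed RNG seed.
#' @return list with `plate` (a [PlateFile]) and `truth` (list of the
#'   truth matrix and all planted factors).
#' @export
simulate_plate <- function(n_columns = 12, n_plex_sets = 3,
                           lane_factor_sd = 0.3, plex_factor_sd = 0.3,
                           content_factor_sd = 0.2, noise_cv = 0.02,
                           true_abundances = NULL, n_rows = 8, seed = 1) {
  check_seed(seed)
  if (n_columns %% n_plex_sets != 0)
    stop_config("n_plex_sets must divide n_columns (one calibration column per plex set)")
  if (noise_cv < 0 || lane_factor_sd < 0 || plex_factor_sd < 0 ||
      content_factor_sd < 0)
    stop_value("factor sds and noise_cv must be >= 0")
  if (is.null(true_abundances)) {
    true_abundances <- setNames(
      round(exp(seq(log(30), log(30000), length.out = 12))),
      sprintf("GENE_%02d", 1:12))
  }
  withr::with_seed(seed, {
    pos_truth <- c(POS_A = 8192, POS_B = 2048, POS_C = 512,
                   POS_D = 128, POS_E = 32, POS_F = 8)
    hk_truth <- c(GUSB = 800, HPRT1 = 1200, NOL7 = 600)
    probes <- data.frame(
      probe_id = c(names(pos_truth), names(hk_truth), names(true_abundances)),
      class = c(rep("Positive", length(pos_truth)),
                rep("Housekeeping", length(hk_truth)),
                rep("Endogenous", length(true_abundances))),
      stringsAsFactors = FALSE)
    cols_per_plex <- n_columns / n_plex_sets
    col_plex <- rep(seq_len(n_plex_sets), each = cols_per_plex)
    cal_cols <- seq_len(n_plex_sets) * cols_per_plex  # last column of each block
    wells <- expand.grid(row = seq_len(n_rows), column = seq_len(n_columns))
    wells <- data.frame(
      well = sprintf("%s%02d", LETTERS[wells$row], wells$column),
      column = wells$column, row = wells$row,
      plex_set = paste0("plex_", col_plex[wells$column]),
      sample_role = ifelse(wells$column %in% cal_cols,
                           "calibration", "experimental"),
      stringsAsFactors = FALSE)
    truth_vec <- c(pos_truth, hk_truth, true_abundances)
    truth_mat <- matrix(truth_vec, nrow(wells), nrow(probes), byrow = TRUE,
                        dimnames = list(wells$well, probes$probe_id))
    lane <- setNames(exp(rnorm(n_columns, 0, lane_factor_sd)),
                     paste0("col_", seq_len(n_columns)))
    plex <- matrix(exp(rnorm(nrow(probes) * n_plex_sets, 0, plex_factor_sd)),
                   nrow(probes), n_plex_sets,
                   dimnames = list(probes$probe_id,
                                   paste0("plex_", seq_len(n_plex_sets))))
    plex[probes$class == "Positive", ] <- 1
    content <- setNames(exp(rnorm(nrow(wells), 0, content_factor_sd)),
                        wells$well)
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- matrix(exp(rnorm(length(truth_mat), -sdlog^2 / 2, sdlog)),
                    nrow(truth_mat), ncol(truth_mat))
    counts <- truth_mat *
      lane[wells$column] * content[wells$well] * noise *
      t(plex[, wells$plex_set])
    dimnames(counts) <- dimnames(truth_mat)
    plate <- PlateFile("sim_plate", wells, probes, counts)
    list(plate = plate,
         truth = list(abundances = truth_mat, lane_factors = lane,
                      plex_factors = plex, content_factors = content))
  })
}

#' Evaluate the four-parameter logistic inhibition curve
#'
#' `y(d) = Imax + (I0 - Imax) / (1 + (d/IC50)^HC)`, with `y(0) = I0` taken
#' as the exact zero-dose limit (valid for `HC > 0`).
#'
#' @param dose non-negative dose vector.
#' @param I0,Imax,IC50,HC curve parameters; `IC50 > 0`, `HC > 0`.
#' @return predicted response vector.
#' @export
fourpl_inhibition <- function(dose, I0, Imax, IC50, HC) {
  frac <- ifelse(dose == 0, 0, (dose / IC50)^HC)
  Imax + (I0 - Imax) / (1 + frac)
}

#' Evaluate the four-parameter logistic activation curve
#'
#' `y(d) = bottom + (top - bottom) / (1 + (EC50/d)^HC)`, with
#' `y(0) = bottom` as the zero-dose limit.
#'
#' @param dose non-negative dose vector.
#' @param bottom,top,EC50,HC curve parameters.
#' @return predicted response vector.
#' @export
fourpl_activation <- function(dose, bottom, top, EC50, HC) {
  frac <- ifelse(dose == 0, Inf, (EC50 / dose)^HC)
  bottom + (top - bottom) / (1 + frac)
}

#' Simulate dose-response observations around a 4PL curve
#'
#' Replicated responses with multiplicative Gaussian noise
#' (`response = curve(dose) * (1 + N(0, cv))`, truncated at 0), the error
#' structure of a plate-based readout reported as mean +/- SD.
#'
#' @param params list with `I0`, `IC50`, `Imax`, `HC` (inhibition mode).
#' @param doses dose vector; defaults to a vehicle (0) plus 8 half-log
#'   doses, the design used for inhibitor titrations.
#' @param n_reps replicates per dose (default 4).
#' @param cv coefficient of variation of the noise (>= 0).
#' @param seed RNG seed.
#' @return data.frame with `dose`, `replicate`, `response`.
#' @export
simulate_dose_response <- function(params, doses = c(0, 10 * 10^(seq(0, 3.5, 0.5))),
                                   n_reps = 4, cv = 0.05, seed = 1) {
  check_seed(seed)
  if (cv < 0) stop_value("cv must be >= 0")
  stopifnot(all(c("I0", "IC50", "Imax", "HC") %in% names(params)))
  withr::with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(n_reps), dose = doses)
    mu <- fourpl_inhibition(grid$dose, params$I0, params$Imax,
                            params$IC50, params$HC)
    resp <- pmax(0, mu * (1 + rnorm(nrow(grid), 0, cv)))
    data.frame(dose = grid$dose, replicate = grid$replicate, response = resp)
  })
}

#' Simulate a two-inhibitor dose grid of Poisson counts
#'
#' Counts are drawn `Poisson(exp(b0 + bA*a + bJ*j + bAJ*a*j))` where `a`
#' and `j` are ordinal dose indices (0 = vehicle). This is exactly the
#' generative model of the interaction GLM, so coefficient recovery is
#' well-posed.
#'
#' @param beta list/vector with `b0`, `bA`, `bJ`, `bAJ` (log scale).
#' @param a_levels,j_levels dose indices (default `0:2`, a vehicle plus two
#'   experimental doses per inhibitor).
#' @param n_reps replicates per grid cell (default 3).
#' @param a_conc,j_conc concentrations attached to the indices (defaults
#'   mirror a sub-IC50 titration: 0/31/62 nM and 0/7.8/15.6 nM).
#' @param gene gene id carried in the output.
#' @param seed RNG seed.
#' @return data.frame with `gene`, `conc_A`, `conc_J`, `a_index`, `j_index`,
#'   `replicate`, `count`.
#' @export
simulate_dual_inhibitor_grid <- function(beta, a_levels = 0:2, j_levels = 0:2,
                                         n_reps = 3,
                                         a_conc = NULL, j_conc = NULL,
                                         gene = "geneX", seed = 1) {
  check_seed(seed)
  beta <- as.list(beta)
  stopifnot(all(c("b0", "bA", "bJ", "bAJ") %in% names(beta)))
  if (is.null(a_conc)) a_conc <- c(0, 31, 62)[seq_along(a_levels)]
  if (is.null(j_conc)) j_conc <- c(0, 7.8, 15.6)[seq_along(j_levels)]
  withr::with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(n_reps),
                        a_index = a_levels, j_index = j_levels)
    mu <- exp(beta$b0 + beta$bA * grid$a_index + beta$bJ * grid$j_index +
                beta$bAJ * grid$a_index * grid$j_index)
    data.frame(gene = gene,
               conc_A = a_conc[match(grid$a_index, a_levels)],
               conc_J = j_conc[match(grid$j_index, j_levels)],
               a_index = grid$a_index, j_index = grid$j_index,
               replicate = grid$replicate,
               count = rpois(nrow(grid), mu),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a peak landscape with planted synergy-specific elements
#'
#' Generates disjoint genomic intervals carrying per-condition fragment
#' counts. Background peaks have a common mean across the four conditions;
#' planted "enhanced" elements keep their baseline accessibility in the
#' single-stimulus conditions but gain `fold` times the signal under
#' costimulation; planted "de novo" elements are near-silent everywhere
#' except the costimulated condition. Counts are Poisson; sequencing depths
#' are equal across conditions by default.
#'
#' @param n_peaks background peaks (default 5000).
#' @param n_ssae_enhanced,n_ssae_denovo planted element counts (default 20
#'   each).
#' @param signal_model list overriding any of: `background_range`
#'   (c(50, 500) mean counts), `fold` (4, planted combo enrichment),
#'   `denovo_base` (2, near-zero single/unstim mean for de novo sites),
#'   `denovo_combo_range` (c(80, 300)), `depth` (1e7 per condition),
#'   `peak_width` (400 bp), `spacing` (2000 bp).
#' @param seed RNG seed.
#' @return list with `peaks` (GRanges with `signal_<condition>` columns),
#'   `depths` (named per-condition), `peaks_A`/`peaks_B` (GRanges of peaks
#'   accessible in each single-stimulus condition: background + enhanced),
#'   and `truth` (data.frame `id`, `label`).
#' @export
simulate_peak_landscape <- function(n_peaks = 5000, n_ssae_enhanced = 20,
                                    n_ssae_denovo = 20, signal_model = list(),
                                    seed = 1) {
  check_seed(seed)
  sm <- modifyList(list(background_range = c(50, 500), fold = 4,
                        denovo_base = 2, denovo_combo_range = c(80, 300),
                        depth = 1e7, peak_width = 400, spacing = 2000),
                   signal_model)
  n_total <- n_peaks + n_ssae_enhanced + n_ssae_denovo
  if (n_total < 1) stop_value("need at least one peak")
  withr::with_seed(seed, {
    label <- sample(c(rep("background", n_peaks),
                      rep("enhanced", n_ssae_enhanced),
                      rep("de_novo", n_ssae_denovo)))
    chrom <- paste0("chr", 1 + (seq_len(n_total) - 1) %% 5)
    idx_on_chr <- stats::ave(seq_len(n_total), chrom, FUN = seq_along)
    start0 <- (idx_on_chr - 1) * sm$spacing + 1000
    base <- exp(runif(n_total, log(sm$background_range[1]),
                      log(sm$background_range[2])))
    mu <- cbind(unstim = base, cytoA = base, cytoB = base, combo = base)
    enh <- label == "enhanced"
    mu[enh, "combo"] <- base[enh] * sm$fold
    dnv <- label == "de_novo"
    mu[dnv, c("unstim", "cytoA", "cytoB")] <- sm$denovo_base
    mu[dnv, "combo"] <- exp(runif(sum(dnv), log(sm$denovo_combo_range[1]),
                                  log(sm$denovo_combo_range[2])))
    sig <- apply(mu, 2, function(m) rpois(n_total, m))
    ids <- sprintf("peak_%05d", seq_len(n_total))
    gr <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = start0 + 1, width = sm$peak_width))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      id = ids, signal_unstim = sig[, "unstim"], signal_cytoA = sig[, "cytoA"],
      signal_cytoB = sig[, "cytoB"], signal_combo = sig[, "combo"])
    gr <- GenomicRanges::sort(gr)
    ord_label <- label[match(gr$id, ids)]
    present_single <- ord_label %in% c("background", "enhanced")
    list(peaks = gr,
         depths = setNames(rep(sm$depth, 4), SYN_CONDITIONS),
         peaks_A = gr[present_single], peaks_B = gr[present_single],
         truth = data.frame(id = gr$id, label = ord_label,
                            stringsAsFactors = FALSE))
  })
}
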