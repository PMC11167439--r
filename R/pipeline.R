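#' Run every analysis end to end on synthetic data with known truth
#'
#' Generates one synthetic dataset per analysis from a single seed, runs the
#' corresponding method, and reports recovered quantities against the
#' planted truth in a machine-readable list: synergy outlier calling
#' (sensitivity / false-positive rate), plate normalization (correlation of
#' normalized counts with true abundances), 4PL dose-response fitting
#' (parameter recovery), the Poisson interaction GLM (coefficient recovery,
#' Wald p, per-dose trends) and SSAE calling (planted-element recovery and
#' class counts).
#'
#' @param seed integer seed driving all generators (sub-analyses use fixed
#'   small offsets of it).
#' @param out_dir optional directory; when given, writes `report.json` plus
#'   the intermediate tables (counts TSV, plate file, SSAE BED).
#' @param glm_truth,dr_truth generative parameters for the GLM grid and the
#'   dose-response curve; the defaults mirror a sub-IC50 two-inhibitor
#'   titration (baseline 1000 counts, 3.5% per-dose single-inhibitor effect
#'   deepening to 11.8% at the top co-dose) and an inhibitor with IC50 68.5
#'   (dose units) with Hill coefficient 2.25.
#' @return the report, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(seed = 1, out_dir = NULL,
                         glm_truth = list(b0 = log(1000), bA = -0.2,
                                          bJ = log(0.965),
                                          bAJ = (log(0.882) - log(0.965)) / 2),
                         dr_truth = list(I0 = 100, Imax = 0, IC50 = 68.5,
                                         HC = 2.25)) {
  check_seed(seed)
  report <- list(seed = seed)

  # 1. synergy outlier calling on planted NB counts
  sim <- simulate_expression_counts(seed = seed)
  contrasts <- contrast_table(sim$counts)
  calls <- call_synergy_genes(contrasts)
  merged <- merge(calls$table, sim$truth, by = "gene")
  pos_truth <- merged$label == "positive_outlier"
  additive <- merged$label == "additive"
  report$synergy <- list(
    n_genes = nrow(merged),
    n_planted_positive = sum(pos_truth),
    n_called_positive = sum(merged$outlier_class == "positive"),
    sensitivity = mean(merged$outlier_class[pos_truth] == "positive"),
    false_positive_rate = mean(merged$outlier_class[additive] != "none"),
    cutoffs = as.list(calls$cutoffs))

  # 2. plate normalization recovery
  plate_sim <- simulate_plate(seed = seed + 1)
  norm <- normalize_pipeline(plate_sim$plate)
  endo <- probe_ids(plate_sim$plate, "Endogenous")
  r <- stats::cor(log2(as.vector(norm$normalized[, endo])),
                  log2(as.vector(plate_sim$truth$abundances[, endo])))
  report$nanostring <- list(recovery_correlation = r,
                            n_wells = nrow(norm$normalized),
                            n_probes = ncol(norm$normalized))

  # 3. dose-response parameter recovery (cv 5%, n = 4 per dose)
  dr <- simulate_dose_response(dr_truth, cv = 0.05, seed = seed + 2)
  fit <- fit_inhibition_4pl(dr$dose, dr$response)
  report$dose_response <- list(
    truth = dr_truth,
    fit = fit[c("I0", "Imax", "IC50", "HC", "rss", "converged")],
    ic50_rel_error = abs(fit$IC50 - dr_truth$IC50) / dr_truth$IC50,
    hc_rel_error = abs(fit$HC - dr_truth$HC) / dr_truth$HC)

  # 4. interaction GLM on a 3x3 grid, n = 3 per cell
  grid <- simulate_dual_inhibitor_grid(glm_truth, seed = seed + 3)
  design <- encode_dose_design(grid)
  gfit <- fit_poisson_interaction(design)
  trends <- marginal_trends(gfit)
  tJ <- trends[trends$trend_of == "J", ]
  report$glm <- list(
    truth = glm_truth,
    coefficients = as.list(gfit$coefficients),
    wald = wald_anova(gfit),
    synergy_call = call_synergy(gfit),
    percent_per_dose_J_at_a0 = tJ$percent_per_dose[tJ$at_index == 0],
    percent_per_dose_J_at_a2 = tJ$percent_per_dose[tJ$at_index == 2],
    dispersion = gfit$dispersion)

  # 5. SSAE calling on a planted landscape
  land <- simulate_peak_landscape(seed = seed + 4)
  ssae <- ssae_workflow(land$peaks, land$peaks_A, land$peaks_B,
                        depths = land$depths)
  truth_cls <- setNames(land$truth$label, land$truth$id)
  planted <- land$truth$id[land$truth$label != "background"]
  recovered <- intersect(planted, ssae$id)
  report$ssae <- list(
    n_peaks = length(land$peaks),
    n_planted = length(planted),
    n_ssae = length(ssae),
    planted_recovery = length(recovered) / length(planted),
    n_background_called = sum(truth_cls[ssae$id] == "background"),
    n_enhanced = sum(ssae$class == "enhanced"),
    n_de_novo = sum(ssae$class == "de_novo"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_count_table(sim$counts, file.path(out_dir, "counts.tsv"))
    write_plate(plate_sim$plate, file.path(out_dir, "plate.tsv"))
    write_bed_signal(ssae, file.path(out_dir, "ssae.bed"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(invisible(report))
  }
  report
}
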