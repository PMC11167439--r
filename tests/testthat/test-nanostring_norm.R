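# two-column, two-plex fixture used by the stage examples; counts chosen so
# the per-well positive geomeans and calibration/housekeeper values are easy
# to enumerate by hand
two_plex_plate <- function(counts) {
  make_test_plate(counts,
                  columns = c(1L, 1L, 2L, 2L),
                  plex_sets = c("plex_1", "plex_1", "plex_2", "plex_2"),
                  roles = c("experimental", "calibration",
                            "experimental", "calibration"),
                  probe_classes = c("Positive", "Positive", "Housekeeping",
                                    "Endogenous"))
}

test_that("stage 1 scales wells to their column's positive-control reference", {
  counts <- rbind(w1 = c(50, 200, 70, 10),    # positive geomean 100
                  w2 = c(200, 800, 70, 10),   # positive geomean 400
                  w3 = c(30, 30, 50, 5),
                  w4 = c(30, 30, 50, 5))
  colnames(counts) <- c("POS_A", "POS_B", "HK1", "G1")
  plate <- two_plex_plate(counts)
  res <- positive_control_normalize(plate)
  # column reference = geomean(100, 400) = 200 -> factors 2.0 and 0.5
  expect_equal(unname(res$factors[c("w1", "w2")]), c(2, 0.5))
  expect_equal(unname(res$factors[c("w3", "w4")]), c(1, 1))
  # after scaling, every well's positive geomean equals its column reference
  pos_geo <- apply(res$counts[, c("POS_A", "POS_B")], 1,
                   function(x) exp(mean(log(x))))
  expect_equal(unname(pos_geo), c(200, 200, 30, 30), tolerance = 1e-12)
  # identical wells -> factors exactly 1
  counts0 <- counts[c(3, 3, 3, 3), ]
  rownames(counts0) <- paste0("w", 1:4)
  expect_equal(unname(positive_control_normalize(two_plex_plate(counts0))$factors),
               rep(1, 4))
  counts[1, "POS_A"] <- 0
  expect_error(positive_control_normalize(two_plex_plate(counts)),
               class = "synergyscope_value_error")
})

test_that("stage 2 equalizes each gene's calibration counts across plex sets", {
  counts <- rbind(w1 = c(40, 40, 60, 500),
                  w2 = c(40, 40, 80, 100),   # calibration, plex 1: G1 = 100
                  w3 = c(40, 40, 90, 700),
                  w4 = c(40, 40, 80, 400))   # calibration, plex 2: G1 = 400
  colnames(counts) <- c("POS_A", "POS_B", "HK1", "G1")
  plate <- two_plex_plate(counts)
  res <- plex_calibration_normalize(plate$counts, plate)
  # G(G1) = geomean(100, 400) = 200 -> factors 2.0 (plex 1) and 0.5 (plex 2)
  expect_equal(unname(res$factors["G1", ]), c(2, 0.5))
  # calibration values now agree across plex sets
  expect_equal(res$counts["w2", "G1"], res$counts["w4", "G1"])
  expect_equal(res$counts["w2", "G1"], 200)
  # positives are untouched by plex calibration
  expect_equal(res$counts[, c("POS_A", "POS_B")],
               plate$counts[, c("POS_A", "POS_B")])
  # identical calibration counts -> all factors 1
  counts_id <- counts; counts_id[4, ] <- counts_id[2, ]
  plate_id <- two_plex_plate(counts_id)
  expect_true(all(abs(plex_calibration_normalize(plate_id$counts, plate_id)$factors - 1) < 1e-12))
})

test_that("stage 3 equalizes housekeeper geomeans across positions", {
  counts <- rbind(w1 = c(40, 40, 100, 500),
                  w2 = c(40, 40, 300, 100),
                  w3 = c(40, 40, 300, 700),
                  w4 = c(40, 40, 300, 400))
  colnames(counts) <- c("POS_A", "POS_B", "HK1", "G1")
  plate <- two_plex_plate(counts)
  res <- housekeeper_normalize(plate$counts, plate)
  # h = {100, 300, 300, 300}, M = 250 -> factors {2.5, 5/6, 5/6, 5/6}
  expect_equal(unname(res$factors), c(2.5, 5 / 6, 5 / 6, 5 / 6))
  expect_equal(unname(res$counts[, "HK1"]), rep(250, 4), tolerance = 1e-12)
  # equal housekeepers -> factors 1
  counts[, "HK1"] <- 200
  plate2 <- two_plex_plate(counts)
  expect_equal(unname(housekeeper_normalize(plate2$counts, plate2)$factors),
               rep(1, 4))
})

test_that("the noiseless pipeline is the identity and recovers planted factors", {
  idsim <- simulate_plate(n_columns = 4, n_plex_sets = 2, n_rows = 3,
                          lane_factor_sd = 0, plex_factor_sd = 0,
                          content_factor_sd = 0, noise_cv = 0, seed = 1)
  rep0 <- normalize_pipeline(idsim$plate)
  expect_equal(rep0$normalized, idsim$truth$abundances, tolerance = 1e-12)
  expect_true(all(abs(rep0$factors$stage1 - 1) < 1e-12))
  expect_true(all(abs(rep0$factors$stage3 - 1) < 1e-12))

  # lane factors only: stage 1 leaves a per-column constant; the full
  # pipeline restores truth up to one global constant
  lane_sim <- simulate_plate(n_columns = 4, n_plex_sets = 2, n_rows = 3,
                             lane_factor_sd = 0.4, plex_factor_sd = 0,
                             content_factor_sd = 0, noise_cv = 0, seed = 2)
  repl <- normalize_pipeline(lane_sim$plate)
  ratio1 <- repl$post1 / lane_sim$truth$abundances
  by_col <- split(as.vector(ratio1), lane_sim$plate$wells$column[row(ratio1)])
  for (r in by_col) expect_lt(diff(range(r)) / mean(r), 1e-9)
  # endogenous and housekeeping probes (the plex-calibrated set) end up
  # proportional to truth with one global constant
  gp <- lane_sim$plate$probes
  gset <- gp$probe_id[gp$class != "Positive"]
  ratio <- repl$normalized[, gset] / lane_sim$truth$abundances[, gset]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
})

test_that("normalization recovers truth under planted factors and noise", {
  sim <- simulate_plate(seed = 3)  # lane 0.3 / plex 0.3 / content 0.2, cv 2%
  rep <- normalize_pipeline(sim$plate)
  endo <- sim$plate$probes$probe_id[sim$plate$probes$class == "Endogenous"]
  r <- cor(log2(as.vector(rep$normalized[, endo])),
           log2(as.vector(sim$truth$abundances[, endo])))
  expect_gte(r, 0.99)
  # all factors positive and finite at every stage
  for (f in rep$factors) expect_true(all(is.finite(f) & unlist(f) > 0))
  # staged matrices chain: post-k = post-(k-1) x stage-k factors
  expect_equal(rep$post1, rep$raw * rep$factors$stage1, tolerance = 1e-12)
  expect_equal(rep$post3, rep$post2 * rep$factors$stage3, tolerance = 1e-12)
})

test_that("each stage is idempotent on its own output", {
  sim <- simulate_plate(n_columns = 6, n_plex_sets = 3, n_rows = 4, seed = 5)
  plate <- sim$plate
  s1 <- positive_control_normalize(plate)
  again1 <- positive_control_normalize(plate, counts = s1$counts)
  expect_true(all(abs(again1$factors - 1) < 1e-12))
  s2 <- plex_calibration_normalize(s1$counts, plate)
  again2 <- plex_calibration_normalize(s2$counts, plate)
  expect_true(all(abs(again2$factors - 1) < 1e-12))
  s3 <- housekeeper_normalize(s2$counts, plate)
  again3 <- housekeeper_normalize(s3$counts, plate)
  expect_true(all(abs(again3$factors - 1) < 1e-12))
})

test_that("reversed stage order still recovers a lane/content-only fixture", {
  sim <- simulate_plate(n_columns = 4, n_plex_sets = 2, n_rows = 3,
                        lane_factor_sd = 0.3, plex_factor_sd = 0,
                        content_factor_sd = 0.2, noise_cv = 0, seed = 6)
  plate <- sim$plate
  r3 <- housekeeper_normalize(plate$counts, plate)
  r2 <- plex_calibration_normalize(r3$counts, plate)
  r1 <- positive_control_normalize(plate, counts = r2$counts)
  ratio <- r1$counts / sim$truth$abundances
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
})

test_that("normalization preserves the zero pattern", {
  sim <- simulate_plate(n_columns = 4, n_plex_sets = 2, n_rows = 3, seed = 7)
  counts <- sim$plate$counts
  # zero an endogenous count in an experimental well
  wexp <- sim$plate$wells$well[sim$plate$wells$sample_role == "experimental"][1]
  counts[wexp, "GENE_01"] <- 0
  plate <- PlateFile("z", sim$plate$wells, sim$plate$probes, counts)
  rep <- normalize_pipeline(plate)
  expect_identical(rep$normalized == 0, plate$counts == 0)
})
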