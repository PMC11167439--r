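glm_truth <- list(b0 = log(1000), bA = -0.2, bJ = log(0.965),
                  bAJ = -0.0225)

fake_fit <- function(beta, vcov = diag(1e-4, 4), a_levels = 0:2,
                     j_levels = 0:2) {
  dimnames(vcov) <- list(names(beta), names(beta))
  structure(list(coefficients = unlist(beta), vcov = vcov,
                 converged = TRUE,
                 design = structure(list(a = a_levels, j = j_levels,
                                         gene = "g"), class = "DoseDesign")),
            class = "InteractionGLMFit")
}

test_that("dose concentrations are encoded as ordinal indices", {
  tab <- expand.grid(conc_A = c(0, 31, 62), conc_J = c(0, 7.8, 15.6),
                     replicate = 1:2)
  tab$count <- 100
  des <- encode_dose_design(tab)
  expect_equal(sort(unique(des$a_index)), 0:2)
  expect_equal(sort(unique(des$j_index)), 0:2)
  expect_equal(des$dose_map$A, c(0, 31, 62))
  # duplicate concentration rows share an index
  expect_equal(unique(des$a_index[tab$conc_A == 31]), 1L)
  # averaged mode collapses replicates per cell
  avg <- encode_dose_design(tab, average_replicates = TRUE)
  expect_equal(length(avg$response), 9)
  tab2 <- tab[tab$conc_A > 0, ]
  expect_error(encode_dose_design(tab2), class = "synergyscope_config_error")
})

test_that("saturated-constant and scale-equivariance identities hold", {
  tab <- expand.grid(conc_A = c(0, 1, 2), conc_J = c(0, 1, 2),
                     replicate = 1:3)
  tab$count <- 250
  fit <- fit_poisson_interaction(encode_dose_design(tab))
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients),
               c(log(250), 0, 0, 0), tolerance = 1e-8)

  tab$count <- 250 * rep(1:2, length.out = nrow(tab))
  f1 <- fit_poisson_interaction(encode_dose_design(tab))
  tab$count <- 2 * tab$count
  f2 <- fit_poisson_interaction(encode_dose_design(tab))
  expect_equal(f2$coefficients[["b0"]] - f1$coefficients[["b0"]], log(2),
               tolerance = 1e-8)
  expect_equal(f2$coefficients[-1], f1$coefficients[-1], tolerance = 1e-8)
})

test_that("IRLS matches stats::glm and direct likelihood maximization", {
  grid <- simulate_dual_inhibitor_grid(glm_truth, seed = 11)
  des <- encode_dose_design(grid)
  fit <- fit_poisson_interaction(des)

  ref <- stats::glm(count ~ a_index * j_index, family = poisson, data = grid)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)

  # independent route: direct numerical maximization of the Poisson
  # log-likelihood
  X <- cbind(1, des$a, des$j, des$a * des$j)
  nll <- function(b) { mu <- exp(drop(X %*% b)); sum(mu - des$response * log(mu)) }
  opt <- optim(c(log(mean(des$response)), 0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(fit$coefficients), opt$par, tolerance = 1e-6)
})

test_that("coefficients are recovered within 3 standard errors", {
  grid <- simulate_dual_inhibitor_grid(glm_truth, seed = 21)
  fit <- fit_poisson_interaction(encode_dose_design(grid))
  se <- sqrt(diag(fit$vcov))
  z <- abs(fit$coefficients - unlist(glm_truth)) / se
  expect_true(all(z < 3))
})

test_that("Wald statistics are definitional and handle the zero boundary", {
  grid <- simulate_dual_inhibitor_grid(glm_truth, seed = 31)
  fit <- fit_poisson_interaction(encode_dose_design(grid))
  w <- wald_anova(fit)
  se <- sqrt(diag(fit$vcov))
  expect_equal(w$W, unname((fit$coefficients / se)^2), tolerance = 1e-12)
  expect_equal(w$p, pchisq(w$W, 1, lower.tail = FALSE), tolerance = 1e-12)

  # a coefficient of exactly zero gives W = 0, p = 1
  f0 <- fake_fit(list(b0 = 5, bA = -0.1, bJ = -0.05, bAJ = 0))
  w0 <- wald_anova(f0)
  expect_equal(w0$W[w0$term == "bAJ"], 0)
  expect_equal(w0$p[w0$term == "bAJ"], 1)
})

test_that("marginal trends reproduce the percent-per-dose identities", {
  # bJ = ln(0.965): 3.5% per J dose in the absence of A; with
  # bAJ = (ln(0.882) - ln(0.965))/2, the effect at A index 2 is 11.8%
  f <- fake_fit(list(b0 = log(1000), bA = -0.2, bJ = log(0.965),
                     bAJ = (log(0.882) - log(0.965)) / 2))
  tr <- marginal_trends(f)
  tJ <- tr[tr$trend_of == "J", ]
  expect_equal(tJ$percent_per_dose[tJ$at_index == 0], 3.5, tolerance = 1e-12)
  expect_equal(tJ$percent_per_dose[tJ$at_index == 2], 11.8, tolerance = 1e-12)

  # no interaction -> the J trend is identical at every A level
  fni <- fake_fit(list(b0 = 5, bA = -0.1, bJ = -0.05, bAJ = 0))
  trni <- marginal_trends(fni)
  expect_equal(length(unique(trni$slope[trni$trend_of == "J"])), 1L)

  # percent-per-dose is a strictly monotone transform of the slope
  expect_true(all(diff(order(tJ$slope)) == diff(order(-tJ$percent_per_dose))))
})

test_that("trend estimates and errors agree with emmeans::emtrends", {
  skip_if_not_installed("emmeans")
  grid <- simulate_dual_inhibitor_grid(glm_truth, seed = 41)
  fit <- fit_poisson_interaction(encode_dose_design(grid))
  ref <- stats::glm(count ~ a_index * j_index, family = poisson, data = grid)
  emt <- as.data.frame(emmeans::emtrends(ref, ~a_index, var = "j_index",
                                         at = list(a_index = 0:2)))
  tJ <- marginal_trends(fit)
  tJ <- tJ[tJ$trend_of == "J", ]
  expect_equal(tJ$slope, emt$j_index.trend, tolerance = 1e-5)
  expect_equal(tJ$se, emt$SE, tolerance = 1e-4)
})

test_that("index relabeling leaves the interaction inference unchanged", {
  grid <- simulate_dual_inhibitor_grid(glm_truth, seed = 51)
  des <- encode_dose_design(grid)
  f1 <- fit_poisson_interaction(des)
  shifted <- des
  shifted$a <- des$a + 1
  shifted$j <- des$j + 1
  f2 <- fit_poisson_interaction(shifted)
  expect_equal(f2$coefficients[["bAJ"]], f1$coefficients[["bAJ"]],
               tolerance = 1e-6)
  expect_equal(wald_anova(f2)$p[4], wald_anova(f1)$p[4], tolerance = 1e-5)
})

test_that("synergy calls respect significance and direction", {
  se <- diag(c(1e-4, 1e-4, 1e-4, 1e-4))
  f_sig <- fake_fit(list(b0 = 5, bA = -0.1, bJ = -0.05, bAJ = -0.1), se)
  expect_true(call_synergy(f_sig)$called)
  f_anti <- fake_fit(list(b0 = 5, bA = -0.1, bJ = -0.05, bAJ = 0.1), se)
  res <- call_synergy(f_anti)
  expect_false(res$called)
  expect_true(res$direction_mismatch)
  f_ns <- fake_fit(list(b0 = 5, bA = -0.1, bJ = -0.05, bAJ = -0.01),
                   diag(c(1e-4, 1e-4, 1e-4, 1)))
  expect_false(call_synergy(f_ns)$called)

  # batch interface with BH adjustment keeps called set monotone
  grids <- lapply(61:64, function(s)
    simulate_dual_inhibitor_grid(glm_truth, seed = s))
  fits <- lapply(grids, function(g) fit_poisson_interaction(encode_dose_design(g)))
  batch <- call_synergy_batch(fits, adjust = "BH")
  expect_true(all(batch$p_adj >= batch$p))
})

test_that("degenerate designs are rejected", {
  tab <- data.frame(conc_A = c(0, 0, 1, 1), conc_J = c(0, 0, 1, 1),
                    count = c(10, 11, 9, 12))
  expect_error(fit_poisson_interaction(encode_dose_design(tab)),
               class = "synergyscope_config_error")
})
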