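#' Encode a two-inhibitor dose grid as ordinal dose indices
#'
#' Maps the distinct concentrations of each inhibitor (which must include a
#' vehicle, concentration 0) to ordinal indices 0, 1, 2, ... in ascending
#' concentration order. The interaction GLM is fit on these indices, so its
#' coefficients read as effects "per experimental dose"; concentration-
#' linear coding is available via `coding = "concentration"`.
#'
#' @param table data.frame with columns `conc_A`, `conc_J`, a response
#'   column (`response`, `count` or `normalized_count`) and optionally
#'   `gene`.
#' @param average_replicates collapse replicates to their cell mean before
#'   fitting (the published workflow fit averaged normalized counts; the
#'   default keeps replicate rows so the Poisson variance model, and hence
#'   the Wald test's calibration, is preserved).
#' @param coding `"index"` (default) or `"concentration"`.
#' @return object of class `DoseDesign`: `a`, `j` (model covariates),
#'   `a_index`, `j_index`, `response`, `dose_map` (index -> concentration
#'   per inhibitor), `gene`, `coding`.
#' @export
encode_dose_design <- function(table, average_replicates = FALSE,
                               coding = c("index", "concentration")) {
  coding <- match.arg(coding)
  if (!all(c("conc_A", "conc_J") %in% names(table)))
    stop_config("table needs conc_A and conc_J columns")
  resp_col <- intersect(c("response", "count", "normalized_count"), names(table))
  if (!length(resp_col)) stop_config("no response column found")
  resp <- table[[resp_col[1]]]
  if (any(resp < 0)) stop_value("responses must be >= 0")
  conc_a <- sort(unique(table$conc_A))
  conc_j <- sort(unique(table$conc_J))
  if (conc_a[1] != 0 || conc_j[1] != 0)
    stop_config("vehicle (concentration 0) required for both inhibitors")
  a_index <- match(table$conc_A, conc_a) - 1L
  j_index <- match(table$conc_J, conc_j) - 1L
  df <- data.frame(a_index = a_index, j_index = j_index, response = resp)
  if (average_replicates) {
    df <- stats::aggregate(response ~ a_index + j_index, df, mean)
  }
  cov_a <- if (coding == "index") df$a_index else conc_a[df$a_index + 1L]
  cov_j <- if (coding == "index") df$j_index else conc_j[df$j_index + 1L]
  structure(list(a = cov_a, j = cov_j,
                 a_index = df$a_index, j_index = df$j_index,
                 response = df$response,
                 dose_map = list(A = conc_a, J = conc_j),
                 gene = if (!is.null(table$gene)) unique(table$gene) else NA,
                 coding = coding),
            class = "DoseDesign")
}

#' Fit the Poisson interaction GLM for two-inhibitor synergy
#'
#' Maximizes the Poisson log-likelihood (quasi-score equations for
#' non-integer normalized counts) for
#' `log mu = b0 + bA*a + bJ*j + bAJ*a*j` by iteratively reweighted least
#' squares. The multiplicative interaction coefficient `bAJ` captures
#' synergy of inhibition: a negative `bAJ` means each inhibitor deepens the
#' per-dose effect of the other. The covariance matrix is the inverse
#' Fisher information at the optimum; a Pearson dispersion estimate is
#' reported so overdispersion can be judged (no correction is applied).
#'
#' @param design a [encode_dose_design()] result.
#' @param max_iter,tol IRLS control: stop when the relative deviance change
#'   drops below `tol` (default 1e-8) or after `max_iter` (default 50)
#'   iterations, flagging non-convergence rather than erroring.
#' @param integer_mode round responses to integers before fitting (for
#'   comparison with strict count likelihoods).
#' @return object of class `InteractionGLMFit`: `coefficients` (b0, bA, bJ,
#'   bAJ), `vcov`, `deviance`, `converged`, `iterations`, `dispersion`,
#'   `fitted`, `design`.
#' @export
fit_poisson_interaction <- function(design, max_iter = 50, tol = 1e-8,
                                    integer_mode = FALSE) {
  stopifnot(inherits(design, "DoseDesign"))
  y <- design$response
  if (integer_mode) y <- round(y)
  a <- design$a; j <- design$j
  if (length(unique(a)) < 2 || length(unique(j)) < 2)
    stop_config("need >= 2 dose levels per inhibitor")
  X <- cbind(b0 = 1, bA = a, bJ = j, bAJ = a * j)
  if (qr(X)$rank < ncol(X))
    stop_config("degenerate design: interaction not identifiable")
  dev_fun <- function(mu) {
    term <- ifelse(y > 0, y * log(y / mu), 0)
    2 * sum(term - (y - mu))
  }
  eta <- log(pmax(y, 0.5))
  mu <- exp(eta)
  dev <- dev_fun(mu)
  beta <- rep(0, ncol(X))
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    z <- eta + (y - mu) / mu
    XtW <- t(X * mu)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta <- drop(beta_new)
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    dev_new <- dev_fun(mu)
    if (abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  info <- t(X * mu) %*% X
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, 4, 4))
  dimnames(vc) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  df_resid <- length(y) - ncol(X)
  pearson <- sum((y - mu)^2 / mu)
  structure(list(coefficients = beta, vcov = vc, deviance = dev,
                 converged = converged, iterations = iter,
                 dispersion = if (df_resid > 0) pearson / df_resid else NA_real_,
                 fitted = mu, design = design),
            class = "InteractionGLMFit")
}

#' @export
print.InteractionGLMFit <- function(x, ...) {
  cat("Poisson interaction GLM (log mu = b0 + bA*a + bJ*j + bAJ*a*j)\n")
  se <- sqrt(diag(x$vcov))
  print(round(cbind(estimate = x$coefficients, se = se), 4))
  cat(sprintf("deviance %.4g; dispersion %.3g; %s in %d iterations\n",
              x$deviance, x$dispersion,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Wald chi-square tests per GLM term
#'
#' For each coefficient, `W = (estimate/se)^2` referred to chi-square with
#' 1 df. The interaction row is the synergy-of-inhibition test.
#'
#' @param fit an [fit_poisson_interaction()] result.
#' @return data.frame with `term`, `estimate`, `se`, `W`, `p` (NA where the
#'   covariance is singular).
#' @export
wald_anova <- function(fit) {
  stopifnot(inherits(fit, "InteractionGLMFit"))
  if (!fit$converged) warning("Wald tests from a non-converged fit")
  se <- sqrt(diag(fit$vcov))
  W <- (fit$coefficients / se)^2
  p <- pchisq(W, df = 1, lower.tail = FALSE)
  bad <- !is.finite(se) | se <= 0
  W[bad] <- NA_real_; p[bad] <- NA_real_
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients), se = unname(se),
             W = unname(W), p = unname(p), stringsAsFactors = FALSE)
}

#' Per-dose marginal trends from the interaction fit
#'
#' The log-scale trend of inhibitor J at A-dose index `a` is
#' `slope_J(a) = bJ + bAJ * a` (and symmetrically for A at each J level),
#' with the delta-method standard error
#' `sqrt(var(bJ) + a^2 var(bAJ) + 2a cov(bJ, bAJ))`. The companion
#' `percent_per_dose = 100 * (1 - exp(slope))` reads as the percent
#' decrease in expected counts per experimental dose step.
#'
#' @param fit an [fit_poisson_interaction()] result.
#' @param level confidence level for the normal-theory interval.
#' @return data.frame of class `TrendTable`: `trend_of` ("J" or "A"),
#'   `at_inhibitor`, `at_index`, `slope`, `se`, `ci_lo`, `ci_hi`,
#'   `percent_per_dose`, `percent_lo`, `percent_hi`.
#' @export
marginal_trends <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "InteractionGLMFit"))
  b <- fit$coefficients; v <- fit$vcov
  zq <- qnorm(1 - (1 - level) / 2)
  one_dir <- function(main, other_levels, other_name) {
    slope <- b[[main]] + b[["bAJ"]] * other_levels
    var_s <- v[main, main] + other_levels^2 * v["bAJ", "bAJ"] +
      2 * other_levels * v[main, "bAJ"]
    se <- sqrt(pmax(var_s, 0))
    lo <- slope - zq * se; hi <- slope + zq * se
    data.frame(trend_of = if (main == "bJ") "J" else "A",
               at_inhibitor = other_name, at_index = other_levels,
               slope = slope, se = se, ci_lo = lo, ci_hi = hi,
               percent_per_dose = 100 * (1 - exp(slope)),
               percent_lo = 100 * (1 - exp(hi)),
               percent_hi = 100 * (1 - exp(lo)),
               stringsAsFactors = FALSE)
  }
  a_levels <- sort(unique(fit$design$a))
  j_levels <- sort(unique(fit$design$j))
  out <- rbind(one_dir("bJ", a_levels, "A"), one_dir("bA", j_levels, "J"))
  class(out) <- c("TrendTable", "data.frame")
  out
}

#' Call synergistic inhibition from the interaction term
#'
#' Synergy of inhibition is called when the interaction Wald p-value is at
#' or below `alpha` and the interaction coefficient has the requested sign
#' (negative: the inhibitors deepen each other's effect). A significant
#' interaction of the opposite sign is flagged as antagonism-direction and
#' not called.
#'
#' @param fit an [fit_poisson_interaction()] result.
#' @param alpha significance level (default 0.05).
#' @param direction `"negative"` (default) or `"positive"`.
#' @return list: `called`, `p`, `estimate`, `direction`,
#'   `direction_mismatch`, `gene`.
#' @export
call_synergy <- function(fit, alpha = 0.05, direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  w <- wald_anova(fit)
  row <- w[w$term == "bAJ", ]
  sign_ok <- if (direction == "negative") row$estimate < 0 else row$estimate > 0
  significant <- is.finite(row$p) && row$p <= alpha
  list(called = significant && sign_ok,
       p = row$p, estimate = row$estimate, direction = direction,
       direction_mismatch = significant && !sign_ok,
       gene = fit$design$gene)
}

#' Batch synergy calls with optional BH correction
#'
#' @param fits list of [fit_poisson_interaction()] results (one per gene).
#' @param alpha significance level applied to the (possibly adjusted)
#'   interaction p-values.
#' @param direction passed to [call_synergy()].
#' @param adjust `"none"` (per-gene conclusions, the default) or `"BH"`.
#' @return data.frame with `gene`, `estimate`, `p`, `p_adj`, `called`.
#' @export
call_synergy_batch <- function(fits, alpha = 0.05, direction = "negative",
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  rows <- lapply(fits, call_synergy, alpha = 1, direction = direction)
  p <- vapply(rows, `[[`, 0, "p")
  est <- vapply(rows, `[[`, 0, "estimate")
  p_adj <- if (adjust == "BH") p.adjust(p, "BH") else p
  sign_ok <- if (direction == "negative") est < 0 else est > 0
  data.frame(gene = vapply(rows, function(r) as.character(r$gene)[1], ""),
             estimate = est, p = p, p_adj = p_adj,
             called = p_adj <= alpha & sign_ok,
             stringsAsFactors = FALSE)
}
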