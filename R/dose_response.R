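#' Express responses as percent of a reference
#'
#' @param responses numeric vector.
#' @param reference positive scalar (e.g. the vehicle mean).
#' @return `100 * responses / reference`.
#' @export
percent_of_max <- function(responses, reference) {
  if (length(reference) != 1 || !is.finite(reference) || reference <= 0)
    stop_value("reference must be a single positive number")
  100 * responses / reference
}

#' Percent inhibition relative to vehicle
#'
#' @param treated treated response(s).
#' @param vehicle positive vehicle response.
#' @return list with `percent` (`100 * (1 - treated/vehicle)`) and
#'   `clipped` flag(s), TRUE where the raw value was negative (treated above
#'   vehicle); values are reported unclipped.
#' @export
percent_inhibition <- function(treated, vehicle) {
  if (any(vehicle <= 0)) stop_value("vehicle must be > 0")
  pct <- 100 * (1 - treated / vehicle)
  list(percent = pct, clipped = pct < 0)
}

# Shared 4PL least-squares engine on the inhibition parameterization
# y(d) = Imax + (I0 - Imax) / (1 + (d/IC50)^HC).
# Optimizes in (I0, Imax, log IC50, log HC) with HC box bounds and a
# multi-start over log-spaced IC50 initializations spanning the dose range.
fit_4pl_core <- function(doses, responses, fix_lower_at = NULL,
                         n_starts = 7, hc_bounds = c(0.1, 10)) {
  stopifnot(length(doses) == length(responses))
  if (any(doses < 0)) stop_value("doses must be >= 0")
  if (any(responses < 0)) stop_value("responses must be >= 0")
  pos <- unique(doses[doses > 0])
  if (length(pos) < 4)
    stop_value("need >= 4 distinct positive doses for a 4PL fit")
  fixed_lower <- !is.null(fix_lower_at)

  model <- function(par) {
    I0 <- par[["I0"]]
    Imax <- if (fixed_lower) fix_lower_at else par[["Imax"]]
    fourpl_inhibition(doses, I0, Imax, exp(par[["logIC50"]]), exp(par[["logHC"]]))
  }
  resid_fn <- function(par) responses - model(par)

  lo_anchor <- mean(responses[doses == min(doses)])
  hi_anchor <- mean(responses[doses == max(doses)])
  ic50_starts <- exp(seq(log(min(pos)), log(max(pos)), length.out = n_starts))
  lower <- c(I0 = -Inf, Imax = -Inf, logIC50 = log(min(pos)) - log(100),
             logHC = log(hc_bounds[1]))
  upper <- c(I0 = Inf, Imax = Inf, logIC50 = log(max(pos)) + log(100),
             logHC = log(hc_bounds[2]))
  keep <- if (fixed_lower) c("I0", "logIC50", "logHC") else names(lower)

  best <- NULL
  for (s in ic50_starts) {
    start <- c(I0 = lo_anchor, Imax = hi_anchor, logIC50 = log(s), logHC = 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start[keep], fn = resid_fn,
                         lower = lower[keep], upper = upper[keep],
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop_value("4PL optimization failed from every start")
  par <- best$par
  list(I0 = unname(par[["I0"]]),
       Imax = if (fixed_lower) fix_lower_at else unname(par[["Imax"]]),
       IC50 = exp(unname(par[["logIC50"]])),
       HC = exp(unname(par[["logHC"]])),
       rss = best$deviance,
       converged = best$info %in% 1:4,
       rss_trace = best$rsstrace,
       fixed_lower = fixed_lower,
       n_obs = length(doses))
}

#' Fit a four-parameter logistic inhibition curve
#'
#' Unweighted least-squares fit of
#' `y(d) = Imax + (I0 - Imax) / (1 + (d/IC50)^HC)` with replicates entering
#' as individual points. Vehicle observations (dose 0) constrain `I0`
#' through the exact zero-dose limit of the model. `IC50` and `HC` are
#' optimized on the log scale with `HC` bounded in `[0.1, 10]`, restarting
#' from log-spaced `IC50` initializations across the dose range and keeping
#' the best residual sum of squares.
#'
#' @param doses non-negative doses (>= 4 distinct positive values).
#' @param responses responses, same length (e.g. percent of maximal
#'   expression).
#' @param fix_lower_at optional value at which to fix `Imax` (0 mirrors
#'   fitting with the bottom asymptote pinned to full inhibition).
#' @param log_x cosmetic flag recorded in the result: doses are displayed /
#'   reported on a log axis; the fit itself always treats dose 0 exactly.
#' @return object of class `DoseResponseFit`: `I0`, `Imax`, `IC50`, `HC`,
#'   `rss`, `converged`, `rss_trace`, `fixed_lower`, `n_obs`,
#'   `dose_log_space`.
#' @export
fit_inhibition_4pl <- function(doses, responses, fix_lower_at = NULL,
                               log_x = TRUE) {
  fit <- fit_4pl_core(doses, responses, fix_lower_at)
  fit$dose_log_space <- log_x
  class(fit) <- "DoseResponseFit"
  fit
}

#' @export
print.DoseResponseFit <- function(x, ...) {
  cat(sprintf(
    "4PL inhibition fit: I0=%.4g  Imax=%.4g%s  IC50=%.4g  HC=%.4g  (RSS %.4g, %s)\n",
    x$I0, x$Imax, if (x$fixed_lower) " [fixed]" else "", x$IC50, x$HC,
    x$rss, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit a four-parameter logistic activation curve
#'
#' Increasing form `y(d) = bottom + (top - bottom) / (1 + (EC50/d)^HC)`,
#' algebraically the same surface as the inhibition parameterization with
#' the asymptotes relabeled, so the same optimizer is used.
#'
#' @param doses non-negative doses (>= 4 distinct positive values).
#' @param responses responses, same length.
#' @return object of class `ActivationFit`: `bottom`, `top`, `EC50`, `HC`,
#'   `rss`, `converged`, `rss_trace`, `n_obs`.
#' @export
fit_activation_4pl <- function(doses, responses) {
  fit <- fit_4pl_core(doses, responses)
  structure(list(bottom = fit$I0, top = fit$Imax, EC50 = fit$IC50,
                 HC = fit$HC, rss = fit$rss, converged = fit$converged,
                 rss_trace = fit$rss_trace, n_obs = fit$n_obs),
            class = "ActivationFit")
}

#' @export
print.ActivationFit <- function(x, ...) {
  cat(sprintf(
    "4PL activation fit: bottom=%.4g  top=%.4g  EC50=%.4g  HC=%.4g  (RSS %.4g, %s)\n",
    x$bottom, x$top, x$EC50, x$HC, x$rss,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Predict from a dose-response fit
#'
#' @param object a `DoseResponseFit` or `ActivationFit`.
#' @param doses doses at which to evaluate the fitted curve.
#' @param ... unused.
#' @return predicted responses.
#' @export
predict.DoseResponseFit <- function(object, doses, ...) {
  fourpl_inhibition(doses, object$I0, object$Imax, object$IC50, object$HC)
}

#' @rdname predict.DoseResponseFit
#' @export
predict.ActivationFit <- function(object, doses, ...) {
  fourpl_activation(doses, object$bottom, object$top, object$EC50, object$HC)
}
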