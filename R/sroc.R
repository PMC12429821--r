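#' Summary ROC curve from bivariate parameters
#'
#' Maps the fitted bivariate normal distribution of (logit sensitivity,
#' logit specificity) to ROC space through the conditional-expectation
#' ("regression of logit-Se on logit-Sp") line:
#' `Se(f) = inv_logit(mu_se + rho * (sigma_se / sigma_sp) *
#' (logit(1 - f) - mu_sp))` for false-positive rate `f` in (0, 1).
#' With `rho = 0` the summary line is flat at the pooled sensitivity; with
#' negative correlation (the usual threshold effect) it rises with `f`.
#'
#' @param params A [bivariate_params()] object.
#' @param fpr Grid of false-positive rates strictly inside (0, 1); the
#'   default covers 0.0005 to 0.9995 in 1999 points. Endpoints 0 and 1 are
#'   excluded (logit undefined) and handled by limits in [sroc_auc()].
#' @return A `data.frame` of class `"dta_sroc"` with columns `fpr`, `sens`,
#'   carrying `params` as an attribute.
#' @export
sroc_curve <- function(params, fpr = seq(0.0005, 0.9995, length.out = 1999)) {
  stopifnot(inherits(params, "bivariate_params"))
  if (any(fpr <= 0 | fpr >= 1)) stop("fpr grid must lie strictly in (0, 1)")
  if (is.unsorted(fpr, strictly = TRUE)) stop("fpr grid must be increasing")
  sens <- .sroc_se(fpr, params$mu_se, params$mu_sp,
                   params$sigma_se, params$sigma_sp, params$rho)
  structure(data.frame(fpr = fpr, sens = sens),
            class = c("dta_sroc", "data.frame"), params = params)
}

.sroc_se <- function(f, mu_se, mu_sp, s_se, s_sp, rho) {
  inv_logit(mu_se + rho * (s_se / s_sp) * (logit(1 - f) - mu_sp))
}

# Limit of Se(f) as f -> 0+ or 1-: logit(1 - f) tends to +Inf / -Inf, so
# the exponent diverges with the sign of rho.
.sroc_limits <- function(params) {
  if (params$rho == 0) {
    rep(inv_logit(params$mu_se), 2)
  } else if (params$rho < 0) {
    c(0, 1)
  } else {
    c(1, 0)
  }
}

#' Area under a summary ROC curve
#'
#' Trapezoidal integral of `Se(f)` over the full false-positive-rate range
#' \[0, 1\]; the endpoint values are the analytic limits of the curve (0/1
#' anchors for a correlated model, the flat level for `rho = 0`). The full
#' range is used rather than the observed-FPR range; restricted-range AUC
#' is a common alternative, so published AUC values are comparable only as
#' soft checks.
#'
#' @param curve A `"dta_sroc"` object from [sroc_curve()].
#' @return The AUC (scalar in \[0, 1\]).
#' @export
sroc_auc <- function(curve) {
  stopifnot(inherits(curve, "dta_sroc"))
  lim <- .sroc_limits(attr(curve, "params"))
  f <- c(0, curve$fpr, 1)
  s <- c(lim[1], curve$sens, lim[2])
  if (is.unsorted(f, strictly = TRUE)) stop("unsorted grid")
  sum(diff(f) * (utils::head(s, -1) + utils::tail(s, -1)) / 2)
}

#' Draw-wise AUC distribution from a fitted model
#'
#' Computes the SROC AUC for each retained posterior draw (thinned to at
#' most `max_draws` for tractability) and returns the distribution together
#' with its summary.
#'
#' @param fit A `"dta_fit"` object.
#' @param fpr Grid passed to [sroc_curve()].
#' @param max_draws Upper bound on the number of draws used (default 2000,
#'   evenly thinned).
#' @return A list with `auc` (the draw-wise values) and `summary` (median,
#'   mean, 95% interval).
#' @export
sroc_auc_draws <- function(fit, fpr = seq(0.0005, 0.9995, length.out = 1999),
                           max_draws = 2000) {
  stopifnot(inherits(fit, "dta_fit"))
  d <- fit$draws
  idx <- if (nrow(d) > max_draws)
    round(seq(1, nrow(d), length.out = max_draws)) else seq_len(nrow(d))
  lf <- logit(1 - fpr)
  w <- diff(c(0, fpr, 1))
  auc <- vapply(idx, function(i) {
    se <- inv_logit(d$mu_se[i] + d$rho[i] * (d$sigma_se[i] / d$sigma_sp[i]) *
                      (lf - d$mu_sp[i]))
    lim <- if (d$rho[i] == 0) rep(inv_logit(d$mu_se[i]), 2)
           else if (d$rho[i] < 0) c(0, 1) else c(1, 0)
    s <- c(lim[1], se, lim[2])
    sum(w * (utils::head(s, -1) + utils::tail(s, -1)) / 2)
  }, numeric(1))
  list(auc = auc, summary = summarize_posterior(data.frame(auc = auc)))
}

#' Per-study point estimates with exact binomial intervals
#'
#' Sensitivity and specificity per study with Clopper-Pearson 95% intervals
#' (beta-quantile form), the standard display statistics behind forest and
#' crosshair plots.
#'
#' @param tables `data.frame` of `tp`, `fp`, `tn`, `fn`.
#' @param level Confidence level, default 0.95.
#' @return A `data.frame` with one row per study: point estimates and
#'   interval bounds for both margins.
#' @export
study_intervals <- function(tables, level = 0.95) {
  tables <- as.data.frame(tables)
  a <- (1 - level) / 2
  cp <- function(x, n) {
    lo <- ifelse(x == 0, 0, qbeta(a, x, n - x + 1))
    hi <- ifelse(x == n, 1, qbeta(1 - a, x + 1, n - x))
    cbind(est = x / n, lower = lo, upper = hi)
  }
  se <- cp(tables$tp, tables$tp + tables$fn)
  sp <- cp(tables$tn, tables$tn + tables$fp)
  out <- data.frame(
    sens = se[, "est"], sens_lower = se[, "lower"], sens_upper = se[, "upper"],
    spec = sp[, "est"], spec_lower = sp[, "lower"], spec_upper = sp[, "upper"])
  if (!is.null(tables$study_id)) out <- cbind(study_id = tables$study_id, out)
  out
}
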