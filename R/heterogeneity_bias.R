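#' Study-level effects and variances on a chosen margin
#'
#' Converts 2x2 tables to per-study effect sizes with delta-method
#' within-study variances: logit sensitivity (`v = 1/tp + 1/fn`), logit
#' specificity (`v = 1/tn + 1/fp`), or the log diagnostic odds ratio
#' (`v = 1/tp + 1/fp + 1/tn + 1/fn`). Any table containing a zero cell has
#' 0.5 added to all four cells before either margin is computed (the
#' standard continuity correction, applied only when needed), which
#' guarantees finite effects and variances.
#'
#' @param tables `data.frame` of `tp`, `fp`, `tn`, `fn`.
#' @param margin One of `"sensitivity"`, `"specificity"`, `"lnDOR"`.
#' @return A `data.frame` of class `"margin_effects"` with columns `theta`,
#'   `v` (and `study_id` when available).
#' @export
logit_effects <- function(tables,
                          margin = c("sensitivity", "specificity", "lnDOR")) {
  margin <- match.arg(margin)
  tables <- as.data.frame(tables)
  cells <- tables[, c("tp", "fp", "tn", "fn")]
  zero <- apply(cells == 0, 1, any)
  cells[zero, ] <- cells[zero, ] + 0.5
  th <- with(cells, switch(margin,
    sensitivity = cbind(log(tp / fn), 1 / tp + 1 / fn),
    specificity = cbind(log(tn / fp), 1 / tn + 1 / fp),
    lnDOR = cbind(log(tp * tn / (fp * fn)),
                  1 / tp + 1 / fp + 1 / tn + 1 / fn)))
  out <- data.frame(theta = th[, 1], v = th[, 2])
  if (!is.null(tables$study_id)) out <- cbind(study_id = tables$study_id, out)
  structure(out, class = c("margin_effects", "data.frame"), margin = margin)
}

#' Cochran's Q and the I-squared statistic
#'
#' Fixed-effect inverse-variance pooling: weights `w_i = 1/v_i`, pooled
#' effect `theta_bar = sum(w theta) / sum(w)`, `Q = sum(w (theta -
#' theta_bar)^2)` on `k - 1` degrees of freedom, and `I2 = max(0, (Q - df) /
#' Q) * 100` (negative values truncated at zero). The p-value is the
#' chi-square upper tail of Q.
#'
#' @param effects A `"margin_effects"` data frame (or any frame with
#'   `theta` and `v` columns), k >= 2 rows.
#' @return A list of class `"heterogeneity_result"`: `Q`, `df`, `i2_pct`,
#'   `p`, `theta_pooled`.
#' @export
q_and_i2 <- function(effects) {
  effects <- as.data.frame(effects)
  k <- nrow(effects)
  if (k < 2) stop("heterogeneity requires at least 2 studies")
  w <- 1 / effects$v
  tb <- sum(w * effects$theta) / sum(w)
  Q <- sum(w * (effects$theta - tb)^2)
  df <- k - 1
  structure(list(Q = Q, df = df,
                 i2_pct = max(0, (Q - df) / Q) * 100,
                 p = pchisq(Q, df, lower.tail = FALSE),
                 theta_pooled = tb),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Q = %.2f on %d df (p = %.3g); I2 = %.1f%%\n",
              x$Q, x$df, x$p, x$i2_pct))
  invisible(x)
}

#' Funnel-plot coordinates with pseudo-confidence bounds
#'
#' Per-study points `(theta_i, sqrt(v_i))`, the fixed-effect center line,
#' and the 95% pseudo-confidence funnel `theta_bar +/- 1.96 * se` evaluated
#' over a standard-error grid (plus all observed standard errors).
#'
#' @param effects A `"margin_effects"` data frame.
#' @param level Pseudo-confidence level, default 0.95.
#' @return A list: `points` (`theta`, `se`), `center` (the fixed-effect
#'   pooled effect), and `bounds` (`se`, `lower`, `upper`).
#' @export
funnel_points <- function(effects, level = 0.95) {
  effects <- as.data.frame(effects)
  se <- sqrt(effects$v)
  w <- 1 / effects$v
  center <- sum(w * effects$theta) / sum(w)
  zcrit <- qnorm(1 - (1 - level) / 2)
  grid <- sort(unique(c(se, seq(0, max(se), length.out = 50))))
  list(points = data.frame(theta = effects$theta, se = se),
       center = center,
       bounds = data.frame(se = grid, lower = center - zcrit * grid,
                           upper = center + zcrit * grid))
}

# Classical Egger precision regression on one margin:
# theta_i / sqrt(v_i) = intercept + slope / sqrt(v_i); a nonzero intercept
# signals small-study asymmetry.
.egger_margin <- function(effects) {
  k <- nrow(effects)
  if (k < 3) stop("Egger regression requires at least 3 studies")
  z <- effects$theta / sqrt(effects$v)
  x <- 1 / sqrt(effects$v)
  fit <- lm(z ~ x)
  est <- summary(fit)$coefficients
  data.frame(intercept = est[1, 1], se = est[1, 2],
             t = est[1, 1] / est[1, 2],
             df = k - 2,
             p = 2 * pt(abs(est[1, 1] / est[1, 2]), k - 2,
                        lower.tail = FALSE),
             slope = est[2, 1])
}

#' Egger-type asymmetry test for a bivariate DTA structure
#'
#' Runs the classical Egger precision regression separately on the logit
#' sensitivity and logit specificity margins, then combines them: the two
#' margins are stacked into one regression with margin-specific intercepts
#' and slopes, the joint covariance of the two intercepts is estimated with
#' a study-clustered CR1 sandwich estimator (the same study contributes
#' both margins), and asymmetry is assessed by a 2-degree-of-freedom Wald
#' statistic on the intercept pair referred to an F(2, k - 2) distribution
#' (the asymptotic chi-square reference is visibly liberal at typical
#' meta-analytic cluster counts).
#'
#' Size caveat: the precision regression assumes homogeneous true effects;
#' between-study heterogeneity, and small strata on a logit margin (where
#' the estimated variance shares counts with the effect), both push the
#' test toward over-rejection. This is intrinsic to Egger-type statistics
#' on proportion margins.
#'
#' @param tables `data.frame` of `tp`, `fp`, `tn`, `fn` (k >= 3).
#' @return A list of class `"egger_result"`: `per_margin` (a `data.frame`
#'   with intercept, SE, t, df, p for each margin), `combined` (`chisq`,
#'   `df`, `p`).
#' @export
egger_test <- function(tables) {
  tables <- as.data.frame(tables)
  se_eff <- logit_effects(tables, "sensitivity")
  sp_eff <- logit_effects(tables, "specificity")
  per <- rbind(cbind(margin = "sensitivity", .egger_margin(se_eff)),
               cbind(margin = "specificity", .egger_margin(sp_eff)))

  k <- nrow(tables)
  stacked <- data.frame(
    z = c(se_eff$theta / sqrt(se_eff$v), sp_eff$theta / sqrt(sp_eff$v)),
    x = c(1 / sqrt(se_eff$v), 1 / sqrt(sp_eff$v)),
    margin = factor(rep(c("se", "sp"), each = k)),
    study = rep(seq_len(k), 2))
  fit <- lm(z ~ 0 + margin + margin:x, data = stacked)
  # CR1 cluster correction with an F(2, k - 2) reference: the chi-square
  # reference is visibly liberal at meta-analytic cluster counts
  V <- sandwich::vcovCL(fit, cluster = stacked$study, type = "HC1")
  b <- coef(fit)[c("marginse", "marginsp")]
  Vi <- V[c("marginse", "marginsp"), c("marginse", "marginsp")]
  W <- drop(t(b) %*% solve(Vi) %*% b)
  structure(list(per_margin = per,
                 combined = list(chisq = W, df = 2,
                                 p = pf(W / 2, 2, k - 2,
                                        lower.tail = FALSE))),
            class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  print(x$per_margin, digits = 3)
  cat(sprintf("combined 2-df Wald chi-square = %.2f, p = %.3g\n",
              x$combined$chisq, x$combined$p))
  invisible(x)
}
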