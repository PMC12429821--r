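#' Reconstruct an integer 2x2 table from printed summary percentages
#'
#' Published DTA tables often print only the total sample size and the
#' sensitivity/specificity/accuracy percentages; the underlying TP/FP/TN/FN
#' counts must be recovered before any binomial-likelihood model can be fit.
#' This routine minimizes, over all integer tables — the unprinted number
#' of diseased patients `D = tp + fn` in `1, ..., n - 1` and counts
#' `tp` in `[0, D]`, `tn` in `[0, n - D]` — the squared percentage-point
#' mismatch
#' `E = (100 tp/D - sen)^2 + (100 tn/(n-D) - spe)^2 + (100 (tp+tn)/n - acc)^2`.
#' The global minimizer is returned; exact ties on `E` are broken by the
#' most balanced design (smallest `|2D - n|`), then by the smaller `D`,
#' then the smaller `tn` and `tp`. For each `D` the candidate counts are
#' `round(sen_pct * D / 100)` / `round(spe_pct * (n - D) / 100)` (halves
#' away from zero) and the integer neighborhood of the continuous optimum
#' of `E` — the two coincide except on rows where the accuracy term pulls
#' the optimum away from the margin-wise roundings; the search is exact
#' because the objective's Hessian in `(tp, tn)` is diagonally dominant
#' (`1/D^2` and `1/(n-D)^2` both exceed the coupling `1/n^2`), which
#' confines the integer optimum to the unit box around the continuous one.
#' Agreement with full enumeration of all `(D, tp, tn)` is asserted in the
#' test suite for every packaged row small enough to enumerate.
#'
#' If the printed accuracy is missing, the accuracy term is dropped from
#' `E`. A minimal residual above `residual_warn` marks the row as
#' inconsistent (the printed percentages cannot be produced by any integer
#' table under this rounding); the row is flagged, never silently altered.
#'
#' @param n Total sample size (>= 2).
#' @param sen_pct,spe_pct Printed sensitivity/specificity, percent.
#' @param acc_pct Printed accuracy, percent, or `NA`.
#' @param residual_warn Residual threshold (squared percentage points) above
#'   which the reconstruction is flagged. Default 25.
#' @return A one-row `data.frame` with `tp`, `fp`, `tn`, `fn`, `d`
#'   (diseased-stratum size), `residual`, `flagged`, and the implied
#'   `sen_hat`, `spe_hat`, `acc_hat` percentages.
#' @examples
#' reconstruct_counts(100, 50, 50, 50)    # tp=fp=tn=fn=25
#' reconstruct_counts(94, 78.6, 98.7, 88.6)
#' @export
reconstruct_counts <- function(n, sen_pct, spe_pct, acc_pct = NA,
                               residual_warn = 25) {
  if (is.na(n) || n < 2) stop("n must be >= 2")
  stopifnot(sen_pct >= 0, sen_pct <= 100, spe_pct >= 0, spe_pct <= 100)
  Ds <- seq_len(n - 1)
  best_tp <- best_tn <- integer(n - 1)
  E <- numeric(n - 1)
  for (i in Ds) {
    D <- i; nd <- n - D
    a <- (100 / D)^2; b <- (100 / nd)^2
    tpc <- sen_pct * D / 100
    tnc <- spe_pct * nd / 100
    if (is.na(acc_pct)) {
      cand_tp <- min(max(round_half_away(tpc), 0), D)
      cand_tn <- min(max(round_half_away(tnc), 0), nd)
    } else {
      # continuous optimum of the coupled quadratic, then its integer
      # neighborhood plus the margin-wise roundings
      cc <- (100 / n)^2
      sc <- acc_pct * n / 100
      s <- (tpc + tnc + cc * sc * (1 / a + 1 / b)) /
        (1 + cc * (1 / a + 1 / b))
      g <- cc * (s - sc)
      tp0 <- tpc - g / a
      tn0 <- tnc - g / b
      cand_tp <- unique(pmin(pmax(c(floor(tp0), ceiling(tp0),
                                    round_half_away(tpc)), 0), D))
      cand_tn <- unique(pmin(pmax(c(floor(tn0), ceiling(tn0),
                                    round_half_away(tnc)), 0), nd))
    }
    grid <- expand.grid(tp = cand_tp, tn = cand_tn)
    e <- (100 * grid$tp / D - sen_pct)^2 + (100 * grid$tn / nd - spe_pct)^2
    if (!is.na(acc_pct))
      e <- e + (100 * (grid$tp + grid$tn) / n - acc_pct)^2
    j <- order(e, grid$tn, grid$tp)[1]
    best_tp[i] <- grid$tp[j]
    best_tn[i] <- grid$tn[j]
    E[i] <- e[j]
  }
  # order by residual, then balance |2D - n|, then smaller D
  best <- order(E, abs(2 * Ds - n), Ds)[1]
  res <- E[best]
  nd_best <- n - Ds[best]
  out <- data.frame(
    tp = best_tp[best], fp = nd_best - best_tn[best],
    tn = best_tn[best], fn = Ds[best] - best_tp[best],
    d = Ds[best], residual = res, flagged = res > residual_warn)
  out$sen_hat <- 100 * out$tp / out$d
  out$spe_hat <- 100 * out$tn / (n - out$d)
  out$acc_hat <- 100 * (out$tp + out$tn) / n
  out
}

#' Reconstruct 2x2 tables for every row of a study table
#'
#' Applies [reconstruct_counts()] row-wise and binds the results to the
#' study identifiers. Rows whose minimal residual exceeds `residual_warn`
#' are flagged (column `flagged`) and reported via a single warning.
#'
#' @param records A `dta_studies` table (see [read_study_table()]) or any
#'   `data.frame` with columns `study_id`, `n`, `sen_pct`, `spe_pct`,
#'   `acc_pct`.
#' @param residual_warn Passed to [reconstruct_counts()].
#' @return A `data.frame` with `study_id`, the counts, `d`, `residual`,
#'   `flagged` and implied metrics; one row per input row.
#' @export
reconstruct_studies <- function(records, residual_warn = 25) {
  records <- as.data.frame(records)
  out <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    reconstruct_counts(r$n, r$sen_pct, r$spe_pct, r$acc_pct, residual_warn)
  }))
  out <- cbind(study_id = records$study_id, out)
  rownames(out) <- NULL
  if (any(out$flagged))
    warning(sprintf("%d row(s) reconstructed with residual > %g: %s",
                    sum(out$flagged), residual_warn,
                    paste(out$study_id[out$flagged], collapse = ", ")))
  out
}
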