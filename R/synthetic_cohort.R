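#' Specify a synthetic meta-analytic cohort
#'
#' Defines the generative model that the bivariate binomial-normal fit
#' assumes: per-study latent `(logit Se_i, logit Sp_i)` drawn from a
#' bivariate normal with means `(mu_se, mu_sp)`, standard deviations
#' `(sigma_se, sigma_sp)` and correlation `rho`; within-study counts then
#' binomial given the stratum sizes.
#'
#' @param k Number of studies (>= 1).
#' @param sizes Per-study total sample size; recycled to length `k`. All
#'   sizes must be >= 2.
#' @param prevalences Per-study diseased fraction, strictly inside (0, 1);
#'   recycled to length `k`. Default 0.5 (the model conditions on stratum
#'   sizes; prevalence is a pure simulation knob).
#' @param params A [bivariate_params()] object. `rho` may be +/-1 here (a
#'   degenerate but well-defined generative model), unlike in the fitted
#'   model where |rho| < 1.
#' @param seed Integer seed; each study gets its own derived substream so
#'   changing `k` never reshuffles earlier studies.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(k, sizes = 100, prevalences = 0.5,
                        params = bivariate_params(), seed = 1) {
  stopifnot(k >= 1)
  sizes <- rep_len(sizes, k)
  prevalences <- rep_len(prevalences, k)
  if (any(sizes < 2)) stop("all study sizes must be >= 2")
  if (any(prevalences <= 0 | prevalences >= 1))
    stop("prevalences must be strictly inside (0, 1)")
  stopifnot(inherits(params, "bivariate_params"))
  if (abs(params$rho) > 1) stop("|rho| must be <= 1")
  structure(list(k = k, sizes = sizes, prevalences = prevalences,
                 params = params, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Per-study substream seed: a fixed odd multiplier keeps streams distinct
# and stable in the study index.
.study_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * i) %% .Machine$integer.max)
}

#' Forward-simulate study-level 2x2 tables from the bivariate model
#'
#' For study `i`, draws `(logit Se_i, logit Sp_i)` from the bivariate normal
#' of the [cohort_spec()], sets the diseased-stratum size to the nearest
#' integer to `prevalence_i * n_i` (clamped to `[1, n_i - 1]`), and draws
#' `tp_i ~ Binomial(n_Di, Se_i)`, `tn_i ~ Binomial(n_i - n_Di, Sp_i)`.
#' Identical specs (including seed) give identical output.
#'
#' @param spec A [cohort_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{records}{A study table in the same schema as the packaged
#'       fixture, with metrics computed from the realized counts.}
#'     \item{tables}{`data.frame` of `study_id`, `tp`, `fp`, `tn`, `fn`.}
#'     \item{truth}{Per-study latent `se`, `sp` (probability scale), their
#'       logits, plus the generating parameters as an attribute.}
#'   }
#' @export
simulate_studies <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  p <- spec$params
  k <- spec$k
  tp <- tn <- nD <- integer(k)
  lse <- lsp <- numeric(k)
  for (i in seq_len(k)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(.study_seed(spec$seed, i))
    z <- rnorm(2)
    lse[i] <- p$mu_se + p$sigma_se * z[1]
    lsp[i] <- p$mu_sp + p$sigma_sp *
      (p$rho * z[1] + sqrt(max(0, 1 - p$rho^2)) * z[2])
    nD[i] <- min(max(round_half_away(spec$prevalences[i] * spec$sizes[i]), 1),
                 spec$sizes[i] - 1)
    tp[i] <- rbinom(1, nD[i], inv_logit(lse[i]))
    tn[i] <- rbinom(1, spec$sizes[i] - nD[i], inv_logit(lsp[i]))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  id <- sprintf("sim_%03d", seq_len(k))
  tables <- data.frame(study_id = id, tp = tp, fp = spec$sizes - nD - tn,
                       tn = tn, fn = nD - tp)
  m <- derive_metrics(tables)
  records <- data.frame(
    study_id = id, year = NA_integer_, country = "synthetic",
    design = "prospective", centers = "monocentric",
    modality = "SE", technique = "none",
    n = spec$sizes, pct_female = NA_real_, mean_age = NA_real_,
    cad_status = "mixed", stenosis_cutoff = NA_real_,
    sen_pct = round(100 * m$sensitivity, 1),
    spe_pct = round(100 * m$specificity, 1),
    acc_pct = round(100 * m$accuracy, 1))
  truth <- data.frame(study_id = id, logit_se = lse, logit_sp = lsp,
                      se = inv_logit(lse), sp = inv_logit(lsp), n_diseased = nD)
  attr(truth, "params") <- p
  list(records = records, tables = tables, truth = truth)
}
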