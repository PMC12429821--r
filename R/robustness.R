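#' Simple descriptive pooling of printed study percentages
#'
#' Reproduces the descriptive "Overall" row of a study-level table: the sum
#' of sample sizes and plain arithmetic means of the printed sensitivity,
#' specificity and accuracy percentages, rounded to one decimal. Percent
#' female is pooled as an n-weighted mean over non-missing rows and mean
#' age as an unweighted mean over non-missing rows; both are approximate
#' (they ignore the rows' internal missingness structure) and are flagged
#' as such in the output.
#'
#' Two pooling conventions are offered because both circulate in summary
#' tables: `"unweighted"` (plain means of the printed percentages; the
#' convention that reproduces this package's fixture) and `"size"`
#' (sample-size-weighted means).
#'
#' @param records A study table (rows of one subgroup).
#' @param weights `"unweighted"` (default) or `"size"`.
#' @return A one-row `data.frame`: `k`, `n_total`, `pct_female`,
#'   `mean_age`, `sen_pct`, `spe_pct`, `acc_pct`, `weights`,
#'   `demo_approximate`.
#' @export
simple_pool <- function(records, weights = c("unweighted", "size")) {
  weights <- match.arg(weights)
  records <- as.data.frame(records)
  stopifnot(nrow(records) >= 1)
  w <- if (weights == "size") records$n else rep(1, nrow(records))
  pool <- function(x) {
    ok <- !is.na(x)
    round(weighted.mean(x[ok], w[ok]), 1)
  }
  fem_ok <- !is.na(records$pct_female)
  data.frame(
    k = nrow(records),
    n_total = sum(records$n),
    pct_female = if (any(fem_ok))
      round(weighted.mean(records$pct_female[fem_ok], records$n[fem_ok]), 1)
      else NA_real_,
    mean_age = if (any(!is.na(records$mean_age)))
      round(mean(records$mean_age, na.rm = TRUE), 1) else NA_real_,
    sen_pct = pool(records$sen_pct),
    spe_pct = pool(records$spe_pct),
    acc_pct = pool(records$acc_pct),
    weights = weights,
    demo_approximate = TRUE)
}

#' Leave-one-out influence analysis
#'
#' Refits the bivariate model k times, omitting one study per refit, and
#' reports the pooled sensitivity/specificity posterior summaries per
#' exclusion together with their min/max envelope and the full-data fit.
#' Refit `i` uses seed `seed + i` so every exclusion is reproducible.
#'
#' @param tables `data.frame` of `tp`, `fp`, `tn`, `fn` (k >= 3).
#' @param prior,chains,iter,seed Passed to [fit_bivariate()].
#' @return A list of class `"loo_report"`: `per_exclusion` (one row per
#'   omitted study), `envelope` (min/max of pooled estimates), `full`
#'   (full-data summary row).
#' @export
loo_analysis <- function(tables, prior = prior_spec(), chains = 2,
                         iter = 2000, seed = 1) {
  tables <- as.data.frame(tables)
  k <- nrow(tables)
  if (k < 3) stop("leave-one-out requires at least 3 studies")
  full <- fit_bivariate(tables, prior = prior, chains = chains, iter = iter,
                        seed = seed)
  row_of <- function(fit) {
    s <- fit$summary
    data.frame(
      se_median = s$median[s$quantity == "se_pooled"],
      se_lower = s$lower[s$quantity == "se_pooled"],
      se_upper = s$upper[s$quantity == "se_pooled"],
      sp_median = s$median[s$quantity == "sp_pooled"],
      sp_lower = s$lower[s$quantity == "sp_pooled"],
      sp_upper = s$upper[s$quantity == "sp_pooled"])
  }
  per <- do.call(rbind, lapply(seq_len(k), function(i) {
    fit <- fit_bivariate(tables[-i, ], prior = prior, chains = chains,
                         iter = iter, seed = seed + i)
    cbind(excluded = if (!is.null(tables$study_id)) tables$study_id[i] else i,
          row_of(fit))
  }))
  rownames(per) <- NULL
  structure(list(
    per_exclusion = per,
    envelope = data.frame(
      quantity = c("se_pooled", "sp_pooled"),
      min = c(min(per$se_median), min(per$sp_median)),
      max = c(max(per$se_median), max(per$sp_median))),
    full = row_of(full)),
    class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  cat(sprintf("Leave-one-out over %d exclusions\n", nrow(x$per_exclusion)))
  print(x$envelope, digits = 3)
  invisible(x)
}

# Country -> region map for the subgroup scheme. Transcontinental Turkey is
# grouped with Europe, following common practice in cardiology cohorts.
.region_map <- c(
  USA = "North America", Canada = "North America",
  Argentina = "South America", Chile = "South America",
  China = "Asia", Taiwan = "Asia", Japan = "Asia", Iran = "Asia",
  Netherlands = "Europe", Spain = "Europe", Turkey = "Europe",
  Italy = "Europe", Ireland = "Europe", Germany = "Europe",
  Serbia = "Europe", Greece = "Europe", Switzerland = "Europe",
  Norway = "Europe", Belgium = "Europe", Poland = "Europe",
  UK = "Europe", France = "Europe", Portugal = "Europe")

#' Map a study record set to subgroup labels
#'
#' Supported schemes: `"modality"`; `"technique"` (stressor within
#' modality, labelled `modality:technique`); `"sex_subgroup"` (female-only
#' vs mixed; meaningful for the exercise-ECG subset); `"region"` (a
#' documented country-to-continent map); `"period"` (publication year
#' <= 2004 vs >= 2005); `"design"` (prospective vs retrospective). Every
#' record maps to exactly one group.
#'
#' @param records A study table.
#' @param scheme One of the schemes above.
#' @return Character vector of group labels, one per record.
#' @export
subgroup_labels <- function(records,
                            scheme = c("modality", "technique",
                                       "sex_subgroup", "region", "period",
                                       "design")) {
  scheme <- match.arg(scheme)
  records <- as.data.frame(records)
  switch(scheme,
    modality = records$modality,
    technique = paste(records$modality, records$technique, sep = ":"),
    sex_subgroup = ifelse(!is.na(records$pct_female) &
                            records$pct_female == 100,
                          "female_only", "mixed"),
    region = {
      r <- .region_map[records$country]
      if (any(is.na(r)))
        stop("no region mapping for: ",
             paste(unique(records$country[is.na(r)]), collapse = ", "))
      unname(r)
    },
    period = ifelse(records$year <= 2004, "1990-2004", "2005-2025"),
    design = records$design)
}

#' Subgroup stratification with independent model fits
#'
#' Splits the records by a [subgroup_labels()] scheme, reconstructs counts
#' per group, fits the bivariate model independently per group with shared
#' priors and iteration budget, and reports per-group posterior summaries,
#' per-margin heterogeneity, and a ranking by pooled sensitivity and
#' specificity. Groups with a single study are fitted with the correlation
#' fixed at 0 and flagged; empty groups cannot arise (every record maps to
#' a group) but groups lost to filtering are skipped with a message.
#'
#' @param records A study table.
#' @param scheme Grouping scheme, see [subgroup_labels()].
#' @param prior,chains,iter,seed Passed to [fit_bivariate()]; the same
#'   configuration is used for every group.
#' @return A list of class `"subgroup_report"`: `groups` (named list with
#'   per-group `fit`, `heterogeneity`, `k`, `rho_fixed` flag), `ranking`
#'   (groups ordered by pooled sensitivity, with specificity alongside),
#'   `config`.
#' @export
subgroup_analysis <- function(records, scheme = "modality",
                              prior = prior_spec(), chains = 4,
                              iter = 10000, seed = 1) {
  records <- as.data.frame(records)
  labels <- subgroup_labels(records, scheme)
  groups <- list()
  for (g in unique(labels)) {
    rows <- records[labels == g, , drop = FALSE]
    if (nrow(rows) == 0) {
      message("subgroup ", g, " empty; skipped")
      next
    }
    tabs <- suppressWarnings(reconstruct_studies(rows))
    single <- nrow(tabs) < 2
    fit <- fit_bivariate(tabs, prior = prior, chains = chains, iter = iter,
                         seed = seed,
                         rho_fixed = if (single) 0 else NULL)
    het <- if (nrow(tabs) >= 2)
      list(sensitivity = q_and_i2(logit_effects(tabs, "sensitivity")),
           specificity = q_and_i2(logit_effects(tabs, "specificity")))
      else NULL
    groups[[g]] <- list(fit = fit, heterogeneity = het, k = nrow(tabs),
                        rho_fixed = single)
  }
  rank_tab <- do.call(rbind, lapply(names(groups), function(g) {
    s <- groups[[g]]$fit$summary
    data.frame(group = g, k = groups[[g]]$k,
               se_pooled = s$median[s$quantity == "se_pooled"],
               sp_pooled = s$median[s$quantity == "sp_pooled"])
  }))
  rank_tab <- rank_tab[order(-rank_tab$se_pooled), ]
  rownames(rank_tab) <- NULL
  structure(list(groups = groups, ranking = rank_tab,
                 config = list(scheme = scheme, prior = prior,
                               chains = chains, iter = iter, seed = seed)),
            class = "subgroup_report")
}

#' @export
print.subgroup_report <- function(x, ...) {
  cat(sprintf("Subgroup analysis by %s (%d groups)\n",
              x$config$scheme, length(x$groups)))
  print(x$ranking, digits = 3)
  invisible(x)
}
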