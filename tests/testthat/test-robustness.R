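test_that("simple pooling reproduces known subgroup summary cells", {
  d <- read_study_table()
  ex_cmr <- d[d$modality == "CMR" & d$technique == "exercise", ]
  expect_equal(simple_pool(ex_cmr)$sen_pct, 70.2)
  dip_cmr <- d[d$modality == "CMR" & d$technique == "dipyridamole", ]
  expect_equal(simple_pool(dip_cmr)$spe_pct, 90.5)

  # identity on a single record
  one <- simple_pool(d[1, ])
  expect_equal(unlist(one[c("sen_pct", "spe_pct", "acc_pct")],
                      use.names = FALSE),
               unlist(d[1, c("sen_pct", "spe_pct", "acc_pct")],
                      use.names = FALSE))
  expect_equal(one$n_total, d$n[1])

  # permutation invariance
  set.seed(1)
  est <- d[d$modality == "EST", ]
  expect_equal(simple_pool(est[sample(nrow(est)), ]), simple_pool(est))

  # the size-weighted variant differs and is labelled
  w <- simple_pool(est, weights = "size")
  expect_equal(w$weights, "size")
  expect_false(w$sen_pct == simple_pool(est)$sen_pct)
})

test_that("subgroup labels partition the fixture as documented", {
  d <- read_study_table()
  for (scheme in c("modality", "technique", "sex_subgroup", "region",
                   "period", "design")) {
    lab <- subgroup_labels(d, scheme)
    expect_equal(length(lab), nrow(d))
    expect_false(any(is.na(lab)))
  }
  est <- d[d$modality == "EST", ]
  expect_equal(sum(subgroup_labels(est, "sex_subgroup") == "female_only"), 7)
  expect_setequal(unique(subgroup_labels(d, "period")),
                  c("1990-2004", "2005-2025"))
  expect_equal(subgroup_labels(d, "period") == "1990-2004", d$year <= 2004)
})

test_that("exchangeable studies give a flat leave-one-out profile", {
  tab <- data.frame(tp = rep(40, 6), fn = rep(10, 6),
                    tn = rep(35, 6), fp = rep(15, 6))
  loo <- loo_analysis(tab, chains = 2, iter = 1500, seed = 2)
  expect_lt(diff(range(loo$per_exclusion$se_median)), 0.01)
  expect_lt(diff(range(loo$per_exclusion$sp_median)), 0.01)
  # envelope property relative to the full fit
  expect_gte(loo$full$se_median, loo$envelope$min[1] - 0.01)
  expect_lte(loo$full$se_median, loo$envelope$max[1] + 0.01)
  expect_error(loo_analysis(tab[1:2, ]), "at least 3")
})

test_that("removing a planted outlier moves the pooled estimate most", {
  sim <- simulate_studies(cohort_spec(10, sizes = 100,
    params = bivariate_params(1.4, 1.0, 0.15, 0.15, 0), seed = 6))
  tabs <- sim$tables
  # one grossly discordant study among ten near-homogeneous ones
  tabs[10, ] <- data.frame(study_id = "outlier", tp = 15, fp = 35,
                           tn = 15, fn = 35)
  loo <- suppressWarnings(
    loo_analysis(tabs, chains = 2, iter = 3000, seed = 4))
  shift <- abs(loo$per_exclusion$se_median - loo$full$se_median)
  expect_equal(which.max(shift), 10)
})

test_that("a single-group scheme reproduces the ungrouped fit exactly", {
  sim <- simulate_studies(cohort_spec(8, sizes = 90,
    params = bivariate_params(1.2, 0.8, 0.3, 0.3, -0.4), seed = 14))
  rec <- sim$records
  rec$modality <- "SE" # one group only
  sub <- subgroup_analysis(rec, "modality", chains = 2, iter = 1500,
                           seed = 9)
  direct <- fit_bivariate(suppressWarnings(reconstruct_studies(rec)),
                          chains = 2, iter = 1500, seed = 9)
  expect_equal(sub$groups[["SE"]]$fit$summary, direct$summary)
  # shared configuration is recorded for every group
  expect_equal(sub$config$iter, 1500)
})

test_that("single-study groups fall back to a fixed correlation", {
  sim <- simulate_studies(cohort_spec(4, sizes = 80,
    params = bivariate_params(1, 1, 0.3, 0.3, 0), seed = 3))
  rec <- sim$records
  rec$modality <- c("SE", "SE", "SE", "CMR")
  sub <- subgroup_analysis(rec, "modality", chains = 2, iter = 800, seed = 2)
  expect_true(sub$groups[["CMR"]]$rho_fixed)
  expect_equal(unique(sub$groups[["CMR"]]$fit$draws$rho), 0)
  expect_false(sub$groups[["SE"]]$rho_fixed)
})
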