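test_that("margin effects follow the delta-method formulas", {
  e <- logit_effects(data.frame(tp = 10, fn = 10, tn = 7, fp = 3),
                     "sensitivity")
  expect_equal(e$theta, 0)
  expect_equal(e$v, 0.2)

  d <- logit_effects(data.frame(tp = 20, fp = 5, tn = 20, fn = 5), "lnDOR")
  expect_equal(d$theta, log(16))
  expect_equal(d$v, 1 / 20 + 1 / 5 + 1 / 20 + 1 / 5)

  # zero anywhere corrects all four cells, for every margin
  z <- logit_effects(data.frame(tp = 10, fp = 0, tn = 10, fn = 10),
                     "sensitivity")
  expect_equal(z$theta, log(10.5 / 10.5))
  expect_equal(z$v, 1 / 10.5 + 1 / 10.5)
  z2 <- logit_effects(data.frame(tp = 10, fp = 0, tn = 10, fn = 10),
                      "specificity")
  expect_equal(z2$theta, log(10.5 / 0.5))
  expect_true(is.finite(z2$v))
})

test_that("Q and I2 match hand calculations and metafor", {
  eff <- data.frame(theta = c(0, 2), v = c(1, 1))
  h <- q_and_i2(eff)
  expect_equal(h$Q, 2)
  expect_equal(h$df, 1)
  expect_equal(h$i2_pct, 50)
  expect_equal(h$theta_pooled, 1)

  h2 <- q_and_i2(data.frame(theta = c(0, 1), v = c(1, 1)))
  expect_equal(h2$Q, 0.5)
  expect_equal(h2$i2_pct, 0) # negative (Q - df)/Q truncated

  expect_equal(q_and_i2(data.frame(theta = c(1, 1, 1),
                                   v = c(1, 2, 3)))$Q, 0)
  expect_error(q_and_i2(data.frame(theta = 1, v = 1)), "at least 2")

  skip_if_not_installed("metafor")
  set.seed(2)
  eff <- data.frame(theta = rnorm(12, 1, 0.6), v = runif(12, 0.05, 0.4))
  h <- q_and_i2(eff)
  m <- metafor::rma(yi = eff$theta, vi = eff$v, method = "FE")
  expect_equal(h$Q, as.numeric(m$QE), tolerance = 1e-8)
  expect_equal(h$p, as.numeric(m$QEp), tolerance = 1e-8)
})

test_that("I2 is invariant to joint rescaling of variances and deviations", {
  set.seed(7)
  eff <- data.frame(theta = rnorm(10, 0.5, 0.8), v = runif(10, 0.1, 0.5))
  h <- q_and_i2(eff)
  c2 <- 3.7
  tb <- h$theta_pooled
  scaled <- data.frame(theta = tb + (eff$theta - tb) * sqrt(c2),
                       v = eff$v * c2)
  expect_equal(q_and_i2(scaled)$i2_pct, h$i2_pct, tolerance = 1e-10)
})

test_that("funnel coordinates carry center and pseudo-confidence bounds", {
  eff <- data.frame(theta = c(0.8, 1.2, 1.0), v = c(0.25, 0.25, 0.25))
  f <- funnel_points(eff)
  expect_equal(f$center, 1)
  b <- f$bounds[abs(f$bounds$se - 0.5) < 1e-9, ]
  expect_equal(c(b$lower, b$upper), c(1 - 1.96 * 0.5, 1 + 1.96 * 0.5),
               tolerance = 1e-3)
  # equal variances: bounds at the observed se are the same for all studies
  expect_equal(nrow(unique(f$points["se"])), 1)
  # a (near) zero-variance study sits at the funnel apex
  apex <- funnel_points(data.frame(theta = c(1, 1.5), v = c(1e-8, 0.2)))
  expect_lt(apex$points$se[1], 1e-3)
})

test_that("Egger intercept matches the closed-form OLS oracle", {
  eff <- data.frame(theta = c(0.2, 0.9, 1.7), v = c(0.5, 0.2, 0.05))
  res <- egger_test(data.frame(tp = c(10, 20, 40), fn = c(5, 8, 10),
                               tn = c(12, 25, 45), fp = c(6, 7, 9)))
  for (mg in c("sensitivity", "specificity")) {
    e <- logit_effects(data.frame(tp = c(10, 20, 40), fn = c(5, 8, 10),
                                  tn = c(12, 25, 45), fp = c(6, 7, 9)), mg)
    o <- ols_intercept(1 / sqrt(e$v), e$theta / sqrt(e$v))
    row <- res$per_margin[res$per_margin$margin == mg, ]
    expect_equal(row$intercept, unname(o["intercept"]), tolerance = 1e-9)
    expect_equal(row$se, unname(o["se"]), tolerance = 1e-9)
    expect_equal(row$df, 1)
  }
})

test_that("noiseless proportional effects give exactly zero intercepts", {
  # theta_i = c for all i: z = c * x passes through the origin
  v <- c(0.5, 0.2, 0.1, 0.05)
  tabs <- data.frame(tp = c(8, 20, 40, 80), fn = c(4, 10, 20, 40),
                     tn = c(8, 20, 40, 80), fp = c(4, 10, 20, 40))
  res <- egger_test(tabs)
  expect_lt(max(abs(res$per_margin$intercept)), 1e-10)
  expect_error(egger_test(tabs[1:2, ]), "at least 3")
})

test_that("adding a constant to effects moves the slope, not the intercept", {
  set.seed(5)
  eff <- data.frame(theta = rnorm(8, 1, 0.4), v = runif(8, 0.05, 0.3))
  o1 <- ols_intercept(1 / sqrt(eff$v), eff$theta / sqrt(eff$v))
  shift <- eff
  shift$theta <- shift$theta + 2
  o2 <- ols_intercept(1 / sqrt(shift$v), shift$theta / sqrt(shift$v))
  expect_equal(unname(o1["intercept"]), unname(o2["intercept"]),
               tolerance = 1e-9)
  expect_equal(unname(o2["slope"] - o1["slope"]), 2, tolerance = 1e-9)
})

test_that("combined Egger test keeps nominal size under the symmetric null", {
  # the null of the precision regression: homogeneous effects, no
  # selection; large strata so the effect/variance count-coupling of the
  # logit margins is negligible (the documented small-stratum inflation is
  # a property of the statistic, not a defect of the implementation)
  set.seed(31)
  reps <- 1000
  hits <- 0
  for (r in seq_len(reps)) {
    sim <- simulate_studies(cohort_spec(40,
      sizes = sample(c(1000, 2000, 4000, 8000), 40, replace = TRUE),
      params = bivariate_params(1, 0.8, 0, 0, 0), seed = 40000 + r))
    hits <- hits + (egger_test(sim$tables)$combined$p < 0.05)
  }
  expect_gt(hits / reps, 0.02)
  expect_lt(hits / reps, 0.09)
})

test_that("combined Egger test detects size-dependent selection", {
  # small studies enter only when their sensitivity effect beats the grand
  # mean: a textbook small-study publication-bias mechanism
  set.seed(77)
  reps <- 200
  hits <- 0
  for (r in seq_len(reps)) {
    sz <- sample(c(30, 40, 60, 100, 200), 120, replace = TRUE)
    sim <- simulate_studies(cohort_spec(120, sizes = sz,
      params = bivariate_params(1, 0.8, 0.5, 0.5, -0.3), seed = 90000 + r))
    th <- logit_effects(sim$tables, "sensitivity")$theta
    keep <- which(sz >= 50 | th > 1)[1:40]
    hits <- hits + (egger_test(sim$tables[keep, ])$combined$p < 0.05)
  }
  expect_gte(hits / reps, 0.8)
})
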