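test_that("PC prior has the stated rate and tail mass", {
  lambda <- -log(0.05) / 3
  expect_equal(pc_prior_logdensity(1e-12), log(lambda), tolerance = 1e-6)
  expect_equal(pc_prior_logdensity(-1), -Inf)
  expect_equal(pc_prior_logdensity(0), -Inf)
  # defining property P(sigma > u) = alpha, by numerical integration
  tail <- integrate(function(s) exp(pc_prior_logdensity(s)), 3, Inf)$value
  expect_equal(tail, 0.05, tolerance = 1e-6)
  total <- integrate(function(s) exp(pc_prior_logdensity(s)), 0, Inf)$value
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("log joint matches its symmetric closed form and is monotone in |phi|", {
  tab <- data.frame(tp = 5, fn = 5, tn = 5, fp = 5)
  pr <- prior_spec()
  p <- bivariate_params(0, 0, 1, 1, 0)
  eff <- matrix(0, 1, 2)
  lj <- log_joint(p, eff, tab, pr)
  binom_part <- 2 * (lchoose(10, 5) + 10 * log(0.5))
  # subtracting the analytic binomial part leaves priors + random-effect
  # density at the origin
  rest <- lj - binom_part
  expect_equal(rest,
               -log(2 * pi) +
                 2 * dnorm(0, 0, 10, log = TRUE) +
                 2 * pc_prior_logdensity(1) +
                 dnorm(0, 0, 5, log = TRUE))

  # Gaussian monotonicity: growing |phi_se| with all else fixed decreases
  # the random-effect term (compare against a likelihood-free state)
  vals <- vapply(c(0.5, 1, 2, 4), function(h)
    log_joint(p, matrix(c(h, 0), 1, 2), tab, pr) -
      sum(dbinom(5, 10, plogis(c(h, 0)), log = TRUE)),
    numeric(1))
  expect_true(all(diff(vals) < 0))

  # out-of-support states
  expect_equal(log_joint(bivariate_params(0, 0, 0, 1, 0), eff, tab, pr),
               -Inf)
})

test_that("log joint agrees term-by-term with a naive reimplementation", {
  tabs <- data.frame(tp = c(18, 30, 9), fp = c(4, 6, 2),
                     tn = c(20, 35, 12), fn = c(5, 8, 6))
  pr <- prior_spec(mu_sd = 8, pc_u = 2, pc_alpha = 0.1, z_sd = 3)
  set.seed(1)
  for (rep in 1:5) {
    p <- bivariate_params(rnorm(1), rnorm(1), runif(1, 0.1, 2),
                          runif(1, 0.1, 2), runif(1, -0.9, 0.9))
    eff <- matrix(rnorm(6, sd = 0.7), 3, 2)
    expect_equal(log_joint(p, eff, tabs, pr),
                 naive_log_joint(p, eff, tabs, pr), tolerance = 1e-10)
  }
  # differences between two states also agree (the quantity MCMC uses)
  p1 <- bivariate_params(0.4, 0.2, 0.5, 0.8, -0.3)
  p2 <- bivariate_params(0.1, -0.2, 1.1, 0.4, 0.2)
  e1 <- matrix(0.3, 3, 2); e2 <- matrix(-0.2, 3, 2)
  expect_equal(log_joint(p1, e1, tabs, pr) - log_joint(p2, e2, tabs, pr),
               naive_log_joint(p1, e1, tabs, pr) -
                 naive_log_joint(p2, e2, tabs, pr),
               tolerance = 1e-10)
})

test_that("posterior summaries have the stated shape and invariances", {
  expect_equal(unlist(summarize_posterior(data.frame(a = rep(2, 50)))[
    , c("median", "mean", "lower", "upper")], use.names = FALSE),
    rep(2, 4))
  set.seed(4)
  x <- rnorm(9999) # odd count: the median is an order statistic
  s <- summarize_posterior(data.frame(x = x))
  expect_lt(abs(s$lower - (-1.96)), 0.08)
  expect_lt(abs(s$upper - 1.96), 0.08)
  # quantiles commute with the monotone inverse-logit map
  s2 <- summarize_posterior(data.frame(p = plogis(x)))
  expect_equal(s2$median, plogis(s$median), tolerance = 1e-12)
  expect_error(summarize_posterior(data.frame()), "no draws")
})

test_that("huge balanced counts concentrate the pooled posteriors at 0.5", {
  tab <- data.frame(tp = 5000, fn = 5000, tn = 5000, fp = 5000)
  fit <- fit_bivariate(tab, chains = 2, iter = 2500, seed = 7)
  expect_lt(abs(pooled_median(fit, "se_pooled") - 0.5), 0.02)
  expect_lt(abs(pooled_median(fit, "sp_pooled") - 0.5), 0.02)
  expect_equal(unique(fit$draws$rho), 0) # fixed for a single study
})

test_that("prior-only sampling reproduces the PC tail probability", {
  fit <- fit_bivariate(data.frame(tp = 5, fn = 5, tn = 5, fp = 5),
                       chains = 2, iter = 5000, seed = 11,
                       likelihood = FALSE, rho_fixed = 0)
  expect_lt(abs(mean(fit$draws$sigma_se > 3) - 0.05), 0.02)
  expect_lt(abs(mean(fit$draws$sigma_sp > 3) - 0.05), 0.02)
})

test_that("margin relabeling swaps the posterior margins and keeps rho", {
  sim <- simulate_studies(cohort_spec(15, sizes = 120,
    params = bivariate_params(1.4, 0.6, 0.35, 0.35, -0.4), seed = 13))
  swapped <- with(sim$tables,
                  data.frame(tp = tn, fn = fp, tn = tp, fp = fn))
  f1 <- fit_bivariate(sim$tables, chains = 2, iter = 4000, seed = 2)
  f2 <- fit_bivariate(swapped, chains = 2, iter = 4000, seed = 2)
  expect_lt(abs(pooled_median(f1, "se_pooled") -
                  pooled_median(f2, "sp_pooled")), 0.02)
  expect_lt(abs(pooled_median(f1, "sp_pooled") -
                  pooled_median(f2, "se_pooled")), 0.02)
  expect_lt(abs(pooled_median(f1, "sigma_se") -
                  pooled_median(f2, "sigma_sp")), 0.1)
  expect_lt(abs(pooled_median(f1, "rho") - pooled_median(f2, "rho")), 0.25)
})

test_that("single study with shrunk heterogeneity matches the grid posterior", {
  tab <- data.frame(tp = 30, fn = 12, tn = 25, fp = 10)
  # force sigma ~ 0 through a sharp PC prior; the pooled sensitivity then
  # reduces to a single binomial proportion with a logit-normal prior
  fit <- fit_bivariate(tab, prior = prior_spec(pc_u = 0.01, pc_alpha = 0.05),
                       chains = 2, iter = 5000, seed = 3)
  expect_lt(abs(pooled_median(fit, "se_pooled") -
                  grid_binomial_median(30, 42)), 0.01)
  expect_lt(abs(pooled_median(fit, "sp_pooled") -
                  grid_binomial_median(25, 35)), 0.01)
})

test_that("empty data and bad configs are rejected", {
  expect_error(fit_bivariate(data.frame()), "no studies|undefined columns")
  tab <- data.frame(tp = 5, fn = 5, tn = 5, fp = 5)
  expect_error(fit_bivariate(tab, iter = 100, burn = 100), "iter")
})
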