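#' Bivariate logit-scale parameters
#'
#' Container for the hyperparameters of the bivariate binomial-normal
#' model: logit-scale means of sensitivity and specificity, between-study
#' SDs, and the between-study correlation.
#'
#' @param mu_se,mu_sp Logit-scale means.
#' @param sigma_se,sigma_sp Between-study SDs (> 0).
#' @param rho Correlation; |rho| < 1 for a fitted model ([cohort_spec()]
#'   additionally admits +/-1 for simulation).
#' @return An object of class `"bivariate_params"`.
#' @export
bivariate_params <- function(mu_se = 0, mu_sp = 0, sigma_se = 1,
                             sigma_sp = 1, rho = 0) {
  stopifnot(sigma_se >= 0, sigma_sp >= 0, abs(rho) <= 1)
  structure(list(mu_se = mu_se, mu_sp = mu_sp, sigma_se = sigma_se,
                 sigma_sp = sigma_sp, rho = rho),
            class = "bivariate_params")
}

# Bivariate normal log density of deviations (phi1, phi2), vectorized over
# rows; returns -Inf when the covariance is degenerate.
.lbvn <- function(phi1, phi2, s1, s2, rho) {
  if (s1 <= 0 || s2 <= 0 || abs(rho) >= 1) return(rep(-Inf, length(phi1)))
  z1 <- phi1 / s1
  z2 <- phi2 / s2
  q <- (z1^2 - 2 * rho * z1 * z2 + z2^2) / (1 - rho^2)
  -log(2 * pi) - log(s1) - log(s2) - 0.5 * log(1 - rho^2) - q / 2
}

# Binomial log likelihood per study (both margins), given the logit-scale
# linear predictors.
.llvec <- function(eta_se, eta_sp, dat) {
  dbinom(dat$x_se, dat$n_se, inv_logit(eta_se), log = TRUE) +
    dbinom(dat$x_sp, dat$n_sp, inv_logit(eta_sp), log = TRUE)
}

.model_data <- function(tables) {
  tables <- as.data.frame(tables)
  if (nrow(tables) < 1 || is.null(tables$tp)) stop("no studies supplied")
  list(x_se = tables$tp, n_se = tables$tp + tables$fn,
       x_sp = tables$tn, n_sp = tables$tn + tables$fp,
       k = nrow(tables))
}

#' Log joint density of the bivariate binomial-normal model
#'
#' Sums (i) the binomial log likelihoods `tp_i ~ Bin(tp_i + fn_i,
#' inv_logit(mu_se + phi_se_i))` and `tn_i ~ Bin(tn_i + fp_i,
#' inv_logit(mu_sp + phi_sp_i))`; (ii) the bivariate normal log density of
#' each deviation pair `(phi_se_i, phi_sp_i)`; (iii) normal log priors on
#' the means; (iv) PC log priors on both SDs; and (v) the normal log prior
#' on `z = atanh(rho)` together with the Jacobian of the z-to-rho map (so
#' the value is a density in `rho`). Out-of-support states return `-Inf`.
#'
#' @param params A [bivariate_params()] object.
#' @param effects A `k x 2` matrix of per-study logit-scale deviations
#'   (columns: sensitivity, specificity).
#' @param tables `data.frame` of `tp`, `fp`, `tn`, `fn` (one row per study).
#' @param prior A [prior_spec()].
#' @return The log joint density (scalar).
#' @export
log_joint <- function(params, effects, tables, prior = prior_spec()) {
  dat <- .model_data(tables)
  effects <- matrix(effects, ncol = 2)
  stopifnot(nrow(effects) == dat$k)
  p <- params
  if (p$sigma_se <= 0 || p$sigma_sp <= 0 || abs(p$rho) >= 1) return(-Inf)
  ll <- sum(.llvec(p$mu_se + effects[, 1], p$mu_sp + effects[, 2], dat))
  lre <- sum(.lbvn(effects[, 1], effects[, 2], p$sigma_se, p$sigma_sp, p$rho))
  lp <- dnorm(p$mu_se, 0, prior$mu_sd, log = TRUE) +
    dnorm(p$mu_sp, 0, prior$mu_sd, log = TRUE) +
    pc_prior_logdensity(p$sigma_se, prior$pc_u, prior$pc_alpha) +
    pc_prior_logdensity(p$sigma_sp, prior$pc_u, prior$pc_alpha) +
    dnorm(atanh(p$rho), 0, prior$z_sd, log = TRUE) - log(1 - p$rho^2)
  ll + lre + lp
}

# Split-chain potential scale reduction factor (rank-free, classic form).
# x: iterations x chains matrix of one quantity.
.split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(xs); nn <- nrow(xs)
  mu <- colMeans(xs)
  B <- nn * var(mu)
  W <- mean(apply(xs, 2, var))
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Effective sample size via initial positive sequence of autocorrelations,
# pooled over chains.
.ess <- function(x) {
  n <- nrow(x); m <- ncol(x)
  rho_sum <- 0
  for (j in seq_len(m)) {
    v <- x[, j] - mean(x[, j])
    if (var(v) == 0) next
    ac <- stats::acf(v, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    pos <- which(ac < 0.05)
    upto <- if (length(pos)) pos[1] - 1 else length(ac)
    rho_sum <- rho_sum + if (upto > 0) sum(ac[seq_len(upto)]) else 0
  }
  rho_bar <- rho_sum / m
  n * m / (1 + 2 * max(0, rho_bar))
}

#' Fit the Bayesian bivariate binomial-normal model by MCMC
#'
#' Adaptive random-walk Metropolis-within-Gibbs targeting the posterior
#' defined by [log_joint()]. The sampler works on the unconstrained scale
#' (log SDs, Fisher-z correlation) in four blocks per sweep: the mean pair,
#' the per-study deviation pairs (updated jointly but accepted per study,
#' which is valid because the deviations are conditionally independent
#' across studies), and the hyperparameter triple `(log sigma_se, log
#' sigma_sp, z)`. Proposal scales adapt during burn-in toward 20-50%
#' acceptance and are frozen afterwards.
#'
#' With a single study the correlation is not identified and is fixed at 0
#' (as is `rho_fixed` for any `k` on request).
#'
#' @param tables `data.frame` of `tp`, `fp`, `tn`, `fn` counts.
#' @param prior A [prior_spec()].
#' @param chains Number of chains (default 4).
#' @param iter Iterations per chain (default 10000); the first
#'   `burn` are discarded.
#' @param burn Burn-in per chain; default `iter / 2`.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param rho_fixed Optional fixed correlation (forced to 0 when `k = 1`).
#' @param likelihood If `FALSE`, sample from the prior only (used to verify
#'   prior tail properties by simulation).
#' @param rhat_max Convergence bound on the split-chain R-hat of every
#'   hyperparameter; exceeding it flags the fit and raises a warning with a
#'   diagnostics dump.
#' @return An object of class `"dta_fit"`: `draws` (retained draws of
#'   `mu_se`, `mu_sp`, `sigma_se`, `sigma_sp`, `rho`, `se_pooled`,
#'   `sp_pooled` across chains), `summary` (see [summarize_posterior()]),
#'   `diagnostics` (split R-hat, effective sample sizes, block acceptance
#'   rates), `converged`, and the call configuration.
#' @examples
#' \donttest{
#' sim <- simulate_studies(cohort_spec(10, sizes = 80,
#'   params = bivariate_params(1.2, 0.8, 0.3, 0.3, -0.4), seed = 7))
#' fit <- fit_bivariate(sim$tables, chains = 2, iter = 1500, seed = 1)
#' fit$summary
#' }
#' @export
fit_bivariate <- function(tables, prior = prior_spec(), chains = 4,
                          iter = 10000, burn = floor(iter / 2), seed = 1,
                          rho_fixed = NULL, likelihood = TRUE,
                          rhat_max = 1.05) {
  dat <- .model_data(tables)
  if (dat$k == 0) stop("no studies supplied")
  if (dat$k == 1 && is.null(rho_fixed)) rho_fixed <- 0
  stopifnot(chains >= 1, iter > burn, burn >= 1)

  keep <- iter - burn
  nq <- 5
  draws <- array(NA_real_, c(keep, chains, nq),
                 dimnames = list(NULL, NULL,
                                 c("mu_se", "mu_sp", "sigma_se", "sigma_sp",
                                   "rho")))
  acc_all <- matrix(0, chains, 5,
                    dimnames = list(NULL, c("mu", "effects", "hyper",
                                            "translation", "scale")))

  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + ch - 1L)
    res <- .run_chain(dat, prior, iter, burn, rho_fixed, likelihood)
    draws[, ch, ] <- res$draws
    acc_all[ch, ] <- res$acc
  }

  flat <- do.call(rbind, lapply(seq_len(chains), function(ch) draws[, ch, ]))
  colnames(flat) <- dimnames(draws)[[3]]
  flat <- as.data.frame(flat)
  flat$se_pooled <- inv_logit(flat$mu_se)
  flat$sp_pooled <- inv_logit(flat$mu_sp)

  hyper <- c("mu_se", "mu_sp", "sigma_se", "sigma_sp",
             if (is.null(rho_fixed)) "rho")
  rhat <- vapply(hyper, function(q) .split_rhat(draws[, , q, drop = TRUE]),
                 numeric(1))
  ess <- vapply(hyper, function(q) .ess(draws[, , q, drop = TRUE]),
                numeric(1))
  converged <- all(is.finite(rhat)) && all(rhat <= rhat_max)

  out <- structure(list(
    draws = flat,
    summary = summarize_posterior(flat),
    diagnostics = list(rhat = rhat, ess = ess,
                       acceptance = colMeans(acc_all)),
    converged = converged,
    k = dat$k,
    config = list(chains = chains, iter = iter, burn = burn, seed = seed,
                  prior = prior, rho_fixed = rho_fixed,
                  likelihood = likelihood)),
    class = "dta_fit")
  if (!converged) {
    warning(sprintf(
      "MCMC not converged (max split R-hat = %.3f > %.2f); diagnostics: %s",
      max(rhat), rhat_max,
      paste(sprintf("%s=%.3f", names(rhat), rhat), collapse = ", ")))
  }
  out
}

# One chain of the adaptive Metropolis-within-Gibbs sampler. Assumes the
# RNG has been seeded by the caller.
.run_chain <- function(dat, prior, iter, burn, rho_fixed, likelihood) {
  k <- dat$k
  lambda <- -log(prior$pc_alpha) / prior$pc_u
  fit_rho <- is.null(rho_fixed)

  # initial values: empirical logits with a light continuity correction
  p_se <- (dat$x_se + 0.5) / (dat$n_se + 1)
  p_sp <- (dat$x_sp + 0.5) / (dat$n_sp + 1)
  mu <- c(mean(logit(p_se)), mean(logit(p_sp)))
  phi <- cbind(logit(p_se) - mu[1], logit(p_sp) - mu[2])
  ls <- log(pmax(c(stats::sd(phi[, 1]), stats::sd(phi[, 2])), 0.2))
  if (k == 1) ls <- c(log(0.5), log(0.5))
  z <- 0
  rho <- if (fit_rho) tanh(z) else rho_fixed

  s1 <- exp(ls[1]); s2 <- exp(ls[2])
  llvec <- if (likelihood) .llvec(mu[1] + phi[, 1], mu[2] + phi[, 2], dat)
           else numeric(k)
  lre <- .lbvn(phi[, 1], phi[, 2], s1, s2, rho)

  lp_mu <- function(m) dnorm(m[1], 0, prior$mu_sd, log = TRUE) +
    dnorm(m[2], 0, prior$mu_sd, log = TRUE)
  # hyper log prior on the unconstrained scale (log-sigma Jacobian folded in;
  # on the z scale the Fisher-z normal prior needs no Jacobian)
  lp_hyper <- function(ls, z) {
    sum(log(lambda) - lambda * exp(ls) + ls) +
      if (fit_rho) dnorm(z, 0, prior$z_sd, log = TRUE) else 0
  }

  # proposal scales, adapted in batches of 50 during burn-in; pairs target
  # ~30% acceptance, scalar hyperparameter updates ~44%
  sc_mu <- 0.2; sc_phi <- 0.5; sc_hyp <- c(0.4, 0.4, 0.4); sc_tr <- 0.2
  sc_sc <- c(0.3, 0.3); sc_zr <- 0.5
  n_acc <- c(mu = 0, phi = 0, hyp = 0, tr = 0, sc = 0)
  b_acc <- c(mu = 0, phi = 0, h1 = 0, h2 = 0, h3 = 0, tr = 0, s1 = 0, s2 = 0,
             zr = 0)
  batch <- 0

  keep <- iter - burn
  out <- matrix(NA_real_, keep, 5)

  for (t in seq_len(iter)) {
    # --- mean pair ---
    mu_p <- mu + rnorm(2, 0, sc_mu)
    ll_p <- if (likelihood) .llvec(mu_p[1] + phi[, 1], mu_p[2] + phi[, 2], dat)
            else numeric(k)
    d <- sum(ll_p) - sum(llvec) + lp_mu(mu_p) - lp_mu(mu)
    if (is.finite(d) && log(runif(1)) < d) {
      mu <- mu_p; llvec <- ll_p
      n_acc["mu"] <- n_acc["mu"] + 1; b_acc["mu"] <- b_acc["mu"] + 1
    }

    # --- translation move: shift the means, counter-shift every deviation.
    # The linear predictors (and so the likelihood) are unchanged; only the
    # random-effect density and the mean priors enter the ratio. This
    # decouples mu from the deviations and is what makes the centered
    # parameterization mix under strong heterogeneity. ---
    delta <- rnorm(2, 0, sc_tr)
    mu_p <- mu + delta
    d <- sum(.lbvn(phi[, 1] - delta[1], phi[, 2] - delta[2], s1, s2, rho)) -
      sum(lre) + lp_mu(mu_p) - lp_mu(mu)
    if (is.finite(d) && log(runif(1)) < d) {
      mu <- mu_p
      phi[, 1] <- phi[, 1] - delta[1]
      phi[, 2] <- phi[, 2] - delta[2]
      lre <- .lbvn(phi[, 1], phi[, 2], s1, s2, rho)
      n_acc["tr"] <- n_acc["tr"] + 1; b_acc["tr"] <- b_acc["tr"] + 1
    }

    # --- per-study deviation pairs (vectorized accept/reject) ---
    phi_p <- phi + matrix(rnorm(2 * k, 0, sc_phi), k, 2)
    ll_p <- if (likelihood) .llvec(mu[1] + phi_p[, 1], mu[2] + phi_p[, 2], dat)
            else numeric(k)
    lre_p <- .lbvn(phi_p[, 1], phi_p[, 2], s1, s2, rho)
    di <- ll_p - llvec + lre_p - lre
    acc <- !is.na(di) & log(runif(k)) < di
    if (any(acc)) {
      phi[acc, ] <- phi_p[acc, ]
      llvec[acc] <- ll_p[acc]
      lre[acc] <- lre_p[acc]
    }
    n_acc["phi"] <- n_acc["phi"] + mean(acc)
    b_acc["phi"] <- b_acc["phi"] + mean(acc)

    # --- scale moves: rescale one margin's SD together with its deviations
    # (the standardized effects are held fixed, so the random-effect density
    # change cancels the Jacobian exactly and only the likelihood and the
    # SD prior enter). This is the non-centered direction and is what keeps
    # sigma mixing when the posterior approaches the no-heterogeneity
    # boundary. ---
    for (j in 1:2) {
      e <- rnorm(1, 0, sc_sc[j])
      ls_p <- ls; ls_p[j] <- ls[j] + e
      phi_p <- phi; phi_p[, j] <- phi[, j] * exp(e)
      ll_p <- if (likelihood)
        .llvec(mu[1] + phi_p[, 1], mu[2] + phi_p[, 2], dat) else numeric(k)
      d <- sum(ll_p) - sum(llvec) + lp_hyper(ls_p, z) - lp_hyper(ls, z)
      if (is.finite(d) && log(runif(1)) < d) {
        ls <- ls_p; phi <- phi_p; llvec <- ll_p
        s1 <- exp(ls[1]); s2 <- exp(ls[2])
        lre <- .lbvn(phi[, 1], phi[, 2], s1, s2, rho)
        b_acc[6 + j] <- b_acc[6 + j] + 1
        n_acc["sc"] <- n_acc["sc"] + 0.5
      }
    }

    # --- hyperparameters: scalar updates of log sigma_se, log sigma_sp, z ---
    nh <- if (fit_rho) 3L else 2L
    for (j in seq_len(nh)) {
      ls_p <- ls; z_p <- z
      if (j <= 2) ls_p[j] <- ls[j] + rnorm(1, 0, sc_hyp[j])
      else z_p <- z + rnorm(1, 0, sc_hyp[3])
      rho_p <- if (fit_rho) tanh(z_p) else rho
      s1_p <- exp(ls_p[1]); s2_p <- exp(ls_p[2])
      lre_p <- .lbvn(phi[, 1], phi[, 2], s1_p, s2_p, rho_p)
      d <- sum(lre_p) - sum(lre) + lp_hyper(ls_p, z_p) - lp_hyper(ls, z)
      if (is.finite(d) && log(runif(1)) < d) {
        ls <- ls_p; z <- z_p; rho <- rho_p; s1 <- s1_p; s2 <- s2_p
        lre <- lre_p
        n_acc["hyp"] <- n_acc["hyp"] + 1 / nh
        b_acc[2 + j] <- b_acc[2 + j] + 1
      }
    }

    # --- joint (z, phi_sp) move: hold the sensitivity deviations and the
    # standardized specificity innovations fixed while moving the
    # correlation, so the deviations are rebuilt under the proposed rho.
    # The bivariate-normal density change cancels the Jacobian of the
    # rebuild, leaving the specificity likelihood and the z prior; this is
    # the move that crosses between a boundary-correlation mode and the
    # interior. ---
    if (fit_rho && abs(rho) < 1 - 1e-12) {
      # sqrt(1 - tanh(z)^2) = sech(z), computed stably
      w2 <- (phi[, 2] / s2 - rho * phi[, 1] / s1) / (1 / cosh(z))
      z_p <- z + rnorm(1, 0, sc_zr)
      rho_p <- tanh(z_p)
      if (abs(rho_p) < 1 - 1e-12) { # otherwise out of support: reject
        phi2_p <- s2 * (rho_p * phi[, 1] / s1 + (1 / cosh(z_p)) * w2)
        ll_p <- if (likelihood) .llvec(mu[1] + phi[, 1], mu[2] + phi2_p, dat)
                else numeric(k)
        d <- sum(ll_p) - sum(llvec) +
          dnorm(z_p, 0, prior$z_sd, log = TRUE) -
          dnorm(z, 0, prior$z_sd, log = TRUE)
        if (is.finite(d) && log(runif(1)) < d) {
          z <- z_p; rho <- rho_p; phi[, 2] <- phi2_p; llvec <- ll_p
          lre <- .lbvn(phi[, 1], phi[, 2], s1, s2, rho)
          b_acc["zr"] <- b_acc["zr"] + 1
        }
      }
    }

    # --- independence refresh of z from its prior: the proposal density
    # cancels the prior in the MH ratio, leaving only the random-effect
    # density, so this jumps freely across the flat region when the
    # correlation is weakly identified (small k) and is simply rejected
    # when the data pin rho down. ---
    if (fit_rho) {
      z_p <- rnorm(1, 0, prior$z_sd)
      rho_p <- tanh(z_p)
      lre_p <- .lbvn(phi[, 1], phi[, 2], s1, s2, rho_p)
      d <- sum(lre_p) - sum(lre)
      if (is.finite(d) && log(runif(1)) < d) {
        z <- z_p; rho <- rho_p; lre <- lre_p
      }
    }

    # --- adaptation (burn-in only), batch size 50, diminishing steps ---
    if (t <= burn && t %% 50 == 0) {
      batch <- batch + 1
      gamma <- min(0.5, 1 / sqrt(batch))
      rate <- b_acc / 50
      sc_mu <- sc_mu * exp(gamma * (rate["mu"] - 0.3))
      sc_phi <- sc_phi * exp(gamma * (rate["phi"] - 0.3))
      sc_hyp <- sc_hyp * exp(gamma * (rate[3:5] - 0.44))
      sc_tr <- sc_tr * exp(gamma * (rate["tr"] - 0.3))
      sc_sc <- sc_sc * exp(gamma * (rate[7:8] - 0.44))
      sc_zr <- sc_zr * exp(gamma * (rate["zr"] - 0.44))
      b_acc[] <- 0
    }

    if (t > burn)
      out[t - burn, ] <- c(mu[1], mu[2], s1, s2, rho)
  }

  list(draws = out, acc = n_acc / iter)
}

#' Posterior summaries of retained draws
#'
#' Median, mean and equal-tailed 95% interval for every column of a draw
#' matrix. Derived quantities (pooled sensitivity/specificity, AUC) must be
#' computed draw-wise *before* summarizing; this function never transforms
#' a summary.
#'
#' @param draws `data.frame` or matrix of posterior draws, one column per
#'   quantity.
#' @return A `data.frame` with one row per quantity: `median`, `mean`,
#'   `lower`, `upper` (2.5% and 97.5% quantiles).
#' @export
summarize_posterior <- function(draws) {
  draws <- as.data.frame(draws)
  if (nrow(draws) == 0) stop("no draws to summarize")
  out <- data.frame(
    quantity = names(draws),
    median = vapply(draws, median, numeric(1)),
    mean = vapply(draws, mean, numeric(1)),
    lower = vapply(draws, quantile, numeric(1), probs = 0.025, names = FALSE),
    upper = vapply(draws, quantile, numeric(1), probs = 0.975, names = FALSE))
  rownames(out) <- NULL
  out
}

#' @export
print.dta_fit <- function(x, ...) {
  cat(sprintf(
    "Bivariate binomial-normal fit: %d studies, %d chains x %d iter (burn %d)\n",
    x$k, x$config$chains, x$config$iter, x$config$burn))
  if (!x$converged)
    cat("** NOT CONVERGED (split R-hat above threshold) -- do not report **\n")
  print(x$summary, digits = 3)
  cat(sprintf("max split R-hat %.3f; acceptance mu %.2f / effects %.2f / hyper %.2f\n",
              max(x$diagnostics$rhat), x$diagnostics$acceptance[1],
              x$diagnostics$acceptance[2], x$diagnostics$acceptance[3]))
  invisible(x)
}
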