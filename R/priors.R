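#' Prior specification for the bivariate model
#'
#' The fixed-effect logit means get independent mean-zero normal priors with
#' a large standard deviation (`mu_sd`, default 10 on the logit scale:
#' effectively flat over any plausible pooled sensitivity/specificity while
#' keeping the posterior proper). The two random-effect standard deviations
#' get penalized complexity (PC) priors with hyperparameters `(pc_u,
#' pc_alpha)`: the exponential prior on an SD calibrated so that
#' `P(sigma > pc_u) = pc_alpha` (default `PC(3, 0.05)`), which shrinks
#' toward the no-heterogeneity base model. The between-study correlation is
#' given a mean-zero normal prior with SD `z_sd` on the Fisher-z scale
#' (`z = atanh(rho)`, default SD 5).
#'
#' @param mu_sd SD of the normal prior on each logit-scale mean. Default 10.
#' @param pc_u,pc_alpha PC-prior hyperparameters: `P(sigma > pc_u) =
#'   pc_alpha`. Defaults 3 and 0.05.
#' @param z_sd SD of the normal prior on the Fisher-z correlation. Default 5.
#' @return An object of class `"prior_spec"`.
#' @export
prior_spec <- function(mu_sd = 10, pc_u = 3, pc_alpha = 0.05, z_sd = 5) {
  stopifnot(mu_sd > 0, pc_u > 0, z_sd > 0, pc_alpha > 0, pc_alpha < 1)
  structure(list(mu_sd = mu_sd, pc_u = pc_u, pc_alpha = pc_alpha,
                 z_sd = z_sd), class = "prior_spec")
}

#' PC prior log density for a random-effect standard deviation
#'
#' The penalized complexity prior on the SD of a Gaussian random effect is
#' exponential with rate `lambda = -log(pc_alpha) / pc_u`, so that
#' `P(sigma > pc_u) = pc_alpha` exactly.
#'
#' @param sigma SD value(s); non-positive values return `-Inf` (an
#'   out-of-support state, rejected inside the sampler rather than raised).
#' @param pc_u,pc_alpha Hyperparameters, see [prior_spec()].
#' @return Log density, vectorized over `sigma`.
#' @examples
#' pc_prior_logdensity(1)                      # log(0.9986) - 0.9986
#' -log(0.05) / 3                              # the rate lambda
#' @export
pc_prior_logdensity <- function(sigma, pc_u = 3, pc_alpha = 0.05) {
  lambda <- -log(pc_alpha) / pc_u
  ifelse(sigma > 0, log(lambda) - lambda * sigma, -Inf)
}
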