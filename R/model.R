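# Model mathematics of the partially observable predictor (POP) model:
# exponential learning-curve process likelihood, logistic structural model,
# hierarchical and hyper priors, and the joint log posterior.

#' Expected response time under the exponential learning model
#'
#' Mean of the learning curve, `a + g * exp(-r * m)`: performance starts at
#' `a + g` on day 0 and decays exponentially towards the asymptote `a` at
#' rate `r`.
#'
#' @param params latent learning parameters; a named vector with elements
#'   `a`, `g`, `r` (see [learning_params()]; `eps` is ignored here).
#' @param m measurement time(s) in days since first assessment; vectorized.
#' @return Expected response time(s) in seconds, same length as `m`.
#' @examples
#' learning_mean(learning_params(2, 1, 0.5, 0.3), m = 0:5)
#' @export
learning_mean <- function(params, m) {
  stopifnot(all(is.finite(m)))
  unname(params["a"] + params["g"] * exp(-params["r"] * m))
}

#' Process-model log likelihood for one participant
#'
#' Sum of Gaussian log densities of the observed daily mean response times
#' around the person's learning curve, with residual SD `eps`.
#'
#' @param y observed daily mean response times, seconds.
#' @param m measurement times in days, same length as `y`.
#' @param params latent learning parameters ([learning_params()]).
#' @return Log likelihood (scalar).
#' @export
process_loglik <- function(y, m, params) {
  if (length(y) != length(m)) stop("'y' and 'm' must have equal length")
  eps <- params[["eps"]]
  if (!is.finite(eps) || eps <= 0)
    stop("'eps' (residual SD) must be positive")
  sum(dnorm(y, learning_mean(params, m), eps, log = TRUE))
}

#' Linear predictor of the structural model
#'
#' The log-odds of MCI: intercept plus weighted latent markers (raw scale)
#' plus weighted manifest covariates.
#'
#' @param coefs structural coefficients ([structural_coefs()]).
#' @param latents latent markers: a named vector (`a`, `g`, `r`, `eps`) or
#'   an n x 4 matrix with those columns.
#' @param covariates manifest covariates: a named vector or n x 5
#'   matrix/data frame with elements `age_std`, `sex_male`, `edu_std`,
#'   `race_black`, `eth_hispanic`. Defaults to the all-zero reference
#'   profile (average age and education, male, White, non-Hispanic).
#' @return Numeric vector of linear predictors, one per row.
#' @export
linear_predictor <- function(coefs, latents, covariates = NULL) {
  coefs <- check_coefs(coefs)
  lat <- as_latent_matrix(latents)
  if (is.null(covariates)) {
    cov <- matrix(0, nrow(lat), length(COVARIATE_NAMES),
                  dimnames = list(NULL, COVARIATE_NAMES))
  } else {
    cov <- as_covariate_matrix(covariates)
  }
  if (nrow(cov) != nrow(lat))
    stop("'latents' and 'covariates' must describe the same persons")
  bl <- coefs[c("beta_a", "beta_g", "beta_r", "beta_eps")]
  bx <- coefs[c("beta_age", "beta_sex", "beta_edu", "beta_race", "beta_eth")]
  as.vector(coefs[["beta0"]] + lat %*% bl + cov %*% bx)
}

#' Model-implied MCI risk
#'
#' Logistic transform of [linear_predictor()]: the probability that a
#' participant with the given latent markers and covariates has MCI.
#'
#' @inheritParams linear_predictor
#' @return Probabilities in (0, 1), one per person.
#' @examples
#' # baseline risk of an average participant under the default estimates
#' mci_risk(default_coefs(), latent_group_means())
#' @export
mci_risk <- function(coefs, latents, covariates = NULL) {
  plogis(linear_predictor(coefs, latents, covariates))
}

#' Hierarchical log prior of the person-level latent markers
#'
#' Sum over persons and markers of Gaussian log densities around the
#' group-level means. The positivity constraint on `eps` is imposed by
#' truncation: non-positive `eps` has log density `-Inf`, and the
#' truncation normalization constant is omitted (applied consistently, it
#' shifts the joint target by a constant for fixed hyperparameters).
#'
#' @param latents n x 4 latent matrix or single named vector.
#' @param hypers group-level hyperparameters ([group_hypers()]).
#' @return Log density (scalar); `-Inf` if any `eps <= 0`.
#' @export
hier_logprior <- function(latents, hypers) {
  hypers <- check_hypers(hypers)
  lat <- as_latent_matrix(latents)
  if (any(lat[, "eps"] <= 0)) return(-Inf)
  sum(dnorm(lat[, "a"], hypers["mu_a"], hypers["sigma_a"], log = TRUE)) +
    sum(dnorm(lat[, "g"], hypers["mu_g"], hypers["sigma_g"], log = TRUE)) +
    sum(dnorm(lat[, "r"], hypers["mu_r"], hypers["sigma_r"], log = TRUE)) +
    sum(dnorm(lat[, "eps"], hypers["mu_eps"], hypers["sigma_eps"],
              log = TRUE))
}

#' Log density of the hyperpriors
#'
#' Weakly informative priors: standard normal on the four group-level means
#' and all ten structural coefficients, and positive half-normal(0, 1) on
#' the four group-level SDs.
#'
#' @param hypers group-level hyperparameters ([group_hypers()]).
#' @param coefs structural coefficients ([structural_coefs()]).
#' @return Log density (scalar).
#' @export
hyper_logprior <- function(hypers, coefs) {
  hypers <- check_hypers(hypers)
  coefs <- check_coefs(coefs)
  mus <- hypers[grep("^mu", names(hypers))]
  sigmas <- hypers[grep("^sigma", names(hypers))]
  sum(dnorm(mus, 0, 1, log = TRUE)) +
    sum(dnorm(sigmas, 0, 1, log = TRUE) + log(2)) +
    sum(dnorm(coefs, 0, 1, log = TRUE))
}

#' Joint log posterior of the POP model
#'
#' Unnormalized log posterior density: process log likelihoods of all
#' participants' response-time series, Bernoulli log likelihood of every
#' observed MCI status at the model-implied risk (participants with missing
#' status contribute no Bernoulli term), the hierarchical prior of the
#' latent markers, and the hyperpriors.
#'
#' @param data a [pop_data] object.
#' @param latents n x 4 latent matrix, rows ordered as the participants in
#'   `data`.
#' @param hypers group-level hyperparameters.
#' @param coefs structural coefficients.
#' @return Log posterior density up to an additive constant.
#' @export
joint_log_posterior <- function(data, latents, hypers, coefs) {
  stopifnot(inherits(data, "pop_data"))
  lat <- as_latent_matrix(latents)
  n <- length(data$ids)
  if (nrow(lat) != n)
    stop("'latents' must have one row per participant")
  lp <- 0
  for (i in seq_len(n)) {
    lp <- lp + process_loglik(data$y[[i]], data$t[[i]], lat[i, ])
  }
  pi_i <- mci_risk(coefs, lat, data$x)
  z <- data$z
  obs <- !is.na(z)
  if (any(obs)) {
    lp <- lp + sum(z[obs] * log(pi_i[obs]) +
                     (1 - z[obs]) * log1p(-pi_i[obs]))
  }
  lp + hier_logprior(lat, hypers) + hyper_logprior(hypers, coefs)
}
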