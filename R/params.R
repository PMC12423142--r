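# Parameter containers: plain named numeric vectors with strict name checks.
# Latent markers for several persons are handled as an n x 4 matrix with
# columns a, g, r, eps.

LATENT_NAMES <- c("a", "g", "r", "eps")

COEF_NAMES <- c("beta0", "beta_a", "beta_g", "beta_r", "beta_eps",
                "beta_age", "beta_sex", "beta_edu", "beta_race", "beta_eth")

HYPER_NAMES <- c("mu_a", "sigma_a", "mu_g", "sigma_g",
                 "mu_r", "sigma_r", "mu_eps", "sigma_eps")

COVARIATE_NAMES <- c("age_std", "sex_male", "edu_std",
                     "race_black", "eth_hispanic")

#' Person-level latent learning parameters
#'
#' Bundle the four latent cognitive markers of the exponential learning
#' model: the asymptote `a` (peak response time approached with practice,
#' seconds), the gain `g` (height of the learning curve above its asymptote,
#' seconds), the learning rate `r` (steepness of improvement per day) and
#' the intra-individual variability `eps` (residual SD of daily performance
#' around the curve, seconds). `a`, `g` and `r` are unconstrained (a
#' negative `r` models worsening performance); `eps` must be positive.
#'
#' @param a asymptote, seconds.
#' @param g gain, seconds.
#' @param r learning rate, per day.
#' @param eps residual SD, seconds; must be `> 0`.
#' @return Named numeric vector with elements `a`, `g`, `r`, `eps`.
#' @examples
#' learning_params(a = 2, g = 1, r = 0.5, eps = 0.3)
#' @export
learning_params <- function(a, g, r, eps) {
  stopifnot(is.numeric(a), is.numeric(g), is.numeric(r), is.numeric(eps),
            length(a) == 1L, length(g) == 1L, length(r) == 1L,
            length(eps) == 1L, is.finite(c(a, g, r, eps)))
  if (eps <= 0) stop("'eps' (residual SD) must be positive")
  c(a = a, g = g, r = r, eps = eps)
}

#' Structural-model coefficients
#'
#' Regression weights of the logistic structural model linking latent
#' markers and manifest covariates to MCI status: an intercept, four
#' weights on the latent markers (asymptote, gain, learning rate,
#' intra-individual variability, entered on their raw scale) and five on
#' the manifest covariates (standardized age, male dummy, standardized
#' education, Black dummy, Hispanic dummy).
#'
#' @param beta0 intercept.
#' @param beta_a,beta_g,beta_r,beta_eps weights on the latent markers.
#' @param beta_age,beta_sex,beta_edu,beta_race,beta_eth weights on the
#'   manifest covariates.
#' @return Named numeric vector of length 10.
#' @seealso [default_coefs()] for defaults mirroring a large aging-cohort
#'   analysis.
#' @export
structural_coefs <- function(beta0 = 0, beta_a = 0, beta_g = 0, beta_r = 0,
                             beta_eps = 0, beta_age = 0, beta_sex = 0,
                             beta_edu = 0, beta_race = 0, beta_eth = 0) {
  out <- c(beta0 = beta0, beta_a = beta_a, beta_g = beta_g, beta_r = beta_r,
           beta_eps = beta_eps, beta_age = beta_age, beta_sex = beta_sex,
           beta_edu = beta_edu, beta_race = beta_race, beta_eth = beta_eth)
  if (!all(is.finite(out))) stop("all coefficients must be finite")
  out
}

#' Group-level hyperparameters of the latent markers
#'
#' Means and standard deviations of the four Gaussian population
#' distributions pooling the person-level latent markers.
#'
#' @param mu_a,mu_g,mu_r,mu_eps group-level means.
#' @param sigma_a,sigma_g,sigma_r,sigma_eps group-level SDs; must be `> 0`.
#' @return Named numeric vector of length 8.
#' @export
group_hypers <- function(mu_a = 0, sigma_a = 1, mu_g = 0, sigma_g = 1,
                         mu_r = 0, sigma_r = 1, mu_eps = 0, sigma_eps = 1) {
  out <- c(mu_a = mu_a, sigma_a = sigma_a, mu_g = mu_g, sigma_g = sigma_g,
           mu_r = mu_r, sigma_r = sigma_r, mu_eps = mu_eps,
           sigma_eps = sigma_eps)
  if (!all(is.finite(out))) stop("all hyperparameters must be finite")
  if (any(out[c("sigma_a", "sigma_g", "sigma_r", "sigma_eps")] <= 0))
    stop("group-level SDs must be positive")
  out
}

#' Default structural coefficients and group-level hyperparameters
#'
#' Posterior-mean estimates from a measurement-burst study of older adults
#' (N = 316, 16 daily assessments, 29% MCI prevalence) in which higher
#' asymptotes and slower learning predicted MCI. They serve as defaults for
#' the synthetic-data generator and for counterfactual risk profiles.
#'
#' @return For `default_coefs()`, a named coefficient vector as
#'   [structural_coefs()]; for `default_hypers()`, a named hyperparameter
#'   vector as [group_hypers()].
#' @examples
#' plogis(linear_predictor(default_coefs(), latent_group_means()))
#' @export
default_coefs <- function() {
  structural_coefs(beta0 = -2.8047, beta_a = 0.6362, beta_g = -0.0339,
                   beta_r = -1.4253, beta_eps = 0.8513, beta_age = 0.1929,
                   beta_sex = -0.1975, beta_edu = 0.1907, beta_race = 0.4855,
                   beta_eth = 0.3031)
}

#' @rdname default_coefs
#' @export
default_hypers <- function() {
  group_hypers(mu_a = 2.9533, sigma_a = 0.9053,
               mu_g = 1.8067, sigma_g = 1.1512,
               mu_r = 0.5367, sigma_r = 0.2989,
               mu_eps = 0.7658, sigma_eps = 0.4436)
}

#' @rdname default_coefs
#' @param hypers group-level hyperparameters; the latent markers are set to
#'   their group-level means.
#' @export
latent_group_means <- function(hypers = default_hypers()) {
  hypers <- check_hypers(hypers)
  c(a = unname(hypers["mu_a"]), g = unname(hypers["mu_g"]),
    r = unname(hypers["mu_r"]), eps = unname(hypers["mu_eps"]))
}

# -- internal validators -----------------------------------------------------

check_coefs <- function(coefs) {
  if (!is.numeric(coefs) || length(coefs) != length(COEF_NAMES) ||
      !all(COEF_NAMES %in% names(coefs)))
    stop("'coefs' must be a named numeric vector with elements ",
         paste(COEF_NAMES, collapse = ", "))
  coefs[COEF_NAMES]
}

check_hypers <- function(hypers, allow_zero = FALSE) {
  if (!is.numeric(hypers) || !all(HYPER_NAMES %in% names(hypers)))
    stop("'hypers' must be a named numeric vector with elements ",
         paste(HYPER_NAMES, collapse = ", "))
  hypers <- hypers[HYPER_NAMES]
  sig <- hypers[grep("^sigma", HYPER_NAMES)]
  if (any(if (allow_zero) sig < 0 else sig <= 0))
    stop("group-level SDs ('sigma_*') must be positive")
  hypers
}

# Accept a single named vector or an n x 4 matrix/data.frame of latents;
# return an n x 4 matrix with canonical column order.
as_latent_matrix <- function(lat) {
  if (is.data.frame(lat)) lat <- as.matrix(lat)
  if (is.null(dim(lat))) {
    if (!all(LATENT_NAMES %in% names(lat)))
      stop("latent parameters must have elements a, g, r, eps")
    lat <- matrix(lat[LATENT_NAMES], nrow = 1L,
                  dimnames = list(NULL, LATENT_NAMES))
  } else {
    if (!all(LATENT_NAMES %in% colnames(lat)))
      stop("latent parameter matrix must have columns a, g, r, eps")
    lat <- lat[, LATENT_NAMES, drop = FALSE]
  }
  storage.mode(lat) <- "double"
  lat
}

as_covariate_matrix <- function(cov) {
  if (is.data.frame(cov)) cov <- as.matrix(cov[, intersect(
    colnames(cov), COVARIATE_NAMES), drop = FALSE])
  if (is.null(dim(cov))) {
    if (!all(COVARIATE_NAMES %in% names(cov)))
      stop("covariates must have elements ",
           paste(COVARIATE_NAMES, collapse = ", "))
    cov <- matrix(cov[COVARIATE_NAMES], nrow = 1L,
                  dimnames = list(NULL, COVARIATE_NAMES))
  } else {
    if (!all(COVARIATE_NAMES %in% colnames(cov)))
      stop("covariate matrix must have columns ",
           paste(COVARIATE_NAMES, collapse = ", "))
    cov <- cov[, COVARIATE_NAMES, drop = FALSE]
  }
  storage.mode(cov) <- "double"
  dm <- cov[, c("sex_male", "race_black", "eth_hispanic")]
  if (!all(dm %in% c(0, 1)))
    stop("dummy covariates must be coded 0/1")
  cov
}
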