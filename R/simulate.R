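# Synthetic measurement-burst data generator with known ground truth.
# Defaults emulate a 316-person, 16-day burst cohort of adults aged 70+
# with ~29% MCI prevalence; generation starts at the daily-mean level the
# model consumes.

#' Configuration for the synthetic measurement-burst generator
#'
#' Defaults describe the cohort the package's defaults were calibrated to:
#' 316 participants assessed daily for 16 days, age 77.5 (SD 5.0) years,
#' 67% female, 15.1 (SD 3.6) years of education, 43% Black, 13% Hispanic,
#' with latent markers and outcome generated from [default_hypers()] and
#' [default_coefs()].
#'
#' @param n_participants number of participants (>= 2).
#' @param n_days number of daily assessments (>= 2); measurement days run
#'   `0 .. n_days - 1`.
#' @param hypers generating group-level hyperparameters.
#' @param coefs generating structural coefficients.
#' @param age_mean,age_sd age distribution in years (standardized
#'   within-sample before entering the model).
#' @param prop_female proportion female (the sex dummy codes male = 1).
#' @param edu_mean,edu_sd education distribution in years (standardized
#'   within-sample).
#' @param p_black,p_hispanic probabilities of the race and ethnicity
#'   dummies.
#' @param seed integer seed making the whole generation deterministic.
#' @return An object of class `pop_sim_config` (a list of the above).
#' @export
pop_sim_config <- function(n_participants = 316, n_days = 16,
                           hypers = default_hypers(),
                           coefs = default_coefs(),
                           age_mean = 77.54, age_sd = 4.98,
                           prop_female = 0.67,
                           edu_mean = 15.09, edu_sd = 3.55,
                           p_black = 0.43, p_hispanic = 0.13,
                           seed = 1L) {
  stopifnot(n_participants >= 2, n_days >= 2,
            prop_female >= 0, prop_female <= 1,
            p_black >= 0, p_black <= 1,
            p_hispanic >= 0, p_hispanic <= 1,
            age_sd > 0, edu_sd > 0)
  structure(list(n_participants = as.integer(n_participants),
                 n_days = as.integer(n_days),
                 hypers = check_hypers(hypers, allow_zero = TRUE),
                 coefs = check_coefs(coefs),
                 age_mean = age_mean, age_sd = age_sd,
                 prop_female = prop_female,
                 edu_mean = edu_mean, edu_sd = edu_sd,
                 p_black = p_black, p_hispanic = p_hispanic,
                 seed = as.integer(seed)),
            class = "pop_sim_config")
}

#' Simulate manifest demographic covariates
#'
#' Age and education are drawn from the configured normals and then
#' standardized within-sample (mean 0, SD 1), matching an analysis of a
#' fixed cohort; sex, race and ethnicity are Bernoulli dummies.
#'
#' @param config a [pop_sim_config()].
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return Data frame with columns `age_std`, `sex_male`, `edu_std`,
#'   `race_black`, `eth_hispanic` (plus raw `age_years`, `edu_years`).
#' @export
simulate_covariates <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_participants
  if (n < 2) stop("need n >= 2 to standardize within-sample")
  age <- rnorm(n, config$age_mean, config$age_sd)
  edu <- rnorm(n, config$edu_mean, config$edu_sd)
  data.frame(
    age_std = as.vector(scale(age)),
    sex_male = rbinom(n, 1, 1 - config$prop_female),
    edu_std = as.vector(scale(edu)),
    race_black = rbinom(n, 1, config$p_black),
    eth_hispanic = rbinom(n, 1, config$p_hispanic),
    age_years = age, edu_years = edu)
}

#' Simulate person-level latent learning parameters
#'
#' Draws `a`, `g`, `r`, `eps` from the four group-level normals. `eps` and
#' `r` are redrawn until positive (rejection) so every generated learning
#' curve improves over days and has a valid residual SD; rejection counts
#' are attached as attribute `"n_rejected"`.
#'
#' @inheritParams simulate_covariates
#' @return n x 4 matrix with columns `a`, `g`, `r`, `eps`.
#' @export
simulate_latents <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- config$hypers
  n <- config$n_participants
  degen <- FALSE
  draw <- function(mu, sigma, positive) {
    if (sigma == 0) { degen <<- TRUE; return(rep(mu, n)) }
    x <- rnorm(n, mu, sigma)
    rej <- 0L
    if (positive) {
      while (any(bad <- x <= 0)) {
        rej <- rej + sum(bad)
        x[bad] <- rnorm(sum(bad), mu, sigma)
      }
    }
    attr(x, "n_rejected") <- rej
    x
  }
  a <- draw(h["mu_a"], h["sigma_a"], FALSE)
  g <- draw(h["mu_g"], h["sigma_g"], FALSE)
  r <- draw(h["mu_r"], h["sigma_r"], TRUE)
  eps <- draw(h["mu_eps"], h["sigma_eps"], TRUE)
  if (degen) warning("degenerate group-level SD of 0: draws equal the mean")
  out <- cbind(a = as.vector(a), g = as.vector(g), r = as.vector(r),
               eps = as.vector(eps))
  attr(out, "n_rejected") <- c(r = attr(r, "n_rejected") %||% 0L,
                               eps = attr(eps, "n_rejected") %||% 0L)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate MCI outcomes from the structural model
#'
#' Computes each person's true risk via [mci_risk()] and draws the binary
#' status from a Bernoulli.
#'
#' @param coefs structural coefficients.
#' @param latents n x 4 latent matrix.
#' @param covariates covariate data frame/matrix aligned with `latents`.
#' @param seed optional seed.
#' @return Data frame with columns `pi` (true risk) and `mci` (0/1 draw).
#' @export
simulate_outcomes <- function(coefs, latents, covariates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lat <- as_latent_matrix(latents)
  cov <- as_covariate_matrix(covariates)
  if (nrow(lat) != nrow(cov))
    stop("'latents' and 'covariates' must have the same number of rows")
  pi_i <- mci_risk(coefs, lat, cov)
  data.frame(pi = pi_i, mci = rbinom(length(pi_i), 1, pi_i))
}

#' Simulate daily mean response-time series
#'
#' Each person is observed on days `0 .. n_days - 1`; observations are the
#' learning-curve mean plus Gaussian noise with SD `eps`. Non-positive
#' draws are redrawn (response times are positive); the redraw count is
#' attached as attribute `"n_rejected"`.
#'
#' @param latents n x 4 latent matrix.
#' @param config a [pop_sim_config()] (only `n_days` is used).
#' @param seed optional seed.
#' @return List of data frames with columns `day` and `rt_seconds`.
#' @export
simulate_timeseries <- function(latents, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lat <- as_latent_matrix(latents)
  days <- seq(0L, config$n_days - 1L)
  rej <- 0L
  out <- lapply(seq_len(nrow(lat)), function(i) {
    mu <- learning_mean(lat[i, ], days)
    y <- rnorm(length(days), mu, lat[i, "eps"])
    while (any(bad <- y <= 0)) {
      rej <<- rej + sum(bad)
      y[bad] <- rnorm(sum(bad), mu[bad], lat[i, "eps"])
    }
    data.frame(day = days, rt_seconds = y)
  })
  attr(out, "n_rejected") <- rej
  out
}

#' Generate a complete synthetic measurement-burst dataset
#'
#' Composes covariate, latent-marker, outcome and time-series generation
#' into a dataset plus its ground truth. The entire pipeline is a
#' deterministic function of the configuration (including its seed).
#'
#' @param config a [pop_sim_config()].
#' @return An object of class `pop_sim`: list with `data` (a [pop_data]
#'   object) and `truth` (list with the generating `latents` matrix,
#'   `covariates`, true risks `pi`, outcomes `mci`, and the generating
#'   `hypers`, `coefs` and `config`).
#' @examples
#' sim <- pop_simulate(pop_sim_config(n_participants = 10, n_days = 6,
#'                                    seed = 42))
#' sim$data
#' @export
pop_simulate <- function(config = pop_sim_config()) {
  stopifnot(inherits(config, "pop_sim_config"))
  set.seed(config$seed)
  covs <- simulate_covariates(config)
  lat <- simulate_latents(config)
  outc <- simulate_outcomes(config$coefs, lat, covs)
  series <- simulate_timeseries(lat, config)
  ids <- sprintf("p%03d", seq_len(config$n_participants))
  timeseries <- do.call(rbind, lapply(seq_along(series), function(i)
    cbind(participant_id = ids[i], series[[i]])))
  participants <- data.frame(participant_id = ids,
                             covs[, COVARIATE_NAMES],
                             mci = outc$mci)
  data <- pop_data(timeseries, participants)
  structure(list(
    data = data,
    truth = list(latents = lat, covariates = covs, pi = outc$pi,
                 mci = outc$mci, hypers = config$hypers,
                 coefs = config$coefs, config = config,
                 n_rejected = list(
                   latents = attr(lat, "n_rejected"),
                   timeseries = attr(series, "n_rejected")))),
    class = "pop_sim")
}

#' @export
print.pop_sim <- function(x, ...) {
  cat("Synthetic measurement-burst cohort (seed",
      x$truth$config$seed, ")\n")
  print(x$data)
  invisible(x)
}

#' Write a simulated cohort (data + ground truth) to disk
#'
#' Writes `timeseries.csv` and `participants.csv` via [write_pop_data()]
#' plus `truth.json` holding the per-person generating parameters, the
#' generating coefficients/hyperparameters and the seed.
#'
#' @param sim a `pop_sim` object from [pop_simulate()].
#' @param dir output directory.
#' @return Invisibly, the output paths.
#' @export
write_pop_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "pop_sim"))
  paths <- write_pop_data(sim$data, dir)
  cfg <- sim$truth$config
  truth <- list(
    seed = cfg$seed,
    n_participants = cfg$n_participants,
    n_days = cfg$n_days,
    coefs = as.list(sim$truth$coefs),
    hypers = as.list(sim$truth$hypers),
    latents = as.data.frame(cbind(sim$truth$latents)),
    pi = sim$truth$pi,
    mci = sim$truth$mci)
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tp))
}
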