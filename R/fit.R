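# Model fitting front end and S3 methods for the fitted-model object.

#' Fit the joint POP model by MCMC
#'
#' Draws from the joint posterior of the partially observable predictor
#' model: person-level latent markers, group-level hyperparameters and
#' structural coefficients are estimated simultaneously, so uncertainty in
#' the latent markers propagates into the outcome regression. Participants
#' with missing MCI status contribute only their response-time data (their
#' Bernoulli term is dropped); their latent markers and model-implied risk
#' are still estimated, which is how cross-validated prediction works.
#'
#' @param data a [pop_data] object. Every participant needs at least two
#'   observations; MCI status may be missing (`NA`) for any subset.
#' @param process process model for the response-time series:
#'   `"exponential"` (the four-parameter learning-curve model),
#'   `"descriptive"` (per-person mean and SD only) or `"manifest"`
#'   (no process model; logistic regression on the covariates alone).
#' @param chains number of MCMC chains.
#' @param warmup,draws adaptation sweeps and retained posterior draws per
#'   chain, counted after thinning.
#' @param thin sweeps of the sampler per retained draw.
#' @param seed integer seed; chains use seeds `seed + chain - 1` and the
#'   fit is fully deterministic given `seed` and the configuration.
#' @param keep_latents retain per-person latent draws (needed for risk
#'   prediction and fit statistics).
#' @return An object of class `popfit` with, amongst others, `draws` (a
#'   list of per-chain draw matrices with named columns), `par_names`,
#'   `structural_names` (coefficients + hyperparameters) and the matched
#'   call. Use [summary()], [coef()], [predict()], [fitted()],
#'   [residuals()], [plot()] on it.
#' @examples
#' sim <- pop_simulate(pop_sim_config(n_participants = 20, n_days = 8,
#'                                    seed = 7))
#' fit <- pop_fit(sim$data, chains = 2, warmup = 100, draws = 100,
#'                thin = 2, seed = 1)
#' coef(fit)
#' @export
pop_fit <- function(data,
                    process = c("exponential", "descriptive", "manifest"),
                    chains = 4, warmup = 2500, draws = 2500, thin = 8,
                    seed = 1L, keep_latents = TRUE) {
  stopifnot(inherits(data, "pop_data"))
  process <- match.arg(process)
  if (length(data$ids) == 0L) stop("empty dataset")
  if (process != "manifest" && any(lengths(data$y) < 2L))
    stop("every participant needs >= 2 observations")
  stopifnot(chains >= 1, warmup >= 1, draws >= 1, thin >= 1)
  proc <- process_spec(process)
  dat <- prepare_mcmc_data(data)
  t0 <- proc.time()[["elapsed"]]
  draw_list <- lapply(seq_len(chains), function(ch)
    run_pop_chain(dat, proc, warmup = warmup, n_keep = draws, thin = thin,
                  chain_seed = as.integer(seed) + ch - 1L,
                  keep_latents = keep_latents))
  elapsed <- proc.time()[["elapsed"]] - t0
  par_names <- colnames(draw_list[[1L]])
  structural_names <- c(
    grep("^beta", par_names, value = TRUE),
    grep("^(mu|sigma)_", par_names, value = TRUE))
  structure(list(draws = draw_list, par_names = par_names,
                 structural_names = structural_names,
                 process = process, lnames = proc$lnames,
                 data = data,
                 config = list(chains = chains, warmup = warmup,
                               draws = draws, thin = thin,
                               seed = as.integer(seed)),
                 elapsed = elapsed, call = match.call()),
            class = "popfit")
}

# all chains stacked, draws x parameters
stack_draws <- function(fit, pars = NULL) {
  m <- do.call(rbind, fit$draws)
  if (!is.null(pars)) m <- m[, pars, drop = FALSE]
  m
}

# draws of one parameter as iterations x chains
param_matrix <- function(fit, par) {
  vapply(fit$draws, function(d) d[, par], numeric(nrow(fit$draws[[1L]])))
}

# posterior draws of the per-person latent matrix, index [draw, person]
latent_draws <- function(fit, lname) {
  cols <- sprintf("%s[%d]", lname, seq_along(fit$data$ids))
  stack_draws(fit, cols)
}

#' @export
print.popfit <- function(x, ...) {
  cat("Joint POP model fit (", x$process, " process)\n", sep = "")
  cat("  ", length(x$data$ids), " participants, ",
      x$config$chains, " chains x ", x$config$draws,
      " draws (thin ", x$config$thin, ", warmup ", x$config$warmup,
      "), seed ", x$config$seed, "\n", sep = "")
  cat("  elapsed:", sprintf("%.1f s", x$elapsed), "\n")
  cat("Structural coefficients (posterior means):\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' Posterior means of the structural coefficients
#'
#' @param object a `popfit` object.
#' @param which `"structural"` (coefficients + group-level
#'   hyperparameters), `"beta"` (coefficients only) or `"all"`.
#' @param ... unused.
#' @return Named numeric vector of posterior means.
#' @export
coef.popfit <- function(object, which = c("beta", "structural", "all"),
                        ...) {
  which <- match.arg(which)
  pars <- switch(which,
    beta = grep("^beta", object$par_names, value = TRUE),
    structural = object$structural_names,
    all = object$par_names)
  colMeans(stack_draws(object, pars))
}

#' Posterior-mean fitted response times
#'
#' Fitted value for each observed person-day: the posterior mean of the
#' process-model mean function (for the exponential process, the learning
#' curve; for the descriptive process, the person mean).
#'
#' @param object a `popfit` object fitted with `keep_latents = TRUE`.
#' @param ... unused.
#' @return Data frame with columns `participant_id`, `day`, `observed`,
#'   `fitted`.
#' @export
fitted.popfit <- function(object, ...) {
  if (object$process == "manifest")
    stop("no process model was fitted; fitted values are undefined")
  ids <- object$data$ids
  n <- length(ids)
  out <- vector("list", n)
  if (object$process == "exponential") {
    a <- latent_draws(object, "a"); g <- latent_draws(object, "g")
    r <- latent_draws(object, "r")
    for (i in seq_len(n)) {
      tt <- object$data$t[[i]]
      curves <- outer(seq_len(nrow(a)), tt, function(d, m)
        a[d, i] + g[d, i] * exp(-r[d, i] * m))
      out[[i]] <- data.frame(participant_id = ids[i], day = tt,
                             observed = object$data$y[[i]],
                             fitted = colMeans(curves))
    }
  } else {
    m <- colMeans(latent_draws(object, "m"))
    for (i in seq_len(n)) {
      out[[i]] <- data.frame(participant_id = ids[i],
                             day = object$data$t[[i]],
                             observed = object$data$y[[i]],
                             fitted = m[i])
    }
  }
  do.call(rbind, out)
}

#' Residuals of the process model
#'
#' @param object a `popfit` object.
#' @param ... unused.
#' @return Numeric vector of observed minus posterior-mean fitted response
#'   times, in the row order of `fitted(object)`.
#' @export
residuals.popfit <- function(object, ...) {
  f <- fitted(object)
  f$observed - f$fitted
}

#' Posterior-mean MCI risk predictions
#'
#' For each participant, the posterior mean of the model-implied risk
#' `logistic(eta_i)` over all draws (coefficients and latent markers drawn
#' jointly), i.e. uncertainty in the latent markers is integrated over, not
#' plugged in. Works identically for participants whose MCI status was
#' missing during fitting, which is how held-out prediction is done.
#'
#' @param object a `popfit` object.
#' @param type `"risk"` for probabilities, `"link"` for the posterior mean
#'   linear predictor.
#' @param ... unused.
#' @return Named numeric vector, one element per participant.
#' @export
predict.popfit <- function(object, type = c("risk", "link"), ...) {
  type <- match.arg(type)
  eta <- predict_eta_draws(object)
  out <- if (type == "risk") colMeans(plogis(eta)) else colMeans(eta)
  setNames(out, object$data$ids)
}

# draws x persons matrix of linear predictors
predict_eta_draws <- function(object) {
  X <- object$data$x
  n <- length(object$data$ids)
  bdr <- stack_draws(object, grep("^beta", object$par_names, value = TRUE))
  eta <- matrix(bdr[, "beta0"], nrow(bdr), n)
  eta <- eta + bdr[, c("beta_age", "beta_sex", "beta_edu",
                       "beta_race", "beta_eth")] %*% t(X)
  for (l in object$lnames) {
    eta <- eta + bdr[, paste0("beta_", l)] * latent_draws(object, l)
  }
  eta
}

#' Posterior predictive simulation of response-time series
#'
#' Draws replicate datasets: for each simulation a joint posterior draw of
#' the latent markers is selected and a new response-time series generated
#' from the process model.
#'
#' @param object a `popfit` object with an exponential or descriptive
#'   process.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return List of `nsim` data frames shaped like the `timeseries` table.
#' @export
simulate.popfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (object$process == "manifest")
    stop("no process model was fitted; nothing to simulate")
  n <- length(object$data$ids)
  ndr <- nrow(object$draws[[1L]]) * length(object$draws)
  lat <- lapply(object$lnames, function(l) latent_draws(object, l))
  names(lat) <- object$lnames
  reps <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    d <- sample.int(ndr, 1L)
    sims <- lapply(seq_len(n), function(i) {
      tt <- object$data$t[[i]]
      mu <- if (object$process == "exponential")
        lat$a[d, i] + lat$g[d, i] * exp(-lat$r[d, i] * tt)
      else rep(lat$m[d, i], length(tt))
      sdv <- if (object$process == "exponential") lat$eps[d, i] else
        lat$s[d, i]
      data.frame(participant_id = object$data$ids[i], day = tt,
                 rt_seconds = rnorm(length(tt), mu, sdv))
    })
    reps[[s]] <- do.call(rbind, sims)
  }
  reps
}

#' Plot a fitted POP model
#'
#' `type = "curves"` overlays observed daily response times and
#' posterior-mean learning curves for a subset of participants;
#' `type = "trace"` shows trace plots of selected parameters.
#'
#' @param x a `popfit` object.
#' @param type `"curves"` or `"trace"`.
#' @param pars parameters for `type = "trace"` (default: intercept and
#'   latent-marker coefficients).
#' @param persons participant indices for `type = "curves"`.
#' @param ... passed to the underlying plotting functions.
#' @return Invisibly, `x`.
#' @export
plot.popfit <- function(x, type = c("curves", "trace"), pars = NULL,
                        persons = seq_len(min(9L, length(x$data$ids))),
                        ...) {
  type <- match.arg(type)
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  if (type == "curves") {
    f <- fitted(x)
    nr <- ceiling(sqrt(length(persons)))
    graphics::par(mfrow = c(nr, ceiling(length(persons) / nr)),
                  mar = c(3, 3, 2, 1))
    for (i in persons) {
      id <- x$data$ids[i]
      fi <- f[f$participant_id == id, ]
      plot(fi$day, fi$observed, pch = 16, xlab = "day",
           ylab = "RT (s)", main = id, ...)
      graphics::lines(fi$day, fi$fitted, lwd = 2)
    }
  } else {
    if (is.null(pars))
      pars <- intersect(c("beta0", "beta_a", "beta_r", "mu_a"),
                        x$par_names)
    graphics::par(mfrow = c(length(pars), 1), mar = c(2, 4, 1, 1))
    for (p in pars) {
      m <- param_matrix(x, p)
      graphics::matplot(m, type = "l", lty = 1, ylab = p, ...)
    }
  }
  invisible(x)
}

#' Proportion of response-time variance explained by the process model
#'
#' `1 - SS_resid / SS_total`, where fitted values are the posterior-mean
#' process-model curves per person-day and the total sum of squares is
#' taken about the grand mean of all observations, pooled over
#' person-days.
#'
#' @param fit a `popfit` object with a process model.
#' @return Proportion in `[0, 1]` (can be negative for a fit worse than
#'   the grand mean).
#' @export
variance_explained <- function(fit) {
  f <- fitted(fit)
  ss_tot <- sum((f$observed - mean(f$observed))^2)
  if (ss_tot == 0) stop("zero total variance: R^2 undefined")
  1 - sum((f$observed - f$fitted)^2) / ss_tot
}
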