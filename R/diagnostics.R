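# Convergence diagnostics and posterior summaries: split R-hat, initial
# monotone sequence effective sample size, directional probabilities.

#' Split R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift also inflates the statistic. Values near 1
#' indicate convergence; the package's default pass threshold is 1.03.
#'
#' @param x matrix of draws, iterations x chains (>= 2 chains' worth of
#'   halves required, i.e. at least one chain with >= 2 iterations).
#' @return R-hat (scalar); `NA` if the draws are constant.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[seq.int(n - half + 1L, n), , drop = FALSE])
  m <- ncol(sp)
  nn <- nrow(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2L, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (W == 0) return(if (B == 0) NA_real_ else Inf)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size of MCMC draws
#'
#' Autocorrelation-based ESS using chain-averaged autocovariances and
#' Geyer's initial monotone positive sequence truncation.
#'
#' @param x matrix of draws, iterations x chains (a vector is treated as
#'   one chain).
#' @return Effective sample size (scalar).
#' @export
ess_draws <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4L) return(NA_real_)
  acov <- vapply(seq_len(m), function(j) {
    a <- acf(x[, j], lag.max = n - 1L, type = "covariance",
             plot = FALSE, demean = TRUE)$acf[, 1L, 1L]
    a
  }, numeric(n))
  mean_var <- mean(acov[1L, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1L) var_plus <- var_plus + var(colMeans(x))
  if (var_plus == 0) return(NA_real_)
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  # Geyer: sum consecutive lag pairs while positive and non-increasing
  max_pairs <- floor((n - 1) / 2)
  tau <- 1
  prev <- Inf
  t <- 1L
  while (t <= max_pairs) {
    pair <- rho[2L * t] + rho[2L * t + 1L]
    if (!is.finite(pair) || pair <= 0) break
    pair <- min(pair, prev)
    tau <- tau + 2 * pair
    prev <- pair
    t <- t + 1L
  }
  min(m * n / tau, m * n)
}

#' Directional probability of a posterior sample
#'
#' Fraction of draws below and above zero: a graded evidence summary of a
#' coefficient's sign. Draws exactly equal to zero count in neither.
#'
#' @param draws non-empty numeric vector of posterior draws.
#' @return Named vector `c(p_negative, p_positive)`.
#' @examples
#' directional_probability(c(-1, -2, 3))
#' @export
directional_probability <- function(draws) {
  if (length(draws) == 0L) stop("empty draws vector")
  c(p_negative = mean(draws < 0), p_positive = mean(draws > 0))
}

#' Posterior summary table of a fitted POP model
#'
#' One row per parameter with posterior mean, 2.5% and 97.5% empirical
#' percentiles, directional probabilities, split R-hat and effective
#' sample size. Rows are ordered intercept, latent-marker coefficients,
#' manifest coefficients, then group-level means and SDs.
#'
#' @param object a `popfit` object.
#' @param pars parameters to summarize; default: the structural
#'   coefficients and group-level hyperparameters.
#' @param ... unused.
#' @return Data frame of class `summary.popfit` with columns `parameter`,
#'   `mean`, `ci_lower`, `ci_upper`, `p_negative`, `p_positive`, `rhat`,
#'   `ess`.
#' @export
summary.popfit <- function(object, pars = object$structural_names, ...) {
  rows <- lapply(pars, function(p) {
    m <- param_matrix(object, p)
    v <- as.vector(m)
    q <- unname(quantile(v, c(0.025, 0.975), type = 7))
    dp <- directional_probability(v)
    data.frame(parameter = p, mean = mean(v),
               ci_lower = q[1L], ci_upper = q[2L],
               p_negative = unname(dp["p_negative"]),
               p_positive = unname(dp["p_positive"]),
               rhat = if (ncol(m) >= 2L) split_rhat(m) else NA_real_,
               ess = ess_draws(m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.popfit", "data.frame")
  out
}

#' @export
print.summary.popfit <- function(x, digits = 4, ...) {
  y <- x
  num <- vapply(y, is.numeric, logical(1L))
  y[num] <- lapply(y[num], round, digits)
  class(y) <- "data.frame"
  print(y, row.names = FALSE)
  invisible(x)
}

#' Convergence check of a fitted POP model
#'
#' Computes split R-hat and ESS for the structural and group-level
#' parameters and flags parameters exceeding the thresholds.
#'
#' @param fit a `popfit` object (>= 2 chains for R-hat; with a single
#'   chain R-hat is `NA` and flagged as not assessable).
#' @param rhat_max pass threshold for R-hat (default 1.03).
#' @param ess_min warn threshold for ESS (default 300).
#' @param pars parameters to check; defaults to the structural set.
#' @return Data frame with columns `parameter`, `rhat`, `ess`,
#'   `rhat_ok`, `ess_ok`, plus attribute `"pass"` (all R-hats below the
#'   threshold).
#' @export
convergence_check <- function(fit, rhat_max = 1.03, ess_min = 300,
                              pars = fit$structural_names) {
  if (fit$config$chains < 2L)
    warning("R-hat requires >= 2 chains; values are NA")
  s <- summary(fit, pars = pars)
  out <- data.frame(parameter = s$parameter, rhat = s$rhat, ess = s$ess,
                    rhat_ok = !is.na(s$rhat) & s$rhat < rhat_max,
                    ess_ok = !is.na(s$ess) & s$ess >= ess_min)
  attr(out, "pass") <- all(out$rhat_ok)
  out
}
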