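# Adaptive Metropolis-within-Gibbs sampler for the joint POP model.
#
# Person-level latent markers are updated component-wise but vectorized
# across persons (their full conditionals are independent given the global
# parameters); group-level means have conjugate Gibbs updates; group-level
# SDs are updated by random-walk Metropolis on the log scale; structural
# coefficients by component-wise adaptive random walk. Proposal scales are
# tuned during warmup by Robbins-Monro adaptation towards 0.44 acceptance.

# log Bernoulli likelihood at logit eta, numerically stable
bern_ll <- function(eta, z) {
  z * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))
}

# -- process-model definitions ----------------------------------------------
# Each process supplies: latent dimension/names, positivity constraints,
# a vectorized per-person log likelihood on NA-padded matrices, and crude
# per-person initial values.

process_spec <- function(process) {
  switch(process,
    exponential = list(
      k = 4L, lnames = c("a", "g", "r", "eps"),
      positive = c(FALSE, FALSE, FALSE, TRUE),
      row_loglik = function(theta, dat) {
        mu <- theta[, 1L] + theta[, 2L] * exp(-theta[, 3L] * dat$TM)
        -dat$ni * (log(theta[, 4L]) + 0.5 * log(2 * pi)) -
          rowSums((dat$Y - mu)^2, na.rm = TRUE) / (2 * theta[, 4L]^2)
      },
      init = function(dat) {
        n <- nrow(dat$Y)
        theta <- matrix(0, n, 4L,
                        dimnames = list(NULL, c("a", "g", "r", "eps")))
        for (i in seq_len(n)) {
          y <- dat$Y[i, !is.na(dat$Y[i, ])]
          tail_mean <- mean(y[seq.int(max(1L, ceiling(length(y) / 2)),
                                      length(y))])
          theta[i, "a"] <- tail_mean
          theta[i, "g"] <- max(y[1L] - tail_mean, 0.2)
          theta[i, "r"] <- 0.4
          theta[i, "eps"] <- max(sd(y) * 0.8, 0.05)
        }
        theta
      }),
    descriptive = list(
      k = 2L, lnames = c("m", "s"),
      positive = c(FALSE, TRUE),
      row_loglik = function(theta, dat) {
        -dat$ni * (log(theta[, 2L]) + 0.5 * log(2 * pi)) -
          rowSums((dat$Y - theta[, 1L])^2, na.rm = TRUE) /
            (2 * theta[, 2L]^2)
      },
      init = function(dat) {
        m0 <- rowMeans(dat$Y, na.rm = TRUE)
        s0 <- pmax(apply(dat$Y, 1L, sd, na.rm = TRUE), 0.05)
        cbind(m = m0, s = s0)
      }),
    manifest = list(k = 0L, lnames = character(0),
                    positive = logical(0),
                    row_loglik = NULL, init = NULL),
    stop("unknown process model: ", process))
}

# pop_data -> NA-padded matrices for vectorized likelihoods
prepare_mcmc_data <- function(data) {
  n <- length(data$ids)
  Tmax <- max(lengths(data$y))
  Y <- TM <- matrix(NA_real_, n, Tmax)
  for (i in seq_len(n)) {
    ni <- length(data$y[[i]])
    Y[i, seq_len(ni)] <- data$y[[i]]
    TM[i, seq_len(ni)] <- data$t[[i]]
  }
  list(Y = Y, TM = TM, ni = lengths(data$y), X = data$x, z = data$z,
       obs = !is.na(data$z), n = n)
}

# One chain of the sampler. Budget semantics: `n_keep` retained draws after
# thinning; warmup runs `warmup * thin` adaptation sweeps.
run_pop_chain <- function(dat, proc, warmup, n_keep, thin, chain_seed,
                          keep_latents = TRUE) {
  set.seed(chain_seed)
  n <- dat$n
  k <- proc$k
  obs <- dat$obs
  zo <- dat$z[obs]
  p_manifest <- ncol(dat$X)
  p <- 1L + k + p_manifest

  # initial values, jittered per chain
  if (k > 0L) {
    theta <- proc$init(dat) * matrix(exp(rnorm(n * k, 0, 0.05)), n, k)
    mu <- colMeans(theta)
    sigma <- pmax(apply(theta, 2L, sd), 0.1)
    ll_proc <- proc$row_loglik(theta, dat)
  } else {
    theta <- matrix(0, n, 0L)
    mu <- sigma <- numeric(0)
  }
  beta <- rnorm(p, 0, 0.1)

  # adaptive proposal scales (log)
  ls_theta <- matrix(log(0.1), n, k)
  ls_sigma <- rep(log(0.2), k)
  ls_shift <- rep(log(0.05), k)
  ls_scale <- rep(log(0.02), k)
  ls_joint <- log(1)
  nb <- 0
  sum_b <- numeric(p)
  M2b <- matrix(0, p, p)
  ls_beta <- rep(log(0.2), p)
  accept_target <- 0.44

  eta_of <- function() {
    e <- rep(beta[1L], n)
    if (k > 0L) e <- e + theta %*% beta[2L:(1L + k)]
    as.vector(e + dat$X %*% beta[(2L + k):p])
  }
  eta <- eta_of()

  warm_sweeps <- warmup * thin
  total_sweeps <- warm_sweeps + n_keep * thin
  nm_beta <- c("beta0",
               if (k > 0L) paste0("beta_", proc$lnames),
               paste0("beta_", c("age", "sex", "edu", "race", "eth")))
  nm_hyp <- if (k > 0L)
    as.vector(rbind(paste0("mu_", proc$lnames),
                    paste0("sigma_", proc$lnames))) else character(0)
  nm_lat <- if (keep_latents && k > 0L)
    as.vector(vapply(proc$lnames, function(l)
      sprintf("%s[%d]", l, seq_len(n)), character(n))) else character(0)
  draws <- matrix(NA_real_, n_keep, length(nm_beta) + length(nm_hyp) +
                    length(nm_lat),
                  dimnames = list(NULL, c(nm_beta, nm_hyp, nm_lat)))
  kept <- 0L

  for (sweep in seq_len(total_sweeps)) {
    adapting <- sweep <= warm_sweeps
    gam <- if (adapting) (sweep + 10)^(-0.6) else 0

    if (k > 0L) {
      bl <- beta[2L:(1L + k)]
      for (j in seq_len(k)) {
        step <- exp(ls_theta[, j]) * rnorm(n)
        prop <- theta
        prop[, j] <- theta[, j] + step
        valid <- if (proc$positive[j]) prop[, j] > 0 else rep(TRUE, n)
        if (!all(valid)) prop[!valid, j] <- theta[!valid, j]  # auto-reject
        ll_prop <- proc$row_loglik(prop, dat)
        delta <- ll_prop - ll_proc +
          dnorm(prop[, j], mu[j], sigma[j], log = TRUE) -
          dnorm(theta[, j], mu[j], sigma[j], log = TRUE)
        eta_prop <- eta + bl[j] * step
        dbern <- numeric(n)  # missing-z persons contribute no Bernoulli term
        dbern[obs] <- bern_ll(eta_prop[obs], zo) - bern_ll(eta[obs], zo)
        delta <- delta + dbern
        acc <- valid & is.finite(delta) & (log(runif(n)) < delta)
        if (any(acc)) {
          theta[acc, j] <- prop[acc, j]
          ll_proc[acc] <- ll_prop[acc]
          eta[acc] <- eta[acc] + bl[j] * step[acc]
        }
        if (adapting)
          ls_theta[, j] <- ls_theta[, j] + gam * (acc - accept_target)
      }

      # group-level means: conjugate Gibbs (N(0,1) hyperprior)
      for (j in seq_len(k)) {
        prec <- n / sigma[j]^2 + 1
        mn <- sum(theta[, j]) / sigma[j]^2 / prec
        mu[j] <- rnorm(1L, mn, sqrt(1 / prec))
      }

      # group-level SDs: random walk on log scale, half-normal prior
      for (j in seq_len(k)) {
        lsp <- log(sigma[j]) + exp(ls_sigma[j]) * rnorm(1L)
        sp <- exp(lsp)
        delta <- sum(dnorm(theta[, j], mu[j], sp, log = TRUE)) -
          sum(dnorm(theta[, j], mu[j], sigma[j], log = TRUE)) +
          dnorm(sp, 0, 1, log = TRUE) - dnorm(sigma[j], 0, 1, log = TRUE) +
          lsp - log(sigma[j])
        acc <- is.finite(delta) && log(runif(1L)) < delta
        if (acc) sigma[j] <- sp
        if (adapting)
          ls_sigma[j] <- ls_sigma[j] + gam * (acc - accept_target)
      }

      # translation move: shift a whole latent column and its group mean
      # together (leaves the hierarchical prior invariant), which
      # decorrelates the group means from the slowly moving ensemble
      bl <- beta[2L:(1L + k)]
      for (j in seq_len(k)) {
        dlt <- exp(ls_shift[j]) * rnorm(1L)
        prop <- theta
        prop[, j] <- theta[, j] + dlt
        if (proc$positive[j] && any(prop[, j] <= 0)) {
          acc <- FALSE
        } else {
          ll_prop <- proc$row_loglik(prop, dat)
          eta_prop <- eta + bl[j] * dlt
          delta <- sum(ll_prop - ll_proc) +
            sum(bern_ll(eta_prop[obs], zo) - bern_ll(eta[obs], zo)) +
            dnorm(mu[j] + dlt, 0, 1, log = TRUE) -
            dnorm(mu[j], 0, 1, log = TRUE)
          acc <- is.finite(delta) && log(runif(1L)) < delta
          if (acc) {
            theta <- prop
            mu[j] <- mu[j] + dlt
            ll_proc <- ll_prop
            eta <- eta_prop
          }
        }
        if (adapting)
          ls_shift[j] <- ls_shift[j] + gam * (acc - accept_target)
      }

      # scale move: rescale a latent column about its group mean together
      # with the group SD (same rationale for the spread as the
      # translation move has for the location)
      for (j in seq_len(k)) {
        cf <- exp(exp(ls_scale[j]) * rnorm(1L))
        prop <- theta
        prop[, j] <- mu[j] + cf * (theta[, j] - mu[j])
        sp <- cf * sigma[j]
        if (proc$positive[j] && any(prop[, j] <= 0)) {
          acc <- FALSE
        } else {
          ll_prop <- proc$row_loglik(prop, dat)
          eta_prop <- eta + bl[j] * (prop[, j] - theta[, j])
          # hierarchical term shifts by -n log cf; the Jacobian of the
          # (theta_j, sigma_j) map contributes (n + 1) log cf
          delta <- sum(ll_prop - ll_proc) +
            sum(bern_ll(eta_prop[obs], zo) - bern_ll(eta[obs], zo)) +
            dnorm(sp, 0, 1, log = TRUE) -
            dnorm(sigma[j], 0, 1, log = TRUE) + log(cf)
          acc <- is.finite(delta) && log(runif(1L)) < delta
          if (acc) {
            theta <- prop
            sigma[j] <- sp
            ll_proc <- ll_prop
            eta <- eta_prop
          }
        }
        if (adapting)
          ls_scale[j] <- ls_scale[j] + gam * (acc - accept_target)
      }
    }

    # structural coefficients: component-wise adaptive random walk plus a
    # joint block proposal with adapted covariance (the latent predictors
    # are uncentred, so the coefficients are strongly cross-correlated)
    eta <- eta_of()  # refresh to avoid incremental drift
    if (sweep > 100L && nb >= 10) {
      covb <- (M2b - tcrossprod(sum_b) / nb) / (nb - 1)
      ch <- tryCatch(chol(covb + diag(1e-8, p)), error = function(e) NULL)
      if (!is.null(ch)) {
        db <- exp(ls_joint) * drop(rnorm(p) %*% ch)
        eta_prop <- eta + db[1L] +
          (if (k > 0L) theta %*% db[2L:(1L + k)] else 0) +
          dat$X %*% db[(2L + k):p]
        eta_prop <- as.vector(eta_prop)
        delta <- sum(bern_ll(eta_prop[obs], zo) - bern_ll(eta[obs], zo)) +
          sum(dnorm(beta + db, 0, 1, log = TRUE) -
                dnorm(beta, 0, 1, log = TRUE))
        acc <- is.finite(delta) && log(runif(1L)) < delta
        if (acc) {
          beta <- beta + db
          eta <- eta_prop
        }
        if (adapting) ls_joint <- ls_joint + gam * (acc - 0.25)
      }
    }
    for (c in seq_len(p)) {
      w <- if (c == 1L) 1 else if (c <= 1L + k) theta[, c - 1L] else
        dat$X[, c - 1L - k]
      db <- exp(ls_beta[c]) * rnorm(1L)
      eta_prop <- eta + db * w
      delta <- sum(bern_ll(eta_prop[obs], zo) - bern_ll(eta[obs], zo)) +
        dnorm(beta[c] + db, 0, 1, log = TRUE) -
        dnorm(beta[c], 0, 1, log = TRUE)
      acc <- is.finite(delta) && log(runif(1L)) < delta
      if (acc) {
        beta[c] <- beta[c] + db
        eta <- eta_prop
      }
      if (adapting) ls_beta[c] <- ls_beta[c] + gam * (acc - accept_target)
    }
    if (adapting) {  # running moments for the joint proposal covariance
      nb <- nb + 1
      sum_b <- sum_b + beta
      M2b <- M2b + tcrossprod(beta)
    }

    if (!adapting && (sweep - warm_sweeps) %% thin == 0L) {
      kept <- kept + 1L
      row <- c(beta,
               if (k > 0L) as.vector(rbind(mu, sigma)),
               if (keep_latents && k > 0L) as.vector(theta))
      draws[kept, ] <- row
    }
  }
  draws
}
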