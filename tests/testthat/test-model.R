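# Model mathematics: learning curve, likelihoods, priors, joint posterior.

test_that("learning curve has the closed-form exponential shape", {
  expect_equal(learning_mean(learning_params(2, 1, 0.5, 1), 0), 3)
  # zero gain collapses to the asymptote at any time
  expect_equal(learning_mean(learning_params(2, 0, 0.7, 1), c(0, 3, 100)),
               rep(2, 3))
  expect_equal(learning_mean(learning_params(3, 2, 0.5, 1), 2),
               3 + 2 * exp(-1), tolerance = 1e-12)
  # strictly decreasing towards the asymptote for positive gain and rate
  p <- learning_params(2.5, 1.8, 0.4, 1)
  mm <- learning_mean(p, seq(0, 40, by = 0.5))
  expect_true(all(diff(mm) < 0))
  expect_equal(learning_mean(p, 1e6), 2.5)
})

test_that("process log likelihood sums Gaussian terms and guards eps", {
  p <- learning_params(2, 1, 0.5, 1)
  # a single observation exactly on the curve with unit SD
  expect_equal(process_loglik(learning_mean(p, 3), 3, p),
               -0.5 * log(2 * pi), tolerance = 1e-12)
  # location family: shifting data and asymptote together changes nothing
  y <- c(3.2, 2.7, 2.4); m <- 0:2
  expect_equal(process_loglik(y, m, p),
               process_loglik(y + 5, m, learning_params(7, 1, 0.5, 1)),
               tolerance = 1e-10)
  # equals the term-by-term sum
  by_term <- sum(vapply(seq_along(y), function(j)
    dnorm(y[j], 2 + 1 * exp(-0.5 * m[j]), 1, log = TRUE), numeric(1)))
  expect_equal(process_loglik(y, m, p), by_term, tolerance = 1e-12)
  expect_error(process_loglik(y, m, c(a = 2, g = 1, r = 0.5, eps = -1)),
               "positive")
})

test_that("linear predictor reproduces the published baseline log-odds", {
  expect_equal(linear_predictor(structural_coefs(), latent_group_means()),
               0)
  eta <- linear_predictor(default_coefs(), latent_group_means())
  expect_equal(eta, -1.10009064, tolerance = 1e-8)
  # additivity in any latent marker
  lat <- latent_group_means()
  lat2 <- lat; lat2["a"] <- lat["a"] + 0.3
  expect_equal(linear_predictor(default_coefs(), lat2) - eta,
               default_coefs()[["beta_a"]] * 0.3, tolerance = 1e-12)
})

test_that("MCI risk is a symmetric logistic in the linear predictor", {
  expect_equal(mci_risk(structural_coefs(), latent_group_means()), 0.5)
  # published worked example: baseline risk .25, +1 SD asymptote .37
  expect_equal(round(mci_risk(default_coefs(), latent_group_means()), 2),
               0.25)
  lat <- latent_group_means()
  lat["a"] <- 2.9533 + 0.9053
  expect_equal(round(mci_risk(default_coefs(), lat), 2), 0.37)
  # logistic symmetry under negating all coefficients
  co <- default_coefs()
  expect_equal(mci_risk(-co, latent_group_means()),
               1 - mci_risk(co, latent_group_means()), tolerance = 1e-12)
  # monotone in a for beta_a > 0, monotone decreasing in r for beta_r < 0
  risks_a <- vapply(seq(2, 4, by = 0.25), function(a) {
    l <- latent_group_means(); l["a"] <- a
    mci_risk(co, l)
  }, numeric(1))
  expect_true(all(diff(risks_a) > 0))
  risks_r <- vapply(seq(0.2, 1, by = 0.1), function(r) {
    l <- latent_group_means(); l["r"] <- r
    mci_risk(co, l)
  }, numeric(1))
  expect_true(all(diff(risks_r) < 0))
})

test_that("hierarchical prior matches per-term summation and is additive", {
  hyp <- group_hypers(mu_a = 1, mu_g = 2, mu_r = 0.5, mu_eps = 0.7)
  one <- matrix(c(1, 2, 0.5, 0.7), 1,
                dimnames = list(NULL, c("a", "g", "r", "eps")))
  expect_equal(hier_logprior(one, hyp), 4 * (-0.5 * log(2 * pi)),
               tolerance = 1e-12)
  two <- rbind(one, one)
  expect_equal(hier_logprior(two, hyp), 2 * hier_logprior(one, hyp),
               tolerance = 1e-12)
  set.seed(42)
  lat <- cbind(a = rnorm(4, 3), g = rnorm(4, 2), r = rnorm(4, 0.5),
               eps = abs(rnorm(4, 0.8, 0.3)))
  hyp <- default_hypers()
  by_term <- 0
  for (i in 1:4) for (nm in c("a", "g", "r", "eps"))
    by_term <- by_term + dnorm(lat[i, nm], hyp[[paste0("mu_", nm)]],
                               hyp[[paste0("sigma_", nm)]], log = TRUE)
  expect_equal(hier_logprior(lat, hyp), unname(by_term),
               tolerance = 1e-12)
  lat[2, "eps"] <- -0.1
  expect_equal(hier_logprior(lat, hyp), -Inf)
})

test_that("hyperprior combines normal and half-normal terms", {
  hyp <- group_hypers(sigma_a = 1e-9, sigma_g = 1e-9, sigma_r = 1e-9,
                      sigma_eps = 1e-9)
  # at the mode (means and betas 0, SDs -> 0+) the density approaches
  # 14 standard-normal log terms plus 4 half-normal log terms
  expect_equal(hyper_logprior(hyp, structural_coefs()),
               14 * dnorm(0, log = TRUE) + 4 * (dnorm(0, log = TRUE) +
                                                  log(2)),
               tolerance = 1e-6)
  # half-normal log density is the normal one plus log 2: changing one SD
  # changes the total by exactly that relation
  base <- hyper_logprior(group_hypers(), structural_coefs())
  moved <- hyper_logprior(group_hypers(sigma_a = 0.7), structural_coefs())
  expect_equal(moved - base,
               dnorm(0.7, 0, 1, log = TRUE) - dnorm(1, 0, 1, log = TRUE),
               tolerance = 1e-12)
  # arbitrary point vs term-by-term oracle
  hyp <- default_hypers(); co <- default_coefs()
  by_term <- sum(dnorm(hyp[c(1, 3, 5, 7)], 0, 1, log = TRUE)) +
    sum(dnorm(hyp[c(2, 4, 6, 8)], 0, 1, log = TRUE) + log(2)) +
    sum(dnorm(co, 0, 1, log = TRUE))
  expect_equal(hyper_logprior(hyp, co), by_term, tolerance = 1e-12)
  expect_error(group_hypers(sigma_a = -1), "positive")
})

test_that("joint log posterior decomposes into its component terms", {
  d <- toy_data()
  lat <- cbind(a = c(2.3, 3.2), g = c(0.9, 0.8), r = c(0.6, 0.4),
               eps = c(0.3, 0.35))
  hyp <- default_hypers(); co <- default_coefs()
  expect_equal(joint_log_posterior(d, lat, hyp, co),
               brute_joint_lp(d, lat, hyp, co), tolerance = 1e-10)
  # Bernoulli contribution: z = 1 at risk 1/2 adds log(1/2)
  d0 <- toy_data(z = c(NA, 0))
  d1 <- toy_data(z = c(1, 0))
  co0 <- structural_coefs()  # all-zero coefficients: every risk is 0.5
  expect_equal(joint_log_posterior(d1, lat, hyp, co0) -
                 joint_log_posterior(d0, lat, hyp, co0),
               log(0.5), tolerance = 1e-12)
  # missing z changes the total by exactly that person's Bernoulli term
  pi1 <- mci_risk(co, lat[1, , drop = FALSE], d$x[1, , drop = FALSE])
  expect_equal(joint_log_posterior(d1, lat, hyp, co) -
                 joint_log_posterior(d0, lat, hyp, co),
               log(pi1), tolerance = 1e-10)
})

test_that("joint posterior equals brute force on random small instances", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    sim <- tiny_sim(n = n, days = sample(2:5, 1), seed = rep)
    d <- sim$data
    d$z[sample(n, 1)] <- NA
    lat <- cbind(a = rnorm(n, 3, 0.5), g = rnorm(n, 1.8, 0.5),
                 r = abs(rnorm(n, 0.5, 0.2)) + 0.05,
                 eps = abs(rnorm(n, 0.7, 0.2)) + 0.05)
    hyp <- default_hypers(); co <- default_coefs()
    expect_equal(joint_log_posterior(d, lat, hyp, co),
                 brute_joint_lp(d, lat, hyp, co), tolerance = 1e-10)
  }
})
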