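# Evaluation protocol: counterfactual risk chains, stratified folds,
# AUC/ROC and the bootstrap interval.

test_that("counterfactual risk chain reproduces the published profile", {
  chain <- mci_risk_chain()
  expect_named(chain, c("baseline", "asymptote+1sd", "race_black=1",
                        "learning_rate-1sd"))
  expect_equal(round(unname(chain[1:3]), 2), c(0.25, 0.37, 0.49))
  # the shifts are cumulative: each step moves the previous profile
  expect_true(all(diff(chain) > 0))
  expect_error(mci_risk_chain(shifts = "sprint+1sd"), "unknown shift")
  # a named covariate shift equals adding its coefficient to the log-odds
  co <- default_coefs()
  one <- mci_risk_chain(shifts = "eth_hispanic=1")
  expect_equal(qlogis(one[[2]]) - qlogis(one[[1]]), co[["beta_eth"]],
               tolerance = 1e-10)
})

test_that("stratified folds balance size and class counts", {
  z <- rep(c(1, 0), c(92, 224))
  fold <- stratified_folds(z, k = 10, seed = 42)
  sizes <- tabulate(fold, 10)
  pos <- tabulate(fold[z == 1], 10)
  expect_true(all(sizes %in% 31:32))
  expect_true(all(pos %in% 9:10))
  # general invariant over random instances
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(20:200, 1); k <- sample(2:10, 1)
    zz <- rbinom(n, 1, runif(1, 0.2, 0.5))
    if (sum(zz) < 2 || sum(1 - zz) < 2) next
    f <- suppressWarnings(stratified_folds(zz, k, seed = rep))
    expect_lte(diff(range(tabulate(f, k))), 1)
    expect_lte(diff(range(tabulate(f[zz == 1] , k))), 1)
  }
  expect_identical(stratified_folds(z, 10, seed = 7),
                   stratified_folds(z, 10, seed = 7))
  expect_true(all(stratified_folds(z, 1, seed = 1) == 1))
  expect_error(stratified_folds(c(1, NA, 0), 2), "missing")
})

test_that("AUC follows the Mann-Whitney convention exactly", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.4, 6), rep(c(1, 0), 3)), 0.5)
  expect_equal(auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 3 / 4)
  # exact agreement with the brute-force pairwise oracle, ties included
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_identical(auc(scores, labels), brute_auc(scores, labels))
  }
  # invariance under strictly increasing transforms
  set.seed(5)
  sc <- runif(30); lb <- rbinom(30, 1, 0.4); lb[1:2] <- c(0, 1)
  expect_equal(auc(sc, lb), auc(qlogis(sc), lb))
  expect_equal(auc(sc, lb), auc(sc^3 + 2, lb))
  expect_error(auc(sc, rep(1, 30)), "both classes")
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (rep in 1:5) {
    sc <- round(runif(40), 2); lb <- rbinom(40, 1, 0.35)
    lb[1:2] <- c(0, 1)
    ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc(sc, lb), ref, tolerance = 1e-12)
  }
})

test_that("ROC points form the exact threshold staircase", {
  sc <- c(0.9, 0.4, 0.6, 0.1); lb <- c(1, 1, 0, 0)
  roc <- roc_points(sc, lb)
  expect_equal(roc$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(roc$tpr, c(0, 0.5, 0.5, 1, 1))
  expect_equal(attr(roc, "auc"), auc(sc, lb))
  # perfect classifier passes through (0, 1)
  rp <- roc_points(c(0.9, 0.8, 0.2), c(1, 1, 0))
  expect_true(any(rp$fpr == 0 & rp$tpr == 1))
  # trapezoidal area equals the rank AUC exactly, including ties
  set.seed(13)
  for (rep in 1:15) {
    n <- sample(5:40, 1)
    sc <- sample(seq(0, 1, 0.05), n, replace = TRUE)
    lb <- c(0, 1, rbinom(n - 2, 1, 0.3))
    r <- roc_points(sc, lb)
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
    expect_equal(attr(r, "auc"), auc(sc, lb), tolerance = 1e-12)
  }
})

test_that("bootstrap interval is stratified, ordered and consistent", {
  set.seed(8)
  n <- 120
  lb <- rbinom(n, 1, 0.3); lb[1:2] <- c(0, 1)
  sc <- plogis(qlogis(0.3) + 1.5 * lb + rnorm(n))
  ci <- bootstrap_auc_ci(sc, lb, n_boot = 500, seed = 2)
  point <- attr(ci, "auc")
  expect_lte(ci[["lower"]], point)
  expect_gte(ci[["upper"]], point)
  # a larger sample gives a narrower interval for the same process
  set.seed(8)
  n2 <- 1000
  lb2 <- rbinom(n2, 1, 0.3); lb2[1:2] <- c(0, 1)
  sc2 <- plogis(qlogis(0.3) + 1.5 * lb2 + rnorm(n2))
  ci2 <- bootstrap_auc_ci(sc2, lb2, n_boot = 500, seed = 2)
  expect_lt(diff(unname(ci2)), diff(unname(ci)))
  # perfectly separated data degenerates to [1, 1]
  ci3 <- bootstrap_auc_ci(c(rep(0.9, 50), rep(0.1, 50)),
                          rep(c(1, 0), each = 50), n_boot = 200, seed = 1)
  expect_equal(unname(ci3), c(1, 1), ignore_attr = TRUE)
  expect_error(bootstrap_auc_ci(sc, lb, n_boot = 10), ">= 100")
})

test_that("cross-validated prediction covers everyone exactly once and
           the manifest-only variant ignores the time series", {
  sim <- tiny_sim(n = 24, days = 6, seed = 15)
  d <- sim$data
  preds <- cv_risk(d, k = 4, variants = c("manifest_only"),
                   chains = 1, warmup = 50, draws = 50, thin = 1,
                   seed = 3)
  expect_setequal(preds$participant_id, d$ids)
  expect_equal(nrow(preds), 24)
  expect_true(all(preds$pi_pred > 0 & preds$pi_pred < 1))
  # permuting all response times must not change manifest-only output
  d2 <- d
  d2$y <- d$y[rev(seq_along(d$y))]
  preds2 <- cv_risk(d2, k = 4, variants = c("manifest_only"),
                    chains = 1, warmup = 50, draws = 50, thin = 1,
                    seed = 3)
  expect_equal(preds$pi_pred, preds2$pi_pred, tolerance = 1e-12)
})

test_that("cross-validation separates classes when latent effects are
           strong", {
  co <- default_coefs()
  co[c("beta_a", "beta_r")] <- 2 * co[c("beta_a", "beta_r")]
  sim <- pop_simulate(pop_sim_config(n_participants = 80, n_days = 16,
                                     coefs = co, seed = 33))
  preds <- cv_risk(sim$data, k = 4, variants = "full_pop",
                   chains = 1, warmup = 200, draws = 200, thin = 2,
                   seed = 5)
  expect_gt(mean(preds$pi_pred[preds$z_true == 1]),
            mean(preds$pi_pred[preds$z_true == 0]))
})
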