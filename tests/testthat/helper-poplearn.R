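# Shared fixtures and independent oracles, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# small synthetic cohort
tiny_sim <- function(n = 12, days = 6, seed = 1) {
  pop_simulate(pop_sim_config(n_participants = n, n_days = days,
                              seed = seed))
}

# hand-built two-person dataset with fully known numbers
toy_data <- function(z = c(1, 0)) {
  ts <- data.frame(
    participant_id = rep(c("u1", "u2"), each = 3),
    day = rep(0:2, 2),
    rt_seconds = c(3.1, 2.6, 2.4, 4.0, 3.4, 3.3))
  pp <- data.frame(
    participant_id = c("u1", "u2"),
    age_std = c(0.5, -0.5), sex_male = c(1, 0), edu_std = c(0.2, -0.1),
    race_black = c(0, 1), eth_hispanic = c(0, 0), mci = z)
  pop_data(ts, pp)
}

# independent brute-force evaluation of the joint log posterior:
# scalar loops and base density calls only, no reuse of package internals
brute_joint_lp <- function(data, lat, hypers, coefs) {
  lp <- 0
  for (i in seq_along(data$ids)) {
    y <- data$y[[i]]; tt <- data$t[[i]]
    for (j in seq_along(y)) {
      mu <- lat[i, "a"] + lat[i, "g"] * exp(-lat[i, "r"] * tt[j])
      lp <- lp + dnorm(y[j], mu, lat[i, "eps"], log = TRUE)
    }
    eta <- coefs[["beta0"]] +
      coefs[["beta_a"]] * lat[i, "a"] + coefs[["beta_g"]] * lat[i, "g"] +
      coefs[["beta_r"]] * lat[i, "r"] +
      coefs[["beta_eps"]] * lat[i, "eps"] +
      coefs[["beta_age"]] * data$x[i, "age_std"] +
      coefs[["beta_sex"]] * data$x[i, "sex_male"] +
      coefs[["beta_edu"]] * data$x[i, "edu_std"] +
      coefs[["beta_race"]] * data$x[i, "race_black"] +
      coefs[["beta_eth"]] * data$x[i, "eth_hispanic"]
    p <- 1 / (1 + exp(-eta))
    if (!is.na(data$z[i]))
      lp <- lp + ifelse(data$z[i] == 1, log(p), log(1 - p))
    for (nm in c("a", "g", "r", "eps"))
      lp <- lp + dnorm(lat[i, nm], hypers[[paste0("mu_", nm)]],
                       hypers[[paste0("sigma_", nm)]], log = TRUE)
  }
  for (nm in c("a", "g", "r", "eps")) {
    lp <- lp + dnorm(hypers[[paste0("mu_", nm)]], 0, 1, log = TRUE)
    lp <- lp + dnorm(hypers[[paste0("sigma_", nm)]], 0, 1, log = TRUE) +
      log(2)
  }
  for (b in coefs) lp <- lp + dnorm(b, 0, 1, log = TRUE)
  unname(lp)
}

# pairwise-comparison AUC oracle (Mann-Whitney with half credit for ties)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
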