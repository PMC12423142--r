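# Predictive evaluation protocol: counterfactual risk profiles, stratified
# k-fold cross-validation with held-out MCI status, ROC/AUC with a
# stratified bootstrap confidence interval, and comparator model variants.

#' Counterfactual MCI-risk chain
#'
#' Evaluates the model-implied MCI risk for a baseline profile — latent
#' markers at their group-level means, manifest covariates at zero /
#' reference (average standardized age and education, male, White,
#' non-Hispanic) — and then applies a sequence of cumulative shifts,
#' returning the risk after each step. Recognized shifts:
#' `"asymptote+1sd"`, `"asymptote-1sd"` (and likewise for `gain`,
#' `learning_rate`, `variability`, shifting that latent marker by one
#' group-level SD), and `"<covariate>=<value>"` for the five manifest
#' covariates (e.g. `"race_black=1"`).
#'
#' @param coefs structural coefficients (default [default_coefs()]).
#' @param hypers group-level hyperparameters (default [default_hypers()]).
#' @param shifts character vector of cumulative shifts; the default chain
#'   raises the asymptote by 1 SD, sets the race dummy, then lowers the
#'   learning rate by 1 SD.
#' @return Named numeric vector of risks: `baseline`, then one element per
#'   shift.
#' @examples
#' round(mci_risk_chain(), 2)
#' @export
mci_risk_chain <- function(coefs = default_coefs(),
                           hypers = default_hypers(),
                           shifts = c("asymptote+1sd", "race_black=1",
                                      "learning_rate-1sd")) {
  coefs <- check_coefs(coefs)
  hypers <- check_hypers(hypers)
  lat <- latent_group_means(hypers)
  cov <- setNames(numeric(length(COVARIATE_NAMES)), COVARIATE_NAMES)
  marker_of <- c(asymptote = "a", gain = "g", learning_rate = "r",
                 variability = "eps")
  out <- c(baseline = mci_risk(coefs, lat, cov))
  for (sh in shifts) {
    m <- regmatches(sh, regexec(
      "^(asymptote|gain|learning_rate|variability)([+-])1sd$", sh))[[1L]]
    if (length(m)) {
      l <- marker_of[[m[2L]]]
      sdv <- hypers[[paste0("sigma_", l)]]
      lat[l] <- lat[l] + if (m[3L] == "+") sdv else -sdv
    } else {
      m <- regmatches(sh, regexec("^([a-z_]+)=(-?[0-9.]+)$", sh))[[1L]]
      if (!length(m) || !(m[2L] %in% COVARIATE_NAMES))
        stop("unknown shift: '", sh, "'")
      cov[m[2L]] <- as.numeric(m[3L])
    }
    out <- c(out, setNames(mci_risk(coefs, lat, cov), sh))
  }
  out
}

#' Stratified fold assignment for cross-validation
#'
#' Participants are shuffled within outcome class and assigned to folds by
#' a single round-robin pass over the class-sorted sequence, so fold sizes
#' differ by at most one and each fold's positive count differs from an
#' even split by at most one.
#'
#' @param z binary outcome vector (no missing values).
#' @param k number of folds (`k <= length(z)`).
#' @param seed integer seed for the within-class shuffles.
#' @return Integer vector of fold indices in `1..k`, aligned with `z`.
#' @examples
#' table(stratified_folds(rep(c(0, 1), c(224, 92)), k = 10, seed = 1))
#' @export
stratified_folds <- function(z, k, seed = 1L) {
  if (anyNA(z)) stop("'z' must not contain missing values")
  if (!all(z %in% c(0, 1))) stop("'z' must be binary 0/1")
  n <- length(z)
  if (k < 1L || k > n) stop("'k' must be in 1..length(z)")
  set.seed(seed)
  if (any(tabulate(z + 1L, 2L) < k))
    warning("a class has fewer members than folds; ",
            "some folds lack that class")
  idx <- c(sample(which(z == 1)), sample(which(z == 0)))
  fold <- integer(n)
  fold[idx] <- rep_len(seq_len(k), n)
  fold
}

#' Cross-validated MCI risk prediction
#'
#' The full evaluation protocol: for each fold, the MCI status of its
#' participants is set to missing and the model refitted on the whole
#' dataset (their response-time data is retained, so their latent markers
#' are still estimated); the held-out participants' predicted risk is the
#' posterior mean of `logistic(eta)` over the refitted draws. Repeating
#' over all folds yields exactly one out-of-sample prediction per
#' participant and model variant.
#'
#' Variants: `"full_pop"` (exponential learning-curve process model +
#' manifest covariates), `"manifest_only"` (Bayesian logistic regression on
#' the covariates alone, ignoring the response-time data) and
#' `"latent_descriptors"` (process model replaced by a per-person
#' mean/SD description of the response times).
#'
#' @param data a [pop_data] object with fully observed MCI status.
#' @param k number of folds (default 10).
#' @param variants subset of
#'   `c("full_pop", "manifest_only", "latent_descriptors")`.
#' @param chains,warmup,draws,thin MCMC budget per fold refit.
#' @param seed integer seed controlling fold assignment and all refits.
#' @return Data frame with columns `participant_id`, `variant`, `fold`,
#'   `pi_pred`, `z_true`.
#' @export
cv_risk <- function(data, k = 10,
                    variants = c("full_pop", "manifest_only",
                                 "latent_descriptors"),
                    chains = 2, warmup = 300, draws = 300, thin = 3,
                    seed = 1L) {
  stopifnot(inherits(data, "pop_data"))
  variants <- match.arg(variants, several.ok = TRUE)
  if (anyNA(data$z))
    stop("cross-validation requires fully observed MCI status")
  process_of <- c(full_pop = "exponential", manifest_only = "manifest",
                  latent_descriptors = "descriptive")
  fold <- stratified_folds(data$z, k, seed = seed)
  out <- list()
  for (v in variants) {
    for (f in seq_len(k)) {
      held <- fold == f
      d <- data
      d$z[held] <- NA
      fit <- tryCatch(
        pop_fit(d, process = process_of[[v]], chains = chains,
                warmup = warmup, draws = draws, thin = thin,
                seed = as.integer(seed) + 1000L * f),
        error = function(e) stop("fold ", f, " (", v, "): ",
                                 conditionMessage(e)))
      pr <- predict(fit, type = "risk")[held]
      out[[length(out) + 1L]] <- data.frame(
        participant_id = data$ids[held], variant = v, fold = f,
        pi_pred = unname(pr), z_true = data$z[held])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive case receives a higher
#' score than a randomly chosen negative case, with ties counted half
#' (Mann-Whitney convention); equals the trapezoidal area under the ROC
#' curve.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1), same length; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have equal length")
  if (!all(labels %in% c(0, 1))) stop("'labels' must be binary 0/1")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L)
    stop("both classes must be present to compute AUC")
  rk <- rank(scores, ties.method = "average")
  (sum(rk[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve points
#'
#' True/false positive rates at every distinct score threshold (predict
#' positive when `score >= threshold`), including the (0, 0) and (1, 1)
#' endpoints. The trapezoidal area under the returned points equals
#' [auc()] exactly, including under ties.
#'
#' @inheritParams auc
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, ordered from
#'   (0, 0) to (1, 1); the trapezoidal area is attached as attribute
#'   `"auc"`.
#' @export
roc_points <- function(scores, labels) {
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L)
    stop("both classes must be present to compute a ROC curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(s) sum(scores >= s & labels == 1),
                numeric(1L)) / npos
  fpr <- vapply(thr, function(s) sum(scores >= s & labels == 0),
                numeric(1L)) / nneg
  out <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (out$fpr[nrow(out)] < 1 || out$tpr[nrow(out)] < 1)
    out <- rbind(out, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  attr(out, "auc") <- sum(diff(out$fpr) *
                            (head(out$tpr, -1) + out$tpr[-1]) / 2)
  out
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Participants are resampled with replacement within outcome class
#' (keeping both class sizes fixed) and the percentile interval of the
#' resampled AUCs is returned.
#'
#' @inheritParams auc
#' @param n_boot number of bootstrap replicates (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return Named vector `c(lower, upper)` with attributes `"auc"` (point
#'   estimate) and `"n_boot"`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 2000, level = 0.95,
                             seed = 1L) {
  if (n_boot < 100) stop("'n_boot' must be >= 100")
  point <- auc(scores, labels)  # validates inputs
  set.seed(seed)
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  stat <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    auc(scores[idx], labels[idx])
  }, numeric(1L))
  alpha <- (1 - level) / 2
  ci <- unname(quantile(stat, c(alpha, 1 - alpha), type = 7))
  structure(c(lower = ci[1L], upper = ci[2L]),
            auc = point, n_boot = n_boot)
}

#' Summarize cross-validated predictions into AUC metrics
#'
#' @param predictions output of [cv_risk()].
#' @param n_boot,level,seed bootstrap settings, see [bootstrap_auc_ci()].
#' @return Data frame with one row per variant: `variant`, `auc`,
#'   `ci_lower`, `ci_upper`, `n_boot`.
#' @export
cv_metrics <- function(predictions, n_boot = 2000, level = 0.95,
                       seed = 1L) {
  rows <- lapply(split(predictions, predictions$variant), function(p) {
    ci <- bootstrap_auc_ci(p$pi_pred, p$z_true, n_boot = n_boot,
                           level = level, seed = seed)
    data.frame(variant = p$variant[1L], auc = attr(ci, "auc"),
               ci_lower = unname(ci["lower"]),
               ci_upper = unname(ci["upper"]), n_boot = n_boot)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
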