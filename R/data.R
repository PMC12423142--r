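# Dataset container and CSV input/output.
#
# A pop_data object holds, per participant: the response-time series (daily
# means and measurement days), the five manifest covariates, and the MCI
# status (0/1 or NA when unknown / held out).

#' Assemble a POP-model dataset
#'
#' Combine a long-format response-time table with a participant-level
#' covariate table into the validated dataset consumed by [pop_fit()].
#'
#' @param timeseries data frame with columns `participant_id`, `day`
#'   (days since the participant's first assessment, non-decreasing within
#'   participant) and `rt_seconds` (positive daily mean response time).
#' @param participants data frame with columns `participant_id`, `age_std`,
#'   `sex_male`, `edu_std`, `race_black`, `eth_hispanic` and `mci` (0, 1 or
#'   `NA` for unknown status). One row per participant.
#' @return An object of class `pop_data`: a list with elements `ids`
#'   (participant labels), `y` and `t` (lists of response-time and
#'   measurement-day vectors), `x` (covariate matrix) and `z` (MCI status
#'   vector with `NA` for missing).
#' @examples
#' sim <- pop_simulate(pop_sim_config(n_participants = 8, n_days = 5,
#'                                    seed = 1))
#' d <- sim$data
#' length(d$ids)
#' @export
pop_data <- function(timeseries, participants) {
  req_ts <- c("participant_id", "day", "rt_seconds")
  req_pp <- c("participant_id", COVARIATE_NAMES, "mci")
  if (!all(req_ts %in% names(timeseries)))
    stop("'timeseries' must have columns ", paste(req_ts, collapse = ", "))
  if (!all(req_pp %in% names(participants)))
    stop("'participants' must have columns ", paste(req_pp, collapse = ", "))
  ids <- as.character(participants$participant_id)
  if (anyDuplicated(ids))
    stop("duplicated participant ids in 'participants'")
  ts_ids <- as.character(timeseries$participant_id)
  only_ts <- setdiff(unique(ts_ids), ids)
  only_pp <- setdiff(ids, unique(ts_ids))
  if (length(only_ts) || length(only_pp))
    stop("participant ids do not match across tables: ",
         paste(c(only_ts, only_pp), collapse = ", "))
  rt <- timeseries$rt_seconds
  if (!is.numeric(rt) || anyNA(rt))
    stop("non-numeric or missing 'rt_seconds' at row(s) ",
         paste(head(which(!is.finite(suppressWarnings(as.numeric(rt)))), 5),
               collapse = ", "))
  if (any(rt <= 0)) stop("'rt_seconds' must be positive")
  if (!is.numeric(timeseries$day) || any(timeseries$day < 0))
    stop("'day' must be non-negative")
  ord <- order(match(ts_ids, ids), timeseries$day)
  ts_ids <- ts_ids[ord]
  day <- timeseries$day[ord]
  rt <- rt[ord]
  y <- split(rt, factor(ts_ids, levels = ids))
  t <- split(day, factor(ts_ids, levels = ids))
  if (any(lengths(y) < 1L)) stop("every participant needs >= 1 observation")
  x <- as_covariate_matrix(participants)
  z <- participants$mci
  if (!all(z[!is.na(z)] %in% c(0, 1)))
    stop("'mci' must be 0, 1 or NA")
  structure(list(ids = ids, y = unname(y), t = unname(t), x = x,
                 z = as.numeric(z)),
            class = "pop_data")
}

#' @export
print.pop_data <- function(x, ...) {
  nobs <- sum(lengths(x$y))
  obs <- !is.na(x$z)
  cat("POP-model dataset:", length(x$ids), "participants,",
      nobs, "daily observations\n")
  cat("  MCI status observed for", sum(obs), "participants",
      sprintf("(prevalence %.1f%%)", 100 * mean(x$z[obs])), "\n")
  if (any(!obs)) cat("  missing MCI status:", sum(!obs), "\n")
  invisible(x)
}

#' Convert a dataset back to its two data frames
#'
#' @param data a `pop_data` object.
#' @return List with data frames `timeseries` and `participants`, in the
#'   column layout accepted by [pop_data()].
#' @export
as_pop_tables <- function(data) {
  stopifnot(inherits(data, "pop_data"))
  timeseries <- data.frame(
    participant_id = rep(data$ids, lengths(data$y)),
    day = unlist(data$t),
    rt_seconds = unlist(data$y))
  participants <- data.frame(participant_id = data$ids, data$x,
                             mci = data$z)
  rownames(timeseries) <- rownames(participants) <- NULL
  list(timeseries = timeseries, participants = participants)
}

#' Read a POP-model dataset from CSV files
#'
#' Missing MCI status is encoded as an empty cell (or `NA`) in the `mci`
#' column.
#'
#' @param timeseries_path CSV with columns `participant_id,day,rt_seconds`.
#' @param participants_path CSV with columns
#'   `participant_id,age_std,sex_male,edu_std,race_black,eth_hispanic,mci`.
#' @return A validated [pop_data] object.
#' @export
read_pop_data <- function(timeseries_path, participants_path) {
  ts <- read.csv(timeseries_path, stringsAsFactors = FALSE)
  pp <- read.csv(participants_path, stringsAsFactors = FALSE)
  if (!is.numeric(ts$rt_seconds)) {
    bad <- which(is.na(suppressWarnings(as.numeric(ts$rt_seconds))))
    stop("non-numeric 'rt_seconds' at row(s) ",
         paste(head(bad, 5), collapse = ", "), " of ", timeseries_path)
  }
  pop_data(ts, pp)
}

#' Write a POP-model dataset to CSV files
#'
#' @param data a `pop_data` object.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths of `timeseries.csv` and `participants.csv`.
#' @export
write_pop_data <- function(data, dir) {
  tabs <- as_pop_tables(data)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("timeseries.csv", "participants.csv"))
  write.csv(tabs$timeseries, paths[1], row.names = FALSE, na = "")
  write.csv(tabs$participants, paths[2], row.names = FALSE, na = "")
  invisible(paths)
}
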