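# Two-group cure-mixture cohort simulator: a cured fraction that never has the
# event, log-normal diagnosis times among the susceptible with group-specific
# medians, uniform loss-to-follow-up censoring, and administrative cutoffs.

stop_config <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' Define a simulation scenario
#'
#' A scenario bundles every parameter of the two-group data-generating
#' process: cohort size, group split, the susceptible (event) rate shared by
#' both groups, the per-group median diagnosis times of the log-normal event
#' time distribution, the log-scale standard deviation, the upper bound of the
#' uniform loss-to-follow-up distribution, a grid of administrative censoring
#' cutoffs, the replicate count and the root seed.
#'
#' The event-time distribution for susceptible subjects in group \eqn{g} is
#' log-normal with location \eqn{\mu_g = \log(\mathrm{median}_g)}, so the
#' configured medians are exact distributional medians. Cured subjects never
#' experience the event (event time \code{+Inf}).
#'
#' @param n_subjects Number of subjects per replicate.
#' @param group_fraction Proportion assigned to group 1, in (0, 1).
#' @param event_rate Proportion susceptible (the true diagnosis probability),
#'   in (0, 1); identical across groups so any between-group difference in
#'   model estimates is bias.
#' @param median_time_g1,median_time_g2 Median diagnosis time (time units,
#'   e.g. years) among susceptible subjects in group 1 / group 2;
#'   `median_time_g2 >= median_time_g1` (equal medians give the null
#'   scenario).
#' @param log_scale_sigma Standard deviation of log event time (> 0).
#' @param censor_upper Upper bound of the uniform(0, `censor_upper`)
#'   loss-to-follow-up censoring distribution.
#' @param admin_censor_times Strictly increasing vector of administrative
#'   cutoff times.
#' @param n_replicates Number of replicates the scenario supports.
#' @param seed Root seed; each replicate draws from a substream derived from
#'   it, so a replicate is fully reproducible from `(seed, replicate_index)`.
#' @param group_assignment `"interleave"` (exact deterministic split, the
#'   default, so group sizes carry no replicate-to-replicate variance) or
#'   `"bernoulli"`.
#' @return An object of class `scenario_config`.
#' @export
#' @examples
#' cfg <- scenario_config(n_subjects = 1000, event_rate = 0.25)
#' cohort <- generate_cohort(cfg, replicate_index = 0)
#' summarize_cohort(cohort)$event_rate
scenario_config <- function(n_subjects = 10000L,
                            group_fraction = 0.5,
                            event_rate = 0.25,
                            median_time_g1 = 4,
                            median_time_g2 = 4,
                            log_scale_sigma = 0.5,
                            censor_upper = 12,
                            admin_censor_times = c(4, 6, 8, 10, 12),
                            n_replicates = 100L,
                            seed = 20260101L,
                            group_assignment = c("interleave", "bernoulli")) {
  group_assignment <- match.arg(group_assignment)
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L ||
      !is.finite(n_subjects) || n_subjects < 1 || n_subjects != round(n_subjects))
    stop_config("n_subjects", "must be a positive integer")
  if (!is.numeric(group_fraction) || length(group_fraction) != 1L ||
      group_fraction <= 0 || group_fraction >= 1)
    stop_config("group_fraction", "must lie strictly between 0 and 1")
  if (!is.numeric(event_rate) || length(event_rate) != 1L ||
      event_rate <= 0 || event_rate >= 1)
    stop_config("event_rate", "must lie strictly between 0 and 1")
  if (!is.numeric(median_time_g1) || length(median_time_g1) != 1L ||
      !is.finite(median_time_g1) || median_time_g1 <= 0)
    stop_config("median_time_g1", "must be a positive number")
  if (!is.numeric(median_time_g2) || length(median_time_g2) != 1L ||
      !is.finite(median_time_g2) || median_time_g2 <= 0)
    stop_config("median_time_g2", "must be a positive number")
  if (median_time_g2 < median_time_g1)
    stop_config("median_time_g2", "must be >= median_time_g1")
  if (!is.numeric(log_scale_sigma) || length(log_scale_sigma) != 1L ||
      !is.finite(log_scale_sigma) || log_scale_sigma <= 0)
    stop_config("log_scale_sigma", "must be a positive number")
  if (!is.numeric(censor_upper) || length(censor_upper) != 1L ||
      !is.finite(censor_upper) || censor_upper <= 0)
    stop_config("censor_upper", "must be a positive number")
  if (!is.numeric(admin_censor_times) || length(admin_censor_times) < 1L ||
      any(!is.finite(admin_censor_times)) || any(admin_censor_times <= 0))
    stop_config("admin_censor_times", "must be positive numbers")
  if (is.unsorted(admin_censor_times, strictly = TRUE))
    stop_config("admin_censor_times", "must be strictly increasing")
  if (!is.numeric(n_replicates) || length(n_replicates) != 1L ||
      !is.finite(n_replicates) || n_replicates < 1 ||
      n_replicates != round(n_replicates))
    stop_config("n_replicates", "must be a positive integer")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed))
    stop_config("seed", "must be an integer")

  structure(
    list(n_subjects = as.integer(n_subjects),
         group_fraction = group_fraction,
         event_rate = event_rate,
         median_time_g1 = median_time_g1,
         median_time_g2 = median_time_g2,
         log_scale_sigma = log_scale_sigma,
         censor_upper = censor_upper,
         admin_censor_times = as.numeric(admin_censor_times),
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed),
         group_assignment = group_assignment),
    class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Simulation scenario\n")
  cat(sprintf("  n = %d, group 1 fraction = %g (%s assignment)\n",
              x$n_subjects, x$group_fraction, x$group_assignment))
  cat(sprintf("  event rate = %g (cured fraction %g)\n",
              x$event_rate, 1 - x$event_rate))
  cat(sprintf("  median diagnosis time: group 1 = %g, group 2 = %g (log-sd %g)\n",
              x$median_time_g1, x$median_time_g2, x$log_scale_sigma))
  cat(sprintf("  censoring ~ U(0, %g); admin cutoffs: %s\n",
              x$censor_upper, paste(x$admin_censor_times, collapse = ", ")))
  cat(sprintf("  %d replicates, seed %d\n", x$n_replicates, x$seed))
  invisible(x)
}

cohort_columns <- c("subject_id", "group", "susceptible", "true_event_time",
                    "censor_time", "observed_time", "event")

assert_cohort <- function(cohort) {
  if (!is.data.frame(cohort))
    stop("`cohort` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(cohort) == 0L)
    stop("cohort is empty", call. = FALSE)
  invisible(cohort)
}

replicate_seed <- function(config, replicate_index) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$n_replicates)
  seeds[replicate_index + 1L]
}

#' Generate one replicate cohort under a scenario
#'
#' Draws a subject-level table: group assignment, latent susceptibility
#' (Bernoulli with the configured event rate), log-normal diagnosis times for
#' the susceptible (cured subjects get `+Inf`), uniform censoring times, and
#' the resulting observed follow-up `min(true_event_time, censor_time)` with
#' its event indicator. The latent columns (`susceptible`, `true_event_time`,
#' `censor_time`) are retained for oracle checks; analysis functions only use
#' `observed_time`, `event` and covariates.
#'
#' @param config A [scenario_config()].
#' @param replicate_index Zero-based replicate number in
#'   `[0, config$n_replicates)`. Each replicate uses its own RNG substream
#'   derived from the root seed, so the same `(seed, replicate_index)` always
#'   yields the identical table.
#' @return A data frame of class `cure_cohort` with `n_subjects` rows and
#'   columns `subject_id`, `group`, `susceptible`, `true_event_time`,
#'   `censor_time`, `observed_time`, `event`, carrying the config, replicate
#'   index and substream seed as attributes.
#' @export
generate_cohort <- function(config, replicate_index = 0L) {
  if (!inherits(config, "scenario_config"))
    stop("`config` must be created by scenario_config()", call. = FALSE)
  if (!is.numeric(replicate_index) || length(replicate_index) != 1L ||
      replicate_index != round(replicate_index) ||
      replicate_index < 0 || replicate_index >= config$n_replicates)
    stop_config("replicate_index",
                sprintf("must be an integer in [0, %d)", config$n_replicates))

  rseed <- replicate_seed(config, replicate_index)
  set.seed(rseed)
  n <- config$n_subjects
  idx <- seq_len(n)

  group <- if (config$group_assignment == "interleave") {
    # Bresenham-style interleaving: exactly floor(n * fraction) group-1
    # subjects, evenly spread through the id sequence.
    f <- config$group_fraction
    ifelse(floor(idx * f) - floor((idx - 1) * f) >= 1, 1L, 2L)
  } else {
    ifelse(stats::runif(n) < config$group_fraction, 1L, 2L)
  }

  susceptible <- stats::runif(n) < config$event_rate
  meanlog <- log(ifelse(group == 1L, config$median_time_g1,
                        config$median_time_g2))
  raw_time <- stats::rlnorm(n, meanlog = meanlog,
                            sdlog = config$log_scale_sigma)
  true_event_time <- ifelse(susceptible, raw_time, Inf)
  censor_time <- stats::runif(n, 0, config$censor_upper)
  observed_time <- pmin(true_event_time, censor_time)
  event <- as.integer(true_event_time <= censor_time)

  out <- data.frame(subject_id = idx,
                    group = group,
                    susceptible = susceptible,
                    true_event_time = true_event_time,
                    censor_time = censor_time,
                    observed_time = observed_time,
                    event = event)
  attr(out, "config") <- config
  attr(out, "replicate_index") <- as.integer(replicate_index)
  attr(out, "replicate_seed") <- rseed
  class(out) <- c("cure_cohort", "data.frame")
  out
}

#' Apply an administrative censoring cutoff
#'
#' Truncates every subject's follow-up at `cutoff`: observed times are capped
#' at the cutoff and events occurring after it are recoded as censored. The
#' operation is idempotent once `cutoff` exceeds the maximum observed time,
#' and applying two cutoffs in sequence equals applying their minimum.
#'
#' @param cohort A cohort table (see [generate_cohort()]).
#' @param cutoff Positive administrative censoring time.
#' @return The truncated cohort; the effective cutoff (minimum of all cutoffs
#'   applied so far) is recorded in the `admin_cutoff` attribute.
#' @export
apply_admin_censoring <- function(cohort, cutoff) {
  assert_cohort(cohort)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff) ||
      cutoff <= 0)
    stop("`cutoff` must be a single positive number", call. = FALSE)
  out <- cohort
  out$event <- as.integer(cohort$event == 1L & cohort$observed_time <= cutoff)
  out$observed_time <- pmin(cohort$observed_time, cutoff)
  prev <- attr(cohort, "admin_cutoff")
  attr(out, "admin_cutoff") <- if (is.null(prev)) cutoff else min(prev, cutoff)
  out
}

#' Summarise a cohort
#'
#' @param cohort A cohort table.
#' @return A list: `n`, `n_by_group`, `event_rate`, `event_rate_by_group`,
#'   `censoring_rate` and `median_observed_time`. Per-group event rates
#'   weighted by group size average to the overall rate.
#' @export
summarize_cohort <- function(cohort) {
  assert_cohort(cohort)
  groups <- sort(unique(cohort$group))
  n_by_group <- vapply(groups, function(g) sum(cohort$group == g), integer(1))
  rate_by_group <- vapply(groups,
                          function(g) mean(cohort$event[cohort$group == g]),
                          numeric(1))
  names(n_by_group) <- names(rate_by_group) <- paste0("group", groups)
  list(n = nrow(cohort),
       n_by_group = n_by_group,
       event_rate = mean(cohort$event),
       event_rate_by_group = rate_by_group,
       censoring_rate = 1 - mean(cohort$event),
       median_observed_time = stats::median(cohort$observed_time))
}

#' Read / write cohort tables as CSV
#'
#' Cured subjects (infinite `true_event_time`) are serialised with an empty
#' `true_event_time` field and restored to `+Inf` on reading. `write_cohort`
#' optionally writes a JSON sidecar (`<path>.json`) with the scenario echo,
#' seed, replicate index and package version.
#'
#' @param cohort A cohort table.
#' @param path CSV file path.
#' @param metadata Write the JSON sidecar? Default `TRUE` when the cohort
#'   carries a scenario config.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   cohort data frame.
#' @export
write_cohort <- function(cohort, path, metadata = TRUE) {
  assert_cohort(cohort)
  out <- as.data.frame(cohort)[, cohort_columns]
  out$true_event_time[!is.finite(out$true_event_time)] <- NA_real_
  utils::write.csv(out, path, row.names = FALSE, na = "")
  cfg <- attr(cohort, "config")
  if (isTRUE(metadata) && !is.null(cfg)) {
    meta <- list(config = unclass(cfg),
                 replicate_index = attr(cohort, "replicate_index"),
                 replicate_seed = attr(cohort, "replicate_seed"),
                 admin_cutoff = attr(cohort, "admin_cutoff"),
                 package_version = as.character(utils::packageVersion("cureaudit")))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("true_event_time" %in% names(out))
    out$true_event_time[is.na(out$true_event_time)] <- Inf
  if ("susceptible" %in% names(out))
    out$susceptible <- as.logical(out$susceptible)
  assert_cohort(out)
  class(out) <- c("cure_cohort", "data.frame")
  out
}

#' Read / write a scenario configuration as YAML
#'
#' @param path YAML file path; keys map 1:1 to [scenario_config()] arguments.
#' @param config A `scenario_config` object.
#' @return `read_scenario_config` returns a validated `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  do.call(scenario_config, yaml::read_yaml(path))
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(config, path) {
  if (!inherits(config, "scenario_config"))
    stop("`config` must be a scenario_config", call. = FALSE)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
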