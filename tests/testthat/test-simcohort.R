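test_that("scenario validation names the offending field", {
  expect_error(scenario_config(n_subjects = 0), "n_subjects")
  expect_error(scenario_config(event_rate = 1), "event_rate")
  expect_error(scenario_config(group_fraction = 0), "group_fraction")
  expect_error(scenario_config(median_time_g1 = -4), "median_time_g1")
  expect_error(scenario_config(median_time_g1 = 5, median_time_g2 = 4),
               "median_time_g2")
  expect_error(scenario_config(log_scale_sigma = 0), "log_scale_sigma")
  expect_error(scenario_config(admin_censor_times = c(4, 4)),
               "admin_censor_times")
  expect_error(generate_cohort(test_config(), replicate_index = 99),
               "replicate_index")
})

test_that("generated cohorts satisfy the structural invariants", {
  cfg <- test_config()
  for (r in c(0L, 3L)) {
    coh <- generate_cohort(cfg, r)
    expect_equal(nrow(coh), cfg$n_subjects)
    expect_true(all(coh$observed_time > 0))
    expect_equal(coh$observed_time, pmin(coh$true_event_time,
                                         coh$censor_time))
    expect_equal(coh$event,
                 as.integer(coh$true_event_time <= coh$censor_time))
    # cured subjects never have the event
    expect_true(all(coh$event[!coh$susceptible] == 0))
    expect_true(all(is.infinite(coh$true_event_time[!coh$susceptible])))
  }
})

test_that("identical (seed, replicate) reproduces the cohort; replicates differ", {
  cfg <- test_config()
  expect_identical(generate_cohort(cfg, 2L), generate_cohort(cfg, 2L))
  expect_false(identical(generate_cohort(cfg, 0L)$observed_time,
                         generate_cohort(cfg, 1L)$observed_time))
})

test_that("susceptible fraction and group split match the configuration", {
  cfg <- test_config(n_subjects = 10000L)
  coh <- generate_cohort(cfg, 0L)
  # binomial sampling error band around the configured event rate
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(mean(coh$susceptible) - 0.25), 3 * se)
  # deterministic interleaving gives an exact 50/50 split
  expect_equal(unname(table(coh$group)), c(5000L, 5000L),
               ignore_attr = TRUE)

  # empirical medians of susceptible event times track the configured medians
  cfg2 <- test_config(n_subjects = 10000L, median_time_g2 = 10)
  coh2 <- generate_cohort(cfg2, 0L)
  m1 <- median(coh2$true_event_time[coh2$susceptible & coh2$group == 1])
  m2 <- median(coh2$true_event_time[coh2$susceptible & coh2$group == 2])
  expect_lt(abs(m1 - 4), 0.3)
  expect_lt(abs(m2 - 10), 0.8)
})

test_that("no-cure limit: every subject eventually has the event", {
  cfg <- scenario_config(n_subjects = 500, event_rate = 1 - 1e-12,
                         censor_upper = 1e6, admin_censor_times = 1e5,
                         n_replicates = 2, seed = 5)
  coh <- apply_admin_censoring(generate_cohort(cfg, 0L), 1e5)
  expect_true(all(coh$event == 1L))
})

test_that("administrative censoring follows the min/indicator rule", {
  one <- make_cohort(time = 5, event = 1)
  one$censor_time <- 9
  at4 <- apply_admin_censoring(one, 4)
  expect_equal(at4$observed_time, 4)
  expect_equal(at4$event, 0L)
  at6 <- apply_admin_censoring(one, 6)
  expect_equal(at6$observed_time, 5)
  expect_equal(at6$event, 1L)

  expect_error(apply_admin_censoring(one, 0), "positive")
  expect_error(apply_admin_censoring(one, -1), "positive")
})

test_that("censoring is idempotent, composable, and degenerate at 0+", {
  coh <- generate_cohort(test_config(n_subjects = 500), 0L)
  # no-op when the cutoff exceeds all observed times
  far <- apply_admin_censoring(coh, max(coh$observed_time) + 1)
  expect_equal(far$observed_time, coh$observed_time)
  expect_equal(far$event, coh$event)
  # composition equals the minimum cutoff
  ab <- apply_admin_censoring(apply_admin_censoring(coh, 6), 3)
  ba <- apply_admin_censoring(apply_admin_censoring(coh, 3), 6)
  m <- apply_admin_censoring(coh, 3)
  expect_equal(ab$observed_time, m$observed_time)
  expect_equal(ab$event, m$event)
  expect_equal(ba$observed_time, m$observed_time)
  expect_equal(ba$event, m$event)
  # near-zero cutoff censors everyone
  tiny <- apply_admin_censoring(coh, 1e-9)
  expect_true(all(tiny$event == 0L))
  expect_true(all(tiny$observed_time > 0))
})

test_that("cohort summaries are consistent", {
  allev <- make_cohort(time = c(1, 2, 3), event = c(1, 1, 1),
                       group = c(1, 2, 1))
  expect_equal(summarize_cohort(allev)$event_rate, 1)

  coh <- generate_cohort(test_config(n_subjects = 4000), 1L)
  s <- summarize_cohort(coh)
  expect_true(s$event_rate >= 0 && s$event_rate <= 1)
  # per-group rates weighted by group sizes average to the overall rate
  expect_equal(sum(s$event_rate_by_group * s$n_by_group) / s$n,
               s$event_rate)
  expect_equal(s$censoring_rate, 1 - s$event_rate)
  expect_error(summarize_cohort(coh[0, ]), "empty")
})

test_that("event rate under generous follow-up approaches the configured rate", {
  cfg <- test_config(n_subjects = 10000L, censor_upper = 200,
                     admin_censor_times = c(50, 100))
  coh <- apply_admin_censoring(generate_cohort(cfg, 0L), 100)
  expect_lt(abs(summarize_cohort(coh)$event_rate - 0.25),
            3 * sqrt(0.25 * 0.75 / 10000) + 0.005)
})

test_that("cohort CSV round-trips, with Inf serialised as empty", {
  coh <- generate_cohort(test_config(n_subjects = 50), 0L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  raw <- readLines(path, n = 2)
  expect_match(raw[1], "true_event_time")
  back <- read_cohort(path)
  expect_equal(back$true_event_time, coh$true_event_time)
  expect_equal(back$observed_time, coh$observed_time)
  expect_equal(back$event, coh$event)
  # metadata sidecar
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$config$n_subjects, 50)
  expect_equal(meta$replicate_index, 0)
})

test_that("scenario YAML round-trips", {
  cfg <- test_config(median_time_g2 = 7)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(cfg, path)
  expect_equal(read_scenario_config(path), cfg)
})

test_that("group KM curves diverge at intermediate times but converge in the tail", {
  cfg <- scenario_config(n_subjects = 10000, median_time_g2 = 10,
                         censor_upper = 100, admin_censor_times = 60,
                         n_replicates = 2, seed = 11)
  coh <- generate_cohort(cfg, 0L)
  km <- kaplan_meier(coh, by_group = TRUE)
  surv_at <- function(g, t) {
    k <- km[km$group == g & km$time <= t, ]
    k$survival[nrow(k)]
  }
  # divergence around the faster group's median
  expect_gt(surv_at(2, 5) - surv_at(1, 5), 0.05)
  # convergence toward the same cure plateau 1 - event_rate
  expect_lt(abs(surv_at(1, 50) - 0.75), 0.02)
  expect_lt(abs(surv_at(2, 50) - 0.75), 0.02)
  expect_lt(abs(surv_at(1, 50) - surv_at(2, 50)), 0.02)
})
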