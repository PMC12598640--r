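# Shared fixtures: all generated in code, no files.

# Small-but-informative default scenario for unit tests.
test_config <- function(n_subjects = 2000L, seed = 20260101L, ...) {
  scenario_config(n_subjects = n_subjects, n_replicates = 20L, seed = seed,
                  ...)
}

# Hand-built cohort table from observed times and event flags (latent columns
# filled consistently: events have true time = observed, censored subjects
# are marked cured with censor time = observed).
make_cohort <- function(time, event, group = rep(1L, length(time))) {
  data.frame(subject_id = seq_along(time),
             group = as.integer(group),
             susceptible = event == 1L,
             true_event_time = ifelse(event == 1L, time, Inf),
             censor_time = ifelse(event == 1L, time * 2, time),
             observed_time = time,
             event = as.integer(event))
}

# Central-difference numerical gradient.
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# Independently coded censored log-normal AFT log-likelihood (the oracle for
# the pi == 1 reduction identity; deliberately written from the density/CDF,
# not via cure_loglik).
aft_lognormal_loglik <- function(beta, sigma, cohort, covariates = "group") {
  X <- model.matrix(reformulate(covariates), data = cohort)
  mu <- drop(X %*% beta)
  t <- cohort$observed_time
  sum(ifelse(cohort$event == 1,
             dlnorm(t, meanlog = mu, sdlog = sigma, log = TRUE),
             plnorm(t, meanlog = mu, sdlog = sigma, lower.tail = FALSE,
                    log.p = TRUE)))
}
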