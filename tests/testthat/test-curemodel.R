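test_that("population survival reduces correctly in the limits", {
  coh <- generate_cohort(test_config(), 0L)
  cc <- apply_admin_censoring(coh, 8)
  fit <- suppressWarnings(fit_mixture_cure(cc))
  nd <- data.frame(group = 2)

  # pinned incidence limits via hand-built fits
  lim <- fit
  lim$gamma <- c(-40, 0)           # pi -> 0: all cured, Spop == 1
  expect_equal(population_survival(lim, nd, c(1, 5, 50)), rep(1, 3),
               tolerance = 1e-10)
  lim$gamma <- c(40, 0)            # pi -> 1: plain log-normal survival
  mu <- sum(lim$beta * c(1, 2))
  expect_equal(population_survival(lim, nd, 5),
               1 - plnorm(5, mu, lim$sigma), tolerance = 1e-8)

  # monotone nonincreasing in t, plateau at the cure fraction 1 - pi(z)
  ts <- c(0.1, 0.5, 1, 2, 4, 8, 16, 1e6)
  s <- population_survival(fit, nd, ts)
  expect_true(all(diff(s) <= 1e-12))
  pi2 <- predict_incidence(fit, nd)
  expect_true(all(s >= 1 - pi2 - 1e-12))
  expect_equal(s[length(s)], 1 - pi2, tolerance = 1e-6)

  expect_error(population_survival(fit, nd, -1), "positive")
})

test_that("log-likelihood matches hand-computed censored and event terms", {
  d <- cure_design(character(0), character(0))  # intercept-only
  # single censored subject with pi = 0.5 and S(t) = 0.8:
  # contribution log(0.5 + 0.5 * 0.8) = log(0.9)
  t0 <- 2
  sigma <- 0.7
  # choose beta so that S(t0) = 0.8 under the log-normal latency
  beta <- log(t0) - sigma * qnorm(0.2)
  one_cens <- make_cohort(time = t0, event = 0)
  expect_equal(cure_loglik(c(qlogis(0.5), beta, log(sigma)), one_cens, d),
               log(0.9), tolerance = 1e-10)

  # single event subject: log pi + log-normal log-density
  one_ev <- make_cohort(time = t0, event = 1)
  expect_equal(cure_loglik(c(qlogis(0.3), beta, log(sigma)), one_ev, d),
               log(0.3) + dlnorm(t0, beta, sigma, log = TRUE),
               tolerance = 1e-10)

  # an event when pi is numerically zero: guarded large negative, not NaN
  ll0 <- cure_loglik(c(-800, beta, log(sigma)), one_ev, d)
  expect_true(is.finite(ll0))
  expect_lt(ll0, -500)

  expect_error(cure_loglik(c(0, 0, 0), make_cohort(time = -1, event = 0), d),
               "positive")
})

test_that("with the incidence pinned to 1 the model reduces to a censored log-normal AFT", {
  coh <- apply_admin_censoring(generate_cohort(test_config(), 1L), 8)
  d <- cure_design("group")
  sr <- survival::survreg(
    survival::Surv(observed_time, event) ~ group, data = coh,
    dist = "lognormal")

  # (a) cure_loglik at pinned pi equals an independently coded AFT loglik
  params <- c(500, 0, coef(sr), log(sr$scale))
  expect_equal(cure_loglik(params, coh, d),
               aft_lognormal_loglik(coef(sr), sr$scale, coh),
               tolerance = 1e-8)
  # (b) ... and equals survreg's maximised log-likelihood (independent code)
  expect_equal(cure_loglik(params, coh, d), as.numeric(logLik(sr)),
               tolerance = 1e-4 * abs(as.numeric(logLik(sr))))
})

test_that("analytic gradient matches central finite differences", {
  coh <- apply_admin_censoring(generate_cohort(test_config(n_subjects = 300), 2L), 8)
  d <- cure_design("group")
  set.seed(99)
  for (i in 1:5) {
    p <- c(rnorm(2, 0, 1), rnorm(2, 1, 0.5), rnorm(1, log(0.5), 0.3))
    ga <- cure_loglik_grad(p, coh, d)
    gn <- num_grad(function(x) cure_loglik(x, coh, d), p)
    expect_lt(max(abs(ga - gn) / pmax(1, abs(gn))), 1e-5)
  }
})

test_that("tiny-data optimum matches a brute-force grid search", {
  set.seed(4)
  d <- cure_design(character(0), character(0))
  n <- 30
  susceptible <- runif(n) < 0.5
  tt <- ifelse(susceptible, rlnorm(n, log(3), 0.5), Inf)
  cens <- runif(n, 0, 10)
  coh <- make_cohort(time = pmin(tt, cens), event = as.integer(tt <= cens))

  fit <- suppressWarnings(fit_mixture_cure(coh, d))
  # coarse 3-D lattice over (gamma0, beta0, log sigma)
  grid <- expand.grid(g = seq(-2, 2, by = 0.1),
                      b = seq(0, 2.5, by = 0.05),
                      ls = seq(-1.5, 0.5, by = 0.05))
  lls <- mapply(function(g, b, ls) cure_loglik(c(g, b, ls), coh, d),
                grid$g, grid$b, grid$ls)
  best <- grid[which.max(lls), ]
  # the optimizer is at least as good as the lattice, and close to its argmax
  expect_gte(fit$loglik, max(lls) - 1e-9)
  expect_lt(fit$loglik - max(lls), 0.05)
  expect_lt(abs(fit$gamma[1] - best$g), 0.1 + 1e-9)
  expect_lt(abs(fit$beta[1] - best$b), 0.05 + 1e-9)
  expect_lt(abs(fit$log_sigma - best$ls), 0.05 + 1e-9)
})

test_that("parameters are recovered within 3 SEs under generous follow-up", {
  # truth: gamma = (logit link), beta, sigma from the generator; group is
  # coded 1/2 so gamma0 + gamma1 * g = logit(0.25) for both groups
  cfg <- scenario_config(n_subjects = 10000, median_time_g2 = 7,
                         censor_upper = 60, admin_censor_times = 40,
                         n_replicates = 2, seed = 77)
  coh <- generate_cohort(cfg, 0L)
  fit <- fit_mixture_cure(coh)
  expect_true(fit$converged)
  truth <- c(qlogis(0.25), 0,                    # incidence
             log(4) + (log(4) - log(7)), log(7) - log(4),  # latency on 1/2
             log(0.5))
  se <- sqrt(diag(fit$covariance))
  expect_true(all(abs(fit$par - truth) <= 3 * se))

  # predicted incidence near the true event rate in both groups
  pi <- predict_incidence(fit, data.frame(group = c(1, 2)))
  expect_lt(max(abs(pi - 0.25)), 0.03)
})

test_that("complete-data logistic fit agrees with the full MLE incidence", {
  # follow-up far beyond the latency bulk: cure status is effectively
  # observed, so a logistic fit of susceptibility approximates gamma-hat
  cfg <- scenario_config(n_subjects = 8000, censor_upper = 500,
                         admin_censor_times = 400, n_replicates = 2,
                         seed = 31)
  coh <- generate_cohort(cfg, 0L)
  fit <- fit_mixture_cure(coh)
  glmfit <- glm(susceptible ~ group, family = binomial(), data = coh)
  expect_lt(max(abs(fit$gamma - coef(glmfit))), 0.1)
})

test_that("degenerate inputs are refused and non-convergence is never silent", {
  no_events <- make_cohort(time = c(1, 2, 3), event = c(0, 0, 0))
  expect_error(suppressWarnings(fit_mixture_cure(no_events)), "no events")
  all_events <- make_cohort(time = c(1, 2, 3), event = c(1, 1, 1))
  expect_error(suppressWarnings(fit_mixture_cure(all_events)), "censored")

  coh <- apply_admin_censoring(generate_cohort(test_config(n_subjects = 400), 0L), 8)
  fit <- suppressWarnings(fit_mixture_cure(coh))
  unconv <- fit
  unconv$converged <- FALSE
  expect_error(predict_incidence(unconv, data.frame(group = 1)),
               "unconverged")
  expect_equal(predict_incidence(unconv, data.frame(group = 1),
                                 allow_unconverged = TRUE),
               predict_incidence(fit, data.frame(group = 1)))
  # gamma = 0 gives pi = 0.5 everywhere
  half <- fit
  half$gamma <- c(0, 0)
  expect_equal(predict_incidence(half, data.frame(group = c(1, 2))),
               c(0.5, 0.5))
})

test_that("multi-start optima agree and incidence is horizon-stable", {
  cfg <- test_config(n_subjects = 3000, median_time_g2 = 7, seed = 13)
  coh <- generate_cohort(cfg, 0L)
  cc <- apply_admin_censoring(coh, 10)
  lls <- vapply(1:3, function(s)
    suppressWarnings(fit_mixture_cure(cc, seed = s))$loglik, numeric(1))
  expect_lt(max(lls) - min(lls), 1e-6)

  # refitting at a later vs earlier cutoff keeps incidence near truth
  nd <- data.frame(group = c(1, 2))
  late <- suppressWarnings(fit_mixture_cure(apply_admin_censoring(coh, 12)))
  early <- suppressWarnings(fit_mixture_cure(apply_admin_censoring(coh, 6)))
  expect_lt(max(abs(predict_incidence(late, nd) - 0.25)), 0.06)
  expect_lt(max(abs(predict_incidence(early, nd) - 0.25)), 0.10)
})

test_that("weak identifiability under early censoring is flagged", {
  cfg <- scenario_config(n_subjects = 3000, median_time_g2 = 10,
                         n_replicates = 2, seed = 19)
  coh <- generate_cohort(cfg, 0L)
  expect_warning(fit_mixture_cure(apply_admin_censoring(coh, 3)),
                 "identifiability")
})

test_that("cure fits serialise to JSON", {
  coh <- apply_admin_censoring(generate_cohort(test_config(n_subjects = 500), 0L), 8)
  fit <- suppressWarnings(fit_mixture_cure(coh))
  path <- withr::local_tempfile(fileext = ".json")
  write_cure_fit(fit, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$loglik, fit$loglik, tolerance = 1e-12)
  expect_equal(unlist(back$gamma), fit$gamma, tolerance = 1e-12)
  expect_equal(back$design$incidence_covariates, "group")
})
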