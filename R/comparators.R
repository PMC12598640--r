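# Reference estimators: ever/never logistic regression, Cox proportional
# hazards (Breslow ties and baseline), log-normal AFT, and the Kaplan-Meier
# product-limit curve. All consume the same cohort table and expose the same
# predicted diagnosis probability surface via predict_diag_prob().

new_diag_model <- function(model_kind, fit, covariates, ...) {
  structure(c(list(model_kind = model_kind, fit = fit,
                   covariates = covariates), list(...)),
            class = "diag_model")
}

#' @export
print.diag_model <- function(x, ...) {
  cat(sprintf("Diagnosis-probability model: %s\n", x$model_kind))
  print(x$coefficients)
  invisible(x)
}

#' Ever/never logistic regression
#'
#' Fits `event ~ covariates` by logistic regression, treating the outcome as
#' ever vs never diagnosed by the (already applied) censoring time and
#' ignoring follow-up duration — the classification comparator. Apply
#' [apply_admin_censoring()] first so the outcome is "diagnosed by the
#' cutoff". Under censoring this model underestimates the true event
#' probability because unfinished follow-up is treated as "never".
#'
#' @param cohort Cohort table with both outcome classes present.
#' @param covariates Covariate column names.
#' @return A `diag_model` with `model_kind = "logistic_ever_never"`; complete
#'   or quasi-complete separation is reported in `$separation`.
#' @export
fit_logistic_ever_never <- function(cohort, covariates = "group") {
  assert_cohort(cohort)
  if (length(unique(cohort$event)) < 2L)
    stop("degenerate data: both outcome classes must be present",
         call. = FALSE)
  separation <- FALSE
  g <- withCallingHandlers(
    stats::glm(stats::reformulate(covariates, response = "event"),
               family = stats::binomial(), data = cohort),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!g$converged) separation <- TRUE
  new_diag_model("logistic_ever_never", g, covariates,
                 coefficients = stats::coef(g),
                 loglik = as.numeric(stats::logLik(g)),
                 separation = separation)
}

#' Cox proportional hazards comparator
#'
#' Partial-likelihood fit of time-to-diagnosis with Breslow tie handling and
#' Breslow baseline cumulative hazard (anchored at covariates = 0), giving the
#' survival predictor `S(t | x) = exp(-Lambda0(t) exp(x' beta))`.
#'
#' @inheritParams fit_logistic_ever_never
#' @return A `diag_model` with `model_kind = "cox_ph"`, coefficients, the
#'   baseline step function (`$baseline`: times and cumulative hazard) and the
#'   partial log-likelihood.
#' @export
fit_cox_ph <- function(cohort, covariates = "group") {
  assert_cohort(cohort)
  if (sum(cohort$event) < 1L)
    stop("degenerate data: no events observed", call. = FALSE)
  f <- stats::as.formula(paste("survival::Surv(observed_time, event) ~",
                               paste(covariates, collapse = " + ")))
  cf <- survival::coxph(f, data = cohort, ties = "breslow")
  bh <- survival::basehaz(cf, centered = FALSE)
  new_diag_model("cox_ph", cf, covariates,
                 coefficients = stats::coef(cf),
                 baseline = list(time = bh$time, cumhaz = bh$hazard),
                 loglik = cf$loglik[length(cf$loglik)])
}

#' Log-normal accelerated failure time comparator
#'
#' Censored maximum likelihood fit of a log-normal survival model,
#' `log T = x' beta + sigma * epsilon` with standard-normal `epsilon` —
#' the plain parametric time-to-event comparator (a mixture cure model with
#' the susceptible fraction pinned to 1).
#'
#' @inheritParams fit_logistic_ever_never
#' @return A `diag_model` with `model_kind = "lognormal_aft"`, coefficients,
#'   `$scale` (sigma) and the log-likelihood.
#' @export
fit_lognormal_aft <- function(cohort, covariates = "group") {
  assert_cohort(cohort)
  if (any(cohort$observed_time <= 0))
    stop("observed_time must be positive", call. = FALSE)
  if (sum(cohort$event) < 1L)
    stop("degenerate data: no events observed", call. = FALSE)
  f <- stats::as.formula(paste("survival::Surv(observed_time, event) ~",
                               paste(covariates, collapse = " + ")))
  sr <- survival::survreg(f, data = cohort, dist = "lognormal")
  new_diag_model("lognormal_aft", sr, covariates,
                 coefficients = stats::coef(sr),
                 scale = sr$scale,
                 loglik = as.numeric(stats::logLik(sr)))
}

#' Predicted diagnosis probability at a censoring horizon
#'
#' The common prediction surface of all four models. For the Cox and
#' log-normal AFT fits the diagnosis probability is `1 - S(t_c | x)`, the
#' model-predicted event probability by the administrative censoring time
#' `t_c`. The ever/never logistic fit returns its fitted class probability
#' (independent of `t_c` by construction), and a mixture cure fit returns the
#' incidence `pi(z)` (horizon-free: the probability of ever being diagnosed).
#'
#' @param fit A `diag_model` or `cure_fit`.
#' @param newdata Data frame of covariate rows.
#' @param t_c Positive censoring horizon.
#' @param ... Passed to methods.
#' @return Probabilities, one per `newdata` row.
#' @export
predict_diag_prob <- function(fit, newdata, t_c, ...) {
  UseMethod("predict_diag_prob")
}

#' @export
predict_diag_prob.cure_fit <- function(fit, newdata, t_c, ...) {
  check_tc(t_c)
  predict_incidence(fit, newdata, ...)
}

#' @export
predict_diag_prob.diag_model <- function(fit, newdata, t_c, ...) {
  check_tc(t_c)
  switch(fit$model_kind,
    logistic_ever_never =
      unname(stats::predict(fit$fit, newdata = newdata, type = "response")),
    cox_ph = {
      lp <- stats::predict(fit$fit, newdata = newdata, type = "lp",
                           reference = "zero")
      bl <- fit$baseline
      if (t_c > max(bl$time)) {
        message("t_c = ", t_c, " exceeds the last baseline time (",
                signif(max(bl$time), 6),
                "); carrying the cumulative hazard flat")
        H0 <- bl$cumhaz[length(bl$cumhaz)]
      } else {
        idx <- findInterval(t_c, bl$time)
        H0 <- if (idx == 0L) 0 else bl$cumhaz[idx]
      }
      unname(1 - exp(-H0 * exp(lp)))
    },
    lognormal_aft = {
      lp <- stats::predict(fit$fit, newdata = newdata, type = "lp")
      unname(stats::plnorm(t_c, meanlog = lp, sdlog = fit$scale))
    },
    stop("unknown model kind: ", fit$model_kind, call. = FALSE))
}

check_tc <- function(t_c) {
  if (!is.numeric(t_c) || length(t_c) != 1L || is.na(t_c) || t_c <= 0)
    stop("`t_c` must be a single positive time", call. = FALSE)
  invisible(t_c)
}

#' Kaplan-Meier product-limit curve(s)
#'
#' @param cohort Cohort table.
#' @param by_group Stratify on the `group` column?
#' @return A data frame of class `km_curve` with columns `time`, `survival`,
#'   `n_risk`, `n_event` and `group` (`NA` when unstratified), including the
#'   `time = 0, survival = 1` anchor per stratum. Survival is stepwise
#'   nonincreasing within each stratum.
#' @export
kaplan_meier <- function(cohort, by_group = TRUE) {
  assert_cohort(cohort)
  f <- if (by_group)
    survival::Surv(observed_time, event) ~ group
  else
    survival::Surv(observed_time, event) ~ 1
  sf <- survival::survfit(f, data = cohort)
  if (is.null(sf$strata)) {
    grp <- rep(NA_integer_, length(sf$time))
    starts <- 1L
  } else {
    grp <- rep(as.integer(sub("^group=", "", names(sf$strata))),
               times = sf$strata)
    starts <- cumsum(c(1L, utils::head(sf$strata, -1)))
  }
  out <- data.frame(time = sf$time, survival = sf$surv,
                    n_risk = sf$n.risk, n_event = sf$n.event, group = grp)
  anchor <- data.frame(time = 0, survival = 1,
                       n_risk = out$n_risk[starts], n_event = 0L,
                       group = out$group[starts])
  out <- rbind(anchor, out)
  out <- out[order(out$group, out$time), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Write Kaplan-Meier curves as CSV
#'
#' @param km A `km_curve` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_km_curve <- function(km, path) {
  utils::write.csv(as.data.frame(km), path, row.names = FALSE, na = "")
  invisible(path)
}
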