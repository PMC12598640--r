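# Mixture cure model: logistic incidence x log-normal latency, estimated by
# direct maximum likelihood on right-censored data.
#
# Population survival:  Spop(t | x, z) = 1 - pi(z) + pi(z) * S(t | x)
# with pi(z) = plogis(z'gamma) the probability of being susceptible
# ("incidence") and S(t | x) = 1 - Phi((log t - x'beta) / sigma) the
# log-normal survival of the susceptible subpopulation ("latency").
#
# Observed-data log-likelihood for subject i with follow-up t_i and event
# indicator d_i:
#   d_i  * [ log pi(z_i) + log f(t_i | x_i) ]
#   (1-d_i) * log[ 1 - pi(z_i) + pi(z_i) S(t_i | x_i) ]
# where f is the log-normal density. The censored term is evaluated as
# log1p(-pi * F) with F the log-normal CDF, clipped away from 0 so the
# likelihood is finite for any finite parameter vector.

#' Covariate design for the two model components
#'
#' Names the cohort columns entering the incidence (susceptibility) and
#' latency (event-time) components. An intercept is always included in both;
#' use `character(0)` for an intercept-only component.
#'
#' @param incidence_covariates Character vector of incidence covariates (z).
#' @param latency_covariates Character vector of latency covariates (x);
#'   defaults to the incidence covariates, matching the common case of the
#'   same grouping variable in both components.
#' @return An object of class `cure_design`.
#' @export
cure_design <- function(incidence_covariates = "group",
                        latency_covariates = incidence_covariates) {
  if (!is.character(incidence_covariates) || anyNA(incidence_covariates))
    stop("`incidence_covariates` must be a character vector", call. = FALSE)
  if (!is.character(latency_covariates) || anyNA(latency_covariates))
    stop("`latency_covariates` must be a character vector", call. = FALSE)
  structure(list(incidence_covariates = incidence_covariates,
                 latency_covariates = latency_covariates),
            class = "cure_design")
}

design_matrix <- function(covariates, data) {
  f <- if (length(covariates)) stats::reformulate(covariates) else ~1
  stats::model.matrix(f, data = data)
}

# Validate and pre-compute the pieces the likelihood needs.
cure_data <- function(cohort, design) {
  if (!is.data.frame(cohort) ||
      !all(c("observed_time", "event") %in% names(cohort)))
    stop("`cohort` must contain observed_time and event columns",
         call. = FALSE)
  t <- cohort$observed_time
  if (anyNA(t) || any(!is.finite(t)) || any(t <= 0))
    stop("observed_time must be positive and finite", call. = FALSE)
  d <- cohort$event
  if (anyNA(d) || !all(d %in% c(0, 1)))
    stop("event must be 0/1", call. = FALSE)
  missing_cov <- setdiff(union(design$incidence_covariates,
                               design$latency_covariates), names(cohort))
  if (length(missing_cov))
    stop("cohort is missing covariate columns: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  Z <- design_matrix(design$incidence_covariates, cohort)
  X <- design_matrix(design$latency_covariates, cohort)
  if (anyNA(Z) || anyNA(X))
    stop("covariates contain missing values", call. = FALSE)
  list(t = t, d = as.integer(d), logt = log(t), Z = Z, X = X,
       k = ncol(Z), p = ncol(X))
}

cure_param_names <- function(dat) {
  c(paste0("incidence_", colnames(dat$Z)),
    paste0("latency_", colnames(dat$X)),
    "log_sigma")
}

.cure_loglik <- function(params, dat) {
  k <- dat$k; p <- dat$p
  gamma <- params[seq_len(k)]
  beta <- params[k + seq_len(p)]
  log_sigma <- params[k + p + 1L]
  sigma <- exp(log_sigma)
  eta <- drop(dat$Z %*% gamma)
  w <- (dat$logt - drop(dat$X %*% beta)) / sigma
  log_pi <- stats::plogis(eta, log.p = TRUE)
  piF <- pmin(stats::plogis(eta) * stats::pnorm(w), 1 - 1e-12)
  ll <- ifelse(dat$d == 1L,
               log_pi + stats::dnorm(w, log = TRUE) - log_sigma - dat$logt,
               log1p(-piF))
  sum(ll)
}

.cure_loglik_grad <- function(params, dat) {
  k <- dat$k; p <- dat$p
  gamma <- params[seq_len(k)]
  beta <- params[k + seq_len(p)]
  sigma <- exp(params[k + p + 1L])
  eta <- drop(dat$Z %*% gamma)
  pi <- stats::plogis(eta)
  w <- (dat$logt - drop(dat$X %*% beta)) / sigma
  phi <- stats::dnorm(w)
  F <- stats::pnorm(w)
  denom <- pmax(1 - pi * F, 1e-12)
  ev <- dat$d == 1L
  wz <- ifelse(ev, 1 - pi, -F * pi * (1 - pi) / denom)
  wx <- ifelse(ev, w / sigma, pi * phi / (sigma * denom))
  ws <- ifelse(ev, w^2 - 1, pi * w * phi / denom)
  c(drop(crossprod(dat$Z, wz)), drop(crossprod(dat$X, wx)), sum(ws))
}

#' Mixture cure observed-data log-likelihood
#'
#' Evaluates the censored-data log-likelihood of the mixture cure model at a
#' parameter vector `c(gamma, beta, log_sigma)` (incidence coefficients,
#' latency location coefficients, log latency scale). Numerically guarded so
#' the value is finite at any finite parameter vector.
#'
#' @param params Numeric vector `c(gamma, beta, log_sigma)`.
#' @param cohort Analytic table with `observed_time`, `event` and the design's
#'   covariate columns.
#' @param design A [cure_design()].
#' @return The log-likelihood (scalar).
#' @export
cure_loglik <- function(params, cohort, design = cure_design("group")) {
  dat <- cure_data(cohort, design)
  if (length(params) != dat$k + dat$p + 1L)
    stop(sprintf("`params` must have length %d (gamma, beta, log_sigma)",
                 dat$k + dat$p + 1L), call. = FALSE)
  .cure_loglik(params, dat)
}

#' @rdname cure_loglik
#' @return `cure_loglik_grad` returns the analytic gradient with respect to
#'   `(gamma, beta, log_sigma)`.
#' @export
cure_loglik_grad <- function(params, cohort, design = cure_design("group")) {
  dat <- cure_data(cohort, design)
  g <- .cure_loglik_grad(params, dat)
  names(g) <- cure_param_names(dat)
  g
}

# Moment-style starting values: logistic fit of the crude event indicator for
# gamma; log-time regression among events for beta/sigma.
cure_start <- function(dat) {
  g <- tryCatch(
    suppressWarnings(stats::glm.fit(dat$Z, dat$d,
                                    family = stats::binomial())),
    error = function(e) NULL)
  gamma0 <- if (is.null(g)) rep(0, dat$k) else stats::coef(g)
  gamma0[!is.finite(gamma0)] <- 0
  ev <- dat$d == 1L
  lfit <- stats::lm.fit(dat$X[ev, , drop = FALSE], dat$logt[ev])
  beta0 <- stats::coef(lfit)
  beta0[!is.finite(beta0)] <- 0
  s0 <- stats::sd(lfit$residuals)
  if (!is.finite(s0) || s0 <= 1e-3) s0 <- 0.5
  unname(c(gamma0, beta0, log(s0)))
}

#' Fit the mixture cure model by maximum likelihood
#'
#' Maximises the observed-data likelihood jointly over the incidence
#' coefficients, latency coefficients and log latency scale with BFGS and the
#' analytic gradient, from a data-driven start (crude logistic fit for the
#' incidence, log-time regression among events for the latency) plus
#' `n_restarts` jittered restarts with a recorded seed. The best optimum is
#' polished until the gradient criterion is met or no further improvement is
#' found. Non-convergence is reported via `converged = FALSE`, never as a
#' silent success.
#'
#' When the largest observed follow-up lies below the fitted median latency
#' time, the cure fraction and late survival are confounded and a
#' weak-identifiability warning is emitted (expect inflated variance, as under
#' early administrative censoring).
#'
#' @param cohort Analytic table with `observed_time`, `event` and covariates.
#' @param design A [cure_design()].
#' @param n_restarts Number of jittered restarts beyond the data-driven start.
#' @param jitter_sd Standard deviation of the restart jitter.
#' @param maxit BFGS iteration cap per start.
#' @param seed Seed for the restart jitter (recorded in the fit).
#' @param starts Optional list of user-supplied start vectors (e.g. a warm
#'   start from a full-data fit when bootstrapping); replaces the data-driven
#'   start and restarts.
#' @param warn_identifiability Emit the weak-identifiability warning?
#' @return An object of class `cure_fit`: `gamma`, `beta`, `log_sigma`,
#'   `sigma`, `loglik`, `converged`, `n_iter`, `covariance` (inverse numeric
#'   Hessian, or `NULL` if singular), the design, and the initialisation
#'   record `seed_or_starts`.
#' @export
fit_mixture_cure <- function(cohort, design = cure_design("group"),
                             n_restarts = 4L, jitter_sd = 0.5,
                             maxit = 1000L, seed = 1L, starts = NULL,
                             warn_identifiability = TRUE) {
  dat <- cure_data(cohort, design)
  n_events <- sum(dat$d)
  if (n_events == 0L)
    stop("degenerate data: no events observed, incidence is unidentifiable",
         call. = FALSE)
  if (n_events == length(dat$d))
    stop("degenerate data: no censored observations, cure fraction lies on ",
         "the boundary", call. = FALSE)

  npar <- dat$k + dat$p + 1L
  if (is.null(starts)) {
    base <- cure_start(dat)
    start_list <- list(base)
    if (n_restarts > 0L) {
      set.seed(seed)
      for (i in seq_len(n_restarts))
        start_list[[i + 1L]] <- base + stats::rnorm(npar, sd = jitter_sd)
    }
  } else {
    start_list <- lapply(starts, function(s) {
      if (length(s) != npar) stop("start vector has wrong length",
                                  call. = FALSE)
      as.numeric(s)
    })
  }

  negll <- function(p) -.cure_loglik(p, dat)
  neggr <- function(p) -.cure_loglik_grad(p, dat)
  run_bfgs <- function(par) {
    tryCatch(stats::optim(par, negll, neggr, method = "BFGS",
                          control = list(maxit = maxit, reltol = 1e-9)),
             error = function(e) NULL)
  }

  fits <- lapply(start_list, run_bfgs)
  fits <- fits[!vapply(fits, is.null, logical(1))]
  start_ll <- vapply(start_list, function(s) .cure_loglik(s, dat), numeric(1))

  if (length(fits) == 0L) {
    par <- start_list[[which.max(start_ll)]]
    best_value <- -max(start_ll)
    opt_converged <- FALSE
    n_iter <- 0L
  } else {
    values <- vapply(fits, `[[`, numeric(1), "value")
    best <- fits[[which.min(values)]]
    par <- best$par
    best_value <- best$value
    opt_converged <- best$convergence == 0L
    n_iter <- sum(vapply(fits, function(f) f$counts[["function"]],
                         numeric(1)))
    # polish: restart BFGS from the incumbent until the gradient criterion
    # holds or the log-likelihood stops improving
    grad_tol <- 1e-5 * max(1, abs(best_value))
    for (i in 1:5) {
      if (max(abs(.cure_loglik_grad(par, dat))) <= grad_tol) break
      more <- run_bfgs(par)
      if (is.null(more) || more$value >= best_value - 1e-12) break
      par <- more$par
      best_value <- more$value
      opt_converged <- more$convergence == 0L
      n_iter <- n_iter + more$counts[["function"]]
    }
  }

  loglik <- -best_value
  # never report an optimum below a start point
  if (loglik < max(start_ll) - 1e-8) {
    par <- start_list[[which.max(start_ll)]]
    loglik <- max(start_ll)
    opt_converged <- FALSE
  }
  grad <- .cure_loglik_grad(par, dat)
  converged <- opt_converged &&
    max(abs(grad)) <= 1e-5 * max(1, abs(loglik)) &&
    is.finite(loglik)

  H <- tryCatch(stats::optimHess(par, negll, neggr), error = function(e) NULL)
  covariance <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) NULL) else NULL

  pn <- cure_param_names(dat)
  names(par) <- pn
  if (!is.null(covariance)) dimnames(covariance) <- list(pn, pn)

  gamma <- par[seq_len(dat$k)]
  beta <- par[dat$k + seq_len(dat$p)]
  names(gamma) <- colnames(dat$Z)
  names(beta) <- colnames(dat$X)

  if (warn_identifiability && converged) {
    fitted_median <- stats::median(exp(drop(dat$X %*% beta)))
    if (max(dat$t) < fitted_median)
      warning("weak identifiability: maximum observed time (",
              signif(max(dat$t), 4), ") is below the fitted median latency ",
              "time (", signif(fitted_median, 4), "); the cure fraction and ",
              "late survival are confounded and incidence estimates may be ",
              "unstable", call. = FALSE)
  }

  structure(list(gamma = gamma, beta = beta,
                 log_sigma = unname(par[npar]),
                 sigma = exp(unname(par[npar])),
                 par = par,
                 loglik = loglik,
                 converged = converged,
                 n_iter = as.integer(n_iter),
                 gradient = grad,
                 covariance = covariance,
                 design = design,
                 n = length(dat$t),
                 n_events = n_events,
                 seed_or_starts = if (is.null(starts))
                   list(seed = seed, n_restarts = n_restarts,
                        jitter_sd = jitter_sd)
                 else list(user_starts = start_list)),
            class = "cure_fit")
}

#' @export
print.cure_fit <- function(x, ...) {
  cat("Mixture cure model fit (logistic incidence x log-normal latency)\n")
  cat(sprintf("  n = %d (%d events), log-likelihood = %.4f, %s\n",
              x$n, x$n_events, x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  cat("  incidence (logit scale):\n")
  print(x$gamma)
  cat("  latency (log-time scale):\n")
  print(x$beta)
  cat(sprintf("  sigma = %.4f\n", x$sigma))
  invisible(x)
}

#' Predict the incidence (diagnosis) probability
#'
#' Returns the fitted probability of belonging to the susceptible subgroup,
#' `pi(z) = plogis(z' gamma)`. In this framework the incidence *is* the
#' predicted diagnosis probability; it does not depend on any censoring
#' horizon.
#'
#' @param fit A converged [fit_mixture_cure()] fit.
#' @param newdata Data frame with the incidence covariate columns.
#' @param allow_unconverged Predict from an unconverged fit anyway? Default
#'   `FALSE`: prediction refuses with a diagnostic.
#' @return Numeric vector of probabilities in (0, 1), one per row.
#' @export
predict_incidence <- function(fit, newdata, allow_unconverged = FALSE) {
  if (!inherits(fit, "cure_fit"))
    stop("`fit` must be a cure_fit", call. = FALSE)
  if (!fit$converged && !allow_unconverged)
    stop("refusing to predict from an unconverged fit (loglik = ",
         signif(fit$loglik, 6), ", max |gradient| = ",
         signif(max(abs(fit$gradient)), 3),
         "); inspect the fit or set allow_unconverged = TRUE", call. = FALSE)
  Z <- design_matrix(fit$design$incidence_covariates, newdata)
  unname(stats::plogis(drop(Z %*% fit$gamma)))
}

#' Population survival under a fitted mixture cure model
#'
#' `Spop(t | x, z) = 1 - pi(z) + pi(z) * S(t | x)`: nonincreasing in `t` and
#' bounded below by the cure fraction `1 - pi(z)`, the plateau reached as
#' `t` grows.
#'
#' @param fit A [fit_mixture_cure()] fit.
#' @param newdata Data frame with the covariate columns (single or multiple
#'   rows).
#' @param t Positive time(s).
#' @return If `newdata` has one row, a vector over `t`; otherwise a matrix
#'   with one row per `newdata` row and one column per time.
#' @export
population_survival <- function(fit, newdata, t) {
  if (!inherits(fit, "cure_fit"))
    stop("`fit` must be a cure_fit", call. = FALSE)
  if (!is.numeric(t) || any(!is.finite(t) & t != Inf) || any(t <= 0))
    stop("`t` must be positive", call. = FALSE)
  pi <- predict_incidence(fit, newdata, allow_unconverged = TRUE)
  mu <- drop(design_matrix(fit$design$latency_covariates, newdata) %*%
               fit$beta)
  surv <- function(tt, m) 1 - stats::plnorm(tt, meanlog = m,
                                            sdlog = fit$sigma)
  out <- outer(seq_along(pi), seq_along(t),
               function(i, j) 1 - pi[i] + pi[i] * surv(t[j], mu[i]))
  if (nrow(out) == 1L || ncol(out) == 1L) drop(out) else out
}

#' Serialise a cure fit as JSON
#'
#' Writes `gamma`, `beta`, `log_sigma`, `loglik`, `converged`, `n_iter`, the
#' covariance (row-major) and the design echo.
#'
#' @param fit A `cure_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cure_fit <- function(fit, path) {
  if (!inherits(fit, "cure_fit"))
    stop("`fit` must be a cure_fit", call. = FALSE)
  obj <- list(gamma = as.list(fit$gamma),
              beta = as.list(fit$beta),
              log_sigma = fit$log_sigma,
              loglik = fit$loglik,
              converged = fit$converged,
              n_iter = fit$n_iter,
              covariance = if (is.null(fit$covariance)) NULL else
                as.vector(t(fit$covariance)),
              covariance_order = if (is.null(fit$covariance)) NULL else
                rownames(fit$covariance),
              design = unclass(fit$design),
              n = fit$n, n_events = fit$n_events)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
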