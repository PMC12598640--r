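# Synthetic administrative-claims emulator and computable-phenotype cohort
# builder: enrollment rules (enrolled within one month of birth, continuous
# through 18 months), a >=2-diagnosis-code case definition with the first
# code's date as the event time, and censoring at disenrollment or the end of
# the database. Only synthetic claims are ever consumed; group labels are
# abstract.

#' Computable phenotype specification
#'
#' A rule over coded claims defining a case: at least `min_code_count`
#' diagnoses drawn from `code_set`, with the event time taken as the date of
#' the first qualifying code.
#'
#' @param code_set Character vector of qualifying diagnosis codes. The default
#'   is a synthetic autism-like placeholder list, not a published code set.
#' @param min_code_count Minimum number of qualifying codes (default 2).
#' @param event_time_rule Only `"first_code"` is supported.
#' @return An object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(code_set = c("F84.0", "F84.5", "F84.8", "F84.9"),
                           min_code_count = 2L,
                           event_time_rule = "first_code") {
  if (!is.character(code_set) || length(code_set) == 0L || anyNA(code_set))
    stop("invalid `code_set`: must be a non-empty character vector",
         call. = FALSE)
  if (!is.numeric(min_code_count) || length(min_code_count) != 1L ||
      min_code_count < 1 || min_code_count != round(min_code_count))
    stop("invalid `min_code_count`: must be an integer >= 1", call. = FALSE)
  event_time_rule <- match.arg(event_time_rule)
  structure(list(code_set = code_set,
                 min_code_count = as.integer(min_code_count),
                 event_time_rule = event_time_rule),
            class = "phenotype_spec")
}

#' @rdname phenotype_spec
#' @param path YAML file path.
#' @export
read_phenotype_spec <- function(path) {
  do.call(phenotype_spec, yaml::read_yaml(path))
}

#' @rdname phenotype_spec
#' @param spec A `phenotype_spec`.
#' @export
write_phenotype_spec <- function(spec, path) {
  if (!inherits(spec, "phenotype_spec"))
    stop("`spec` must be a phenotype_spec", call. = FALSE)
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Generate a synthetic claims stream
#'
#' Emulates a birth-cohort claims extract on top of the cure-mixture
#' data-generating process: susceptible subjects receive at least
#' `min_code_count` qualifying diagnosis codes starting at their simulated
#' diagnosis time (follow-up codes at short visit-like gaps), non-cases
#' receive at most one qualifying code (at rate `noise_rate`), and every
#' subject accrues background out-of-set claims. Enrollment spans include a
#' configurable fraction of late enrollees and early disenrollees to exercise
#' the cohort filters; claims are only emitted while a subject is enrolled.
#'
#' The latent truth table records, per subject, the group, susceptibility,
#' true diagnosis age, censoring age (disenrollment or database end),
#' eligibility under the enrollment rules, and the case status / event age the
#' phenotype pipeline should recover (computed from the latent scheduled code
#' dates, independently of [build_cohort()]'s claim handling).
#'
#' @param config A [scenario_config()] supplying the mixture mechanism (sizes,
#'   event rate, per-group diagnosis-time medians, censoring).
#' @param phenotype A [phenotype_spec()].
#' @param seed Integer seed for the whole stream.
#' @param birth_year Calendar year of birth (birth dates uniform within it).
#' @param database_end Last date covered by the database.
#' @param noise_rate Probability a non-susceptible subject receives one
#'   qualifying code.
#' @param late_enroll_frac Fraction enrolling later than one month after
#'   birth (excluded by the pipeline).
#' @param short_span_frac Fraction disenrolling before 18 months (excluded by
#'   the pipeline).
#' @param background_rate Mean number of out-of-set background claims per
#'   subject.
#' @return A list: `claims` (person_id, service_date, dx_code), `spans`
#'   (person_id, birth_date, span_start, span_end, group), `truth`, the
#'   `phenotype` echo and `database_end`.
#' @export
generate_synthetic_claims <- function(config,
                                      phenotype = phenotype_spec(),
                                      seed = 1L,
                                      birth_year = 2014L,
                                      database_end = as.Date("2023-12-31"),
                                      noise_rate = 0.05,
                                      late_enroll_frac = 0.02,
                                      short_span_frac = 0.02,
                                      background_rate = 1) {
  if (!inherits(config, "scenario_config"))
    stop("`config` must be a scenario_config", call. = FALSE)
  if (!inherits(phenotype, "phenotype_spec"))
    stop("`phenotype` must be a phenotype_spec", call. = FALSE)
  database_end <- as.Date(database_end)

  set.seed(seed)
  s_cohort <- sample.int(.Machine$integer.max - 1L, 1L)
  s_claims <- sample.int(.Machine$integer.max - 1L, 1L)
  cfg <- config
  cfg$seed <- s_cohort
  latent <- generate_cohort(cfg, 0L)
  set.seed(s_claims)

  n <- nrow(latent)
  ids <- sprintf("P%06d", latent$subject_id)
  birth_date <- as.Date(sprintf("%d-01-01", birth_year)) +
    sample(0:364, n, replace = TRUE)
  late <- stats::runif(n) < late_enroll_frac
  span_start <- birth_date +
    ifelse(late, sample(45:150, n, replace = TRUE),
           sample(0:28, n, replace = TRUE))
  short <- stats::runif(n) < short_span_frac
  # disenrollment: the latent uniform censoring time, kept past 18 months for
  # regular subjects; deliberately short spans exercise the 18-month filter
  span_age <- pmax(latent$censor_time, 1.6)
  span_age[short] <- stats::runif(sum(short), 0.2, 1.4)
  span_end <- birth_date + round(span_age * 365.25)
  eligible <- !late & !short

  censor_date <- pmin(span_end, database_end)
  censor_age <- as.numeric(censor_date - birth_date) / 365.25

  code_set <- phenotype$code_set
  noise_codes <- c("Z00.129", "J06.9", "B34.9", "H66.90", "K59.00")

  claims <- list()
  add_claims <- function(i, dates, codes) {
    keep <- dates >= span_start[i] & dates <= span_end[i]
    if (!any(keep)) return()
    claims[[length(claims) + 1L]] <<- data.frame(
      person_id = ids[i], service_date = dates[keep],
      dx_code = codes[keep], stringsAsFactors = FALSE)
  }

  # latent scheduled qualifying-code dates per susceptible subject
  min_codes <- phenotype$min_code_count
  observed_case <- rep(FALSE, n)
  event_age <- rep(NA_real_, n)
  for (i in which(latent$susceptible)) {
    diag_date <- birth_date[i] + round(latent$true_event_time[i] * 365.25)
    n_codes <- min_codes + stats::rpois(1L, 1)
    gaps <- sample(7:90, n_codes - 1L, replace = TRUE)
    dates <- diag_date + c(0L, cumsum(gaps))
    add_claims(i, dates, sample(code_set, n_codes, replace = TRUE))
    in_window <- dates >= span_start[i] & dates <= censor_date[i]
    if (eligible[i] && sum(in_window) >= min_codes) {
      observed_case[i] <- TRUE
      event_age[i] <- as.numeric(min(dates[in_window]) - birth_date[i]) /
        365.25
    }
  }

  # noise: at most one qualifying code for non-susceptible subjects
  noisy <- which(!latent$susceptible & stats::runif(n) < noise_rate)
  for (i in noisy) {
    span_days <- as.integer(span_end[i] - span_start[i])
    if (span_days < 1L) next
    add_claims(i, span_start[i] + sample.int(span_days, 1L),
               sample(code_set, 1L))
  }

  # background out-of-set claims for realism
  n_bg <- stats::rpois(n, background_rate)
  for (i in which(n_bg > 0L)) {
    span_days <- as.integer(span_end[i] - span_start[i])
    if (span_days < 1L) next
    add_claims(i, span_start[i] + sample.int(span_days, n_bg[i],
                                             replace = TRUE),
               sample(noise_codes, n_bg[i], replace = TRUE))
  }

  claims <- if (length(claims)) do.call(rbind, claims) else
    data.frame(person_id = character(), service_date = as.Date(character()),
               dx_code = character())
  claims <- claims[order(claims$person_id, claims$service_date), ]
  rownames(claims) <- NULL

  spans <- data.frame(person_id = ids, birth_date = birth_date,
                      span_start = span_start, span_end = span_end,
                      group = latent$group, stringsAsFactors = FALSE)
  truth <- data.frame(person_id = ids,
                      group = latent$group,
                      susceptible = latent$susceptible,
                      true_event_time = latent$true_event_time,
                      censor_age = censor_age,
                      eligible = eligible,
                      observed_case = observed_case,
                      event_age = event_age,
                      stringsAsFactors = FALSE)
  list(claims = claims, spans = spans, truth = truth,
       phenotype = phenotype, database_end = database_end)
}

#' Build an analytic cohort from claims and enrollment spans
#'
#' Applies the study's enrollment filters (span starting within
#' `enroll_within_days` of birth; continuous coverage through
#' `continuous_through_days`), classifies cases under the phenotype rule
#' (at least `min_code_count` qualifying codes observed before censoring),
#' sets the event time to the age at the first qualifying code, and censors at
#' disenrollment or the database end — emitting the same cohort schema that
#' all model-fitting functions consume (ages in years, days / 365.25).
#'
#' Persons with claims but no enrollment span are excluded with a logged
#' count; filter-by-filter attrition is attached as the `attrition` attribute.
#'
#' @param claims Data frame: `person_id`, `service_date`, `dx_code`.
#' @param spans Data frame: `person_id`, `birth_date`, `span_start`,
#'   `span_end` and the grouping column `group`.
#' @param phenotype A [phenotype_spec()].
#' @param database_end Last date covered by the database.
#' @param enroll_within_days Enrollment must start within this many days of
#'   birth (default 31, i.e. within one month).
#' @param continuous_through_days Coverage must extend at least this many days
#'   past birth (default 548, i.e. 18 months).
#' @return A `cure_cohort` data frame (latent columns `susceptible` and
#'   `true_event_time` are `NA`: truth is unknown to the pipeline), with the
#'   attrition log as an attribute.
#' @export
build_cohort <- function(claims, spans, phenotype = phenotype_spec(),
                         database_end = as.Date("2023-12-31"),
                         enroll_within_days = 31L,
                         continuous_through_days = 548L) {
  if (!inherits(phenotype, "phenotype_spec"))
    stop("`phenotype` must be a phenotype_spec", call. = FALSE)
  need_claims <- c("person_id", "service_date", "dx_code")
  need_spans <- c("person_id", "birth_date", "span_start", "span_end",
                  "group")
  if (!all(need_claims %in% names(claims)))
    stop("`claims` must have columns: ",
         paste(need_claims, collapse = ", "), call. = FALSE)
  if (!all(need_spans %in% names(spans)))
    stop("`spans` must have columns: ",
         paste(need_spans, collapse = ", "), call. = FALSE)
  spans$birth_date <- as.Date(spans$birth_date)
  spans$span_start <- as.Date(spans$span_start)
  spans$span_end <- as.Date(spans$span_end)
  claims$service_date <- as.Date(claims$service_date)
  database_end <- as.Date(database_end)
  if (any(spans$span_start > spans$span_end))
    stop("spans with span_start after span_end", call. = FALSE)

  orphans <- setdiff(unique(claims$person_id), spans$person_id)
  if (length(orphans))
    message("excluding ", length(orphans),
            " person(s) with claims but no enrollment span")
  claims <- claims[claims$person_id %in% spans$person_id, , drop = FALSE]

  n0 <- nrow(spans)
  ok_enroll <- spans$span_start <=
    spans$birth_date + as.integer(enroll_within_days)
  spans1 <- spans[ok_enroll, , drop = FALSE]
  ok_cont <- spans1$span_end >=
    spans1$birth_date + as.integer(continuous_through_days)
  spans2 <- spans1[ok_cont, , drop = FALSE]
  attrition <- data.frame(
    stage = c("enrollment spans",
              sprintf("enrolled within %d days of birth", enroll_within_days),
              sprintf("continuous coverage through %d days",
                      continuous_through_days)),
    n = c(n0, nrow(spans1), nrow(spans2)))
  if (nrow(spans2) == 0L)
    stop("no subjects remain after enrollment filters", call. = FALSE)

  spans2$censor_date <- pmin(spans2$span_end, database_end)
  spans2$censor_age <- as.numeric(spans2$censor_date - spans2$birth_date) /
    365.25

  qual <- claims[claims$dx_code %in% phenotype$code_set, , drop = FALSE]
  qual <- merge(qual,
                spans2[, c("person_id", "birth_date", "span_start",
                           "censor_date")],
                by = "person_id")
  qual <- qual[qual$service_date >= qual$span_start &
                 qual$service_date <= qual$censor_date, , drop = FALSE]

  if (nrow(qual)) {
    counts <- stats::aggregate(service_date ~ person_id, data = qual,
                               FUN = length)
    names(counts)[2] <- "n_codes"
    first <- stats::aggregate(service_date ~ person_id, data = qual,
                              FUN = min)
    names(first)[2] <- "first_code_date"
    pheno <- merge(counts, first, by = "person_id")
  } else {
    pheno <- data.frame(person_id = character(), n_codes = integer(),
                        first_code_date = as.Date(character()))
  }

  out <- merge(spans2, pheno, by = "person_id", all.x = TRUE)
  out$n_codes[is.na(out$n_codes)] <- 0L
  case <- out$n_codes >= phenotype$min_code_count
  event_age <- as.numeric(out$first_code_date - out$birth_date) / 365.25

  cohort <- data.frame(
    subject_id = out$person_id,
    group = out$group,
    susceptible = NA,
    true_event_time = NA_real_,
    censor_time = out$censor_age,
    observed_time = ifelse(case, event_age, out$censor_age),
    event = as.integer(case),
    stringsAsFactors = FALSE)
  cohort <- cohort[order(cohort$subject_id), ]
  rownames(cohort) <- NULL
  attr(cohort, "attrition") <- attrition
  attr(cohort, "phenotype") <- phenotype
  attr(cohort, "database_end") <- database_end
  class(cohort) <- c("cure_cohort", "data.frame")
  cohort
}
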