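HEALTH_OUTCOMES <- c("IHD", "ischemic_stroke", "T2D", "colorectal_cancer",
                     "lung_cancer", "esophageal_cancer")
HEALTH_EXPOSURES <- c("fruit", "vegetables", "legumes", "red_meat",
                      "processed_meat")

#' Packaged exposure-response table
#'
#' The thirteen dietary risk-disease pairs used in the health impact
#' modeling: relative risks with 95% CIs per stated unit change (100 g or
#' 50 g), transcribed from pooled Global Burden of Disease estimates.
#' Fruit affects ischemic heart disease, ischemic stroke, lung cancer,
#' esophageal cancer and type 2 diabetes; vegetables ischemic heart disease
#' and stroke; legumes ischemic heart disease; red and processed meat
#' colorectal cancer, type 2 diabetes and (processed only) ischemic heart
#' disease.
#'
#' @param path optional path to an alternative CSV with columns
#'   `exposure,outcome,unit_g,direction,rr,ci_low,ci_high`.
#' @return validated exposure-response data.frame.
#' @export
exposure_response <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "exposure_response.csv",
                        package = "fiveaday", mustWork = TRUE)
  er <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_exposure_response(er)
  er
}

validate_exposure_response <- function(er) {
  need <- c("exposure", "outcome", "unit_g", "direction", "rr",
            "ci_low", "ci_high")
  missing <- setdiff(need, names(er))
  if (length(missing) > 0L)
    stop("exposure-response table missing columns: ",
         paste(missing, collapse = ", "))
  stopifnot(all(er$exposure %in% HEALTH_EXPOSURES),
            all(er$outcome %in% HEALTH_OUTCOMES),
            all(er$direction %in% c("increase", "decrease")),
            all(er$unit_g > 0))
  if (any(er$rr <= 0 | er$ci_low <= 0 | er$ci_high <= 0))
    stop("relative risks and CI bounds must be > 0")
  if (any(er$ci_low > er$rr | er$rr > er$ci_high))
    stop("require ci_low <= rr <= ci_high in every row")
  invisible(er)
}

#' Dietary exposure changes between two diets
#'
#' Aggregates per-food intake changes into the five exposure categories
#' used by the health model. Legume changes are kept separate from other
#' vegetables because their exposure-response relation differs; poultry is
#' excluded (no relative-risk data), so a poultry-only change yields all
#' zeros.
#'
#' @param baseline,pathway diet vectors aligned to `foods`.
#' @param foods validated food table.
#' @return named numeric vector of signed changes (g/person/day) for
#'   `fruit`, `vegetables`, `legumes`, `red_meat`, `processed_meat`.
#' @export
delta_exposures <- function(baseline, pathway, foods) {
  d <- as.numeric(as_diet(pathway, foods)) -
    as.numeric(as_diet(baseline, foods))
  cat_sum <- function(categ) sum(d[foods$category == categ])
  c(fruit = cat_sum("fruit"),
    vegetables = cat_sum("vegetable"),
    legumes = cat_sum("legume"),
    red_meat = cat_sum("red_meat"),
    processed_meat = cat_sum("processed_meat"))
}

#' Log-linear relative risk at a given exposure change
#'
#' The exposure-response is log-linear: risk scales as `rr^(delta/unit)`
#' in the stated direction. For a pair stated per unit *increase* the
#' log-risk slope is `log(rr)/unit_g`; for one stated per unit *decrease*
#' the sign flips, so that moving in the stated beneficial direction is
#' protective.
#'
#' @param rr central relative risk per `unit_g` change (> 0).
#' @param unit_g stated unit change in grams (100 or 50 in the packaged
#'   table).
#' @param direction `"increase"` or `"decrease"`: the direction of intake
#'   change the stated `rr` refers to.
#' @param delta_g signed intake change in g/day (positive = increase).
#' @return the relative risk applying at `delta_g`.
#' @export
log_linear_rr <- function(rr, unit_g, direction, delta_g) {
  if (any(rr <= 0)) stop("relative risk must be > 0")
  beta <- ifelse(direction == "increase", log(rr), -log(rr)) / unit_g
  exp(beta * delta_g)
}

#' Combine relative risks acting on one outcome
#'
#' Where several dietary exposures affect the same disease the risks are
#' multiplied together.
#'
#' @param rrs numeric vector of relative risks (> 0); may be empty.
#' @return the product (1 for an empty input).
#' @export
combine_rr <- function(rrs) {
  if (length(rrs) == 0L) return(1)
  stopifnot(all(rrs > 0))
  prod(rrs)
}

#' Time-lag profile for an outcome class
#'
#' Effects phase in over time following an S-shaped (normal CDF) curve.
#' Cardiometabolic outcomes (ischemic heart disease, ischemic stroke,
#' type 2 diabetes) reach full effect after 10 years; cancers after
#' 30 years with no effect at all in the first 10. The normal mean sits at
#' the midpoint of the ramp and the SD is ramp/5.164 so the weight is
#' about 0.005 at the start of the ramp and 0.995 at its end.
#'
#' @param outcome_class `"cardiometabolic"` or `"cancer"`.
#' @return list with `zero_years`, `max_years`, `mean`, `sd`.
#' @export
lag_profile <- function(outcome_class = c("cardiometabolic", "cancer")) {
  outcome_class <- match.arg(outcome_class)
  if (outcome_class == "cardiometabolic") {
    zero <- 0; maxy <- 10
  } else {
    zero <- 10; maxy <- 30
  }
  list(outcome_class = outcome_class, zero_years = zero, max_years = maxy,
       mean = (zero + maxy) / 2, sd = (maxy - zero) / 5.164)
}

#' Lag weight at a given time since dietary change
#'
#' @param t years since adoption (>= 0); vectorized.
#' @param profile a [lag_profile()].
#' @return weight in \[0, 1\], 0 before `zero_years`, ~1 at `max_years`.
#' @export
lag_weight <- function(t, profile) {
  stopifnot(all(t >= 0))
  w <- stats::pnorm((t - profile$mean) / profile$sd)
  w[t < profile$zero_years] <- 0
  w
}

outcome_class_of <- function(outcome) {
  ifelse(outcome %in% c("IHD", "ischemic_stroke", "T2D"),
         "cardiometabolic", "cancer")
}

#' Final and time-resolved relative risks for a set of exposure changes
#'
#' Evaluates the log-linear exposure-response for every risk-disease pair
#' at the supplied intake changes, multiplies risks acting on the same
#' outcome, and phases the combined log-risk in over time with the
#' outcome-class lag curve evaluated at mid-year:
#' `RR(outcome, year) = exp(log(RR_final) * w(year - 0.5))`.
#'
#' @param deltas named exposure changes as from [delta_exposures()].
#' @param er exposure-response table (default packaged).
#' @param horizon_years number of annual cycles.
#' @param scenario `"central"` (point estimates), `"low"` (lower CI
#'   bounds) or `"high"` (upper CI bounds).
#' @return list with `final` (named vector of combined RR per outcome) and
#'   `schedule` (outcomes x years matrix of RR(t)).
#' @export
rr_schedule <- function(deltas, er = exposure_response(),
                        horizon_years = 120,
                        scenario = c("central", "low", "high")) {
  scenario <- match.arg(scenario)
  validate_exposure_response(er)
  rr_col <- switch(scenario, central = er$rr, low = er$ci_low,
                   high = er$ci_high)
  delta <- deltas[er$exposure]
  delta[is.na(delta)] <- 0
  per_pair <- log_linear_rr(rr_col, er$unit_g, er$direction, delta)
  final <- vapply(HEALTH_OUTCOMES, function(o)
    combine_rr(per_pair[er$outcome == o]), numeric(1))
  t_mid <- seq_len(horizon_years) - 0.5
  schedule <- t(vapply(HEALTH_OUTCOMES, function(o) {
    w <- lag_weight(t_mid, lag_profile(outcome_class_of(o)))
    exp(log(final[[o]]) * w)
  }, numeric(horizon_years)))
  rownames(schedule) <- HEALTH_OUTCOMES
  list(final = final, schedule = schedule)
}

#' Validate an age/sex population and mortality table
#'
#' @param pop data.frame with columns `sex` (`male`/`female`), `age`
#'   (integer years 0..top, top open-ended), `population`,
#'   `all_cause_rate` and one cause-rate column per outcome in
#'   `r paste(HEALTH_OUTCOMES, collapse = ", ")` (deaths/person/year).
#' @return `pop` invisibly.
#' @export
validate_population <- function(pop) {
  need <- c("sex", "age", "population", "all_cause_rate", HEALTH_OUTCOMES)
  missing <- setdiff(need, names(pop))
  if (length(missing) > 0L)
    stop("population table missing columns: ",
         paste(missing, collapse = ", "))
  stopifnot(all(pop$sex %in% c("male", "female")),
            all(pop$age == round(pop$age)), all(pop$age >= 0),
            all(pop$population >= 0), all(pop$all_cause_rate >= 0))
  cause_sum <- rowSums(pop[, HEALTH_OUTCOMES, drop = FALSE])
  if (any(pop[, HEALTH_OUTCOMES] < 0))
    stop("cause-specific rates must be >= 0")
  if (any(cause_sum > pop$all_cause_rate + 1e-12))
    stop("cause-specific rates exceed the all-cause rate at age(s) ",
         paste(head(pop$age[cause_sum > pop$all_cause_rate + 1e-12], 5),
               collapse = ", "))
  for (s in c("male", "female")) {
    ages <- sort(pop$age[pop$sex == s])
    if (length(ages) && !isTRUE(all(ages == seq(min(ages), max(ages)))))
      stop("ages for sex '", s, "' must form a contiguous integer grid")
  }
  invisible(pop)
}

#' Impacted all-cause mortality schedule
#'
#' Applies outcome-specific relative risks to the cause-specific mortality
#' rates and subtracts the averted deaths from the all-cause rate:
#' `m'(age, t) = m(age) - sum_o cause_rate_o(age) * (1 - RR_o(t))`.
#' Baseline rates are held constant over follow-up.
#'
#' @param pop_sex population table rows for a single sex, ordered by age.
#' @param schedule outcomes x years matrix of RR(t) (see [rr_schedule()]).
#' @return ages x years matrix of adjusted all-cause rates.
#' @export
impacted_mortality <- function(pop_sex, schedule) {
  m <- pop_sex$all_cause_rate
  cr <- as.matrix(pop_sex[, HEALTH_OUTCOMES, drop = FALSE])
  # averted(age, t) = sum_o cr[age, o] * (1 - RR[o, t])
  averted <- cr %*% (1 - schedule[HEALTH_OUTCOMES, , drop = FALSE])
  out <- matrix(m, nrow = length(m), ncol = ncol(schedule)) - averted
  if (any(out < -1e-12))
    stop("impacted all-cause rate fell below zero; inputs impossible")
  pmax(out, 0)
}

# Extend an age-indexed vector/matrix past the top (open-ended) age group
# by repeating the top-age value, so cohorts can age beyond it.
extend_ages <- function(x, extra) {
  if (is.matrix(x)) rbind(x, x[rep(nrow(x), extra), , drop = FALSE])
  else c(x, rep(x[length(x)], extra))
}

#' Run an annual-cycle life table
#'
#' Ages a starting population forward through annual cycles under a
#' (possibly time-varying) mortality schedule. Hazards convert to annual
#' death probabilities via `q = 1 - exp(-m)`; survivors move up one age;
#' deaths are credited half a year of person-time; no in-migration or
#' births. Ages beyond the top input age use the top age's rates.
#'
#' @param start_pop numeric vector of persons by age (age 0 first).
#' @param m_schedule either a numeric vector of age-specific rates (held
#'   constant over time) or an ages x years matrix.
#' @param horizon_years number of annual cycles (default 120 so every
#'   cohort closes out).
#' @return list with `person_years` (by calendar year),
#'   `total_person_years`, and `survivors` (final population by age).
#' @export
run_life_table <- function(start_pop, m_schedule, horizon_years = 120) {
  n_age <- length(start_pop)
  if (is.matrix(m_schedule)) {
    stopifnot(nrow(m_schedule) == n_age)
    horizon_years <- min(horizon_years, ncol(m_schedule))
    get_m <- function(t) m_ext[, t]
    m_ext <- extend_ages(m_schedule, horizon_years)
  } else {
    stopifnot(length(m_schedule) == n_age)
    m_vec <- extend_ages(m_schedule, horizon_years)
    get_m <- function(t) m_vec
  }
  stopifnot(all(get_m(1) >= 0))
  N <- c(start_pop, numeric(horizon_years))
  py <- numeric(horizon_years)
  for (t in seq_len(horizon_years)) {
    q <- 1 - exp(-get_m(t))
    d <- N * q
    py[t] <- sum(N - d) + sum(d) / 2
    N <- c(0, (N - d)[-length(N)])
  }
  list(person_years = py, total_person_years = sum(py),
       survivors = N)
}

#' Life expectancy at birth under an age-specific mortality schedule
#'
#' Follows a birth cohort through [run_life_table()]; life expectancy is
#' the cohort's expected life-years divided by its starting size.
#'
#' @param m age-specific all-cause rates (vector, age 0 first) or an
#'   ages x years matrix of time-varying rates experienced by a cohort
#'   born at time zero.
#' @param horizon_years annual cycles (default 120).
#' @return life expectancy at birth in years.
#' @export
life_expectancy_at_birth <- function(m, horizon_years = 120) {
  if (is.matrix(m)) {
    # Cohort born at t = 0 is age t-1 in year t: pick the diagonal.
    H <- min(horizon_years, ncol(m))
    m_ext <- extend_ages(m, max(0, H - nrow(m)))
    m <- m_ext[cbind(seq_len(H), seq_len(H))]
  } else {
    m <- extend_ages(m, horizon_years)[seq_len(horizon_years)]
  }
  run_life_table(c(1, numeric(length(m) - 1)),
                 m, horizon_years = length(m))$total_person_years
}
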