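test_that("packaged exposure-response table has the 13 expected pairs", {
  er <- exposure_response()
  expect_equal(nrow(er), 13)
  expect_true(all(er$ci_low <= er$rr & er$rr <= er$ci_high))
  row <- er[er$exposure == "fruit" & er$outcome == "IHD", ]
  expect_equal(row$rr, 0.86)
  expect_equal(c(row$ci_low, row$ci_high), c(0.79, 0.95))
  expect_equal(row$unit_g, 100)
  expect_equal(sum(er$direction == "decrease"), 5)  # the meat rows
})

test_that("log-linear exposure-response scales risk per gram", {
  expect_equal(log_linear_rr(0.86, 100, "increase", 100), 0.86)
  expect_equal(log_linear_rr(0.86, 100, "increase", 0), 1)
  expect_equal(log_linear_rr(0.86, 100, "increase", 50),
               exp(0.5 * log(0.86)))
  # stated per decrease: decreasing intake is protective
  expect_equal(log_linear_rr(0.56, 50, "decrease", -50), 0.56)
  expect_gt(log_linear_rr(0.56, 50, "decrease", 50), 1)
  expect_error(log_linear_rr(-0.5, 100, "increase", 10), "> 0")
})

test_that("risks on the same outcome multiply", {
  expect_equal(combine_rr(numeric(0)), 1)
  expect_equal(combine_rr(c(0.86, 0.86, 0.76)), 0.86 * 0.86 * 0.76)
  expect_equal(combine_rr(c(0.86, 0.86, 0.76)), 0.5621, tolerance = 1e-4)
  expect_equal(combine_rr(c(0.9, 1)), combine_rr(0.9))
})

test_that("lag weights follow the stated S-curves", {
  cardio <- lag_profile("cardiometabolic")
  expect_lt(lag_weight(0, cardio), 0.01)
  expect_equal(lag_weight(5, cardio), 0.5)
  expect_gte(lag_weight(10, cardio), 0.99)

  cancer <- lag_profile("cancer")
  expect_equal(lag_weight(9, cancer), 0)
  expect_equal(lag_weight(c(0, 5, 9.999), cancer), c(0, 0, 0))
  expect_gte(lag_weight(30, cancer), 0.99)

  t <- seq(0, 40, by = 0.25)
  for (p in list(cardio, cancer)) {
    w <- lag_weight(t, p)
    expect_true(all(w >= 0 & w <= 1))
    expect_true(all(diff(w) >= 0))
  }
})

test_that("exposure deltas aggregate categories and exclude poultry", {
  foods <- paper_fixture()$foods
  base <- baseline_diet(foods)
  expect_equal(unname(delta_exposures(base, base, foods)), rep(0, 5))

  opt <- optimize_pathway(base, foods, pathway_spec("FV_ALL"))
  d <- delta_exposures(base, opt$diet, foods)
  expect_equal(d[["fruit"]], 88 * (400 / 228 - 1), tolerance = 1e-6)
  expect_lt(d[["red_meat"]], 0)

  po <- base
  poultry_id <- foods$id[foods$category == "poultry"][1]
  po[poultry_id] <- po[poultry_id] + 50
  expect_equal(unname(delta_exposures(base, as_diet(po, foods), foods)),
               rep(0, 5))
})

test_that("impacted mortality subtracts averted cause-specific deaths", {
  pop <- toy_population(m = c(0.01, 0.02, 0.05), sexes = "male")
  sched <- matrix(1, nrow = 6, ncol = 3,
                  dimnames = list(c("IHD", "ischemic_stroke", "T2D",
                                    "colorectal_cancer", "lung_cancer",
                                    "esophageal_cancer"), NULL))
  expect_equal(impacted_mortality(pop, sched),
               matrix(c(0.01, 0.02, 0.05), 3, 3))

  pop2 <- toy_population(m = 0.01, pop = 100, ihd_frac = 0.2,
                         sexes = "male")
  pop2$IHD <- 0.002
  sched2 <- sched[, 1, drop = FALSE] * 1
  sched2["IHD", ] <- 0.8
  expect_equal(impacted_mortality(pop2, sched2)[1, 1], 0.01 - 0.0004)

  sched2["IHD", ] <- 1.5  # harmful change raises the rate
  expect_gt(impacted_mortality(pop2, sched2)[1, 1], 0.01)

  pop2$IHD <- 0.01
  sched2["IHD", ] <- -2
  expect_error(impacted_mortality(pop2, sched2))
})

test_that("constant-hazard life expectancy matches the closed form", {
  mu <- 0.01
  le <- life_expectancy_at_birth(rep(mu, 101), horizon_years = 2000)
  expect_equal(le, 1 / mu, tolerance = 0.005)

  # zero mortality: person-years = population x horizon
  lt <- run_life_table(c(10, 20), c(0, 0), horizon_years = 50)
  expect_equal(lt$total_person_years, 30 * 50)

  # identical schedules give exactly zero gain
  m <- c(0.02, 0.1, 0.4)
  a <- run_life_table(c(5, 5, 5), m, 30)
  b <- run_life_table(c(5, 5, 5), m, 30)
  expect_identical(a$person_years, b$person_years)
})

test_that("life table matches hand-enumerated survival on a 3-age cohort", {
  # cohort of 1 newborn; rates 0.1, 0.2, 10 (third year ~closes out)
  m <- c(0.1, 0.2, 10)
  p1 <- exp(-0.1); p2 <- exp(-0.2); p3 <- exp(-10)
  py1 <- p1 + (1 - p1) / 2
  py2 <- p1 * p2 + p1 * (1 - p2) / 2
  py3 <- p1 * p2 * p3 + p1 * p2 * (1 - p3) / 2
  lt <- run_life_table(c(1, 0, 0), m, horizon_years = 3)
  expect_equal(lt$person_years, c(py1, py2, py3), tolerance = 1e-9)
  expect_equal(life_expectancy_at_birth(m, horizon_years = 3),
               py1 + py2 + py3, tolerance = 1e-9)
})

test_that("null dietary change produces exactly zero impact", {
  fx <- paper_fixture()
  base <- baseline_diet(fx$foods)
  hi <- health_impact(base, base, fx$foods, fx$population,
                      horizon_years = 40)
  expect_equal(hi$total_life_years_gained, 0)
  expect_equal(unname(hi$delta_le_months), c(0, 0))
  expect_true(all(hi$rr_final == 1))
})

test_that("protective deltas give positive gains that grow with the delta", {
  fx <- paper_fixture()
  foods <- fx$foods
  base <- baseline_diet(foods)
  bump <- function(extra) {
    d <- base
    fruit_ids <- foods$id[foods$category == "fruit" & foods$counts_5aday]
    d[fruit_ids] <- d[fruit_ids] * (1 + extra)
    as_diet(d, foods)
  }
  h1 <- health_impact(base, bump(0.3), foods, fx$population,
                      horizon_years = 60)
  h2 <- health_impact(base, bump(0.6), foods, fx$population,
                      horizon_years = 60)
  expect_gt(h1$delta_le_months_combined, 0)
  expect_gt(h1$total_life_years_gained, 0)
  expect_gt(h2$delta_le_months_combined, h1$delta_le_months_combined)
  expect_gt(h2$total_life_years_gained, h1$total_life_years_gained)
})

test_that("instant effects bound lagged effects for protective changes", {
  pop <- paper_fixture()$population
  ps <- pop[pop$sex == "female", ]
  ps <- ps[order(ps$age), ]
  H <- 60
  rr_final <- c(IHD = 0.9, ischemic_stroke = 0.95, T2D = 0.97,
                colorectal_cancer = 0.95, lung_cancer = 0.96,
                esophageal_cancer = 0.98)
  lagged <- t(vapply(names(rr_final), function(o) {
    cls <- if (o %in% c("IHD", "ischemic_stroke", "T2D"))
      "cardiometabolic" else "cancer"
    exp(log(rr_final[[o]]) * lag_weight(seq_len(H) - 0.5,
                                        lag_profile(cls)))
  }, numeric(H)))
  instant <- matrix(rr_final, nrow = 6, ncol = H,
                    dimnames = list(names(rr_final), NULL))
  le0 <- life_expectancy_at_birth(ps$all_cause_rate, H)
  le_lag <- life_expectancy_at_birth(impacted_mortality(ps, lagged), H)
  le_inst <- life_expectancy_at_birth(impacted_mortality(ps, instant), H)
  expect_gte(le_lag, le0)
  expect_gte(le_inst, le_lag)
})

test_that("CI scenarios bracket the central estimate on random protective tables", {
  fx <- paper_fixture()
  foods <- fx$foods
  base <- baseline_diet(foods)
  opt <- optimize_pathway(base, foods, pathway_spec("FV_ALL"))
  set.seed(99)
  for (i in 1:4) {
    er <- exposure_response()
    # random protective tables: rr < 1 with random CI widths
    er$rr <- runif(nrow(er), 0.55, 0.98)
    er$ci_low <- er$rr * runif(nrow(er), 0.7, 1)
    er$ci_high <- pmin(er$rr / runif(nrow(er), 0.7, 1), 1.5)
    hl <- health_impact(base, opt$diet, foods, fx$population, er,
                        horizon_years = 60, scenario = "low")
    hc <- health_impact(base, opt$diet, foods, fx$population, er,
                        horizon_years = 60, scenario = "central")
    hh <- health_impact(base, opt$diet, foods, fx$population, er,
                        horizon_years = 60, scenario = "high")
    expect_gte(hl$delta_le_months_combined, hc$delta_le_months_combined)
    expect_gte(hc$delta_le_months_combined, hh$delta_le_months_combined)
  }
})

test_that("sensitivity bounds collapse when the CI collapses", {
  fx <- paper_fixture()
  foods <- fx$foods
  base <- baseline_diet(foods)
  opt <- optimize_pathway(base, foods, pathway_spec("VEG_ALL"))
  er <- exposure_response()
  er$ci_low <- er$rr; er$ci_high <- er$rr
  out <- lapply(c("low", "central", "high"), function(sc)
    health_impact(base, opt$diet, foods, fx$population, er,
                  horizon_years = 50, scenario = sc))
  expect_equal(out[[1]]$delta_le_months_combined,
               out[[2]]$delta_le_months_combined)
  expect_equal(out[[2]]$delta_le_months_combined,
               out[[3]]$delta_le_months_combined)
})

test_that("attribution is 1 without meat changes and 0 without F&V changes", {
  fx <- paper_fixture()
  foods <- fx$foods
  base <- baseline_diet(foods)

  fruit_only <- base
  ids <- foods$id[foods$category == "fruit" & foods$counts_5aday]
  fruit_only[ids] <- fruit_only[ids] * 1.5
  expect_equal(attribution_fv(base, as_diet(fruit_only, foods), foods,
                              fx$population, horizon_years = 50), 1)

  meat_only <- base
  mid <- foods$id[foods$category == "red_meat"]
  meat_only[mid] <- meat_only[mid] * 0.5
  expect_equal(attribution_fv(base, as_diet(meat_only, foods), foods,
                              fx$population, horizon_years = 50), 0)

  expect_warning(
    out <- attribution_fv(base, base, foods, fx$population,
                          horizon_years = 50), "undefined")
  expect_true(is.na(out))
})
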