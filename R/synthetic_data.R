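# Named fruit and vegetable groups pinned in the calibrated fixture, with
# their baseline national-average intakes (g/person/day).  Together they
# provide ~90% of their categories, with heavy tails (bananas alone are 27%
# of fruit), matching the skew of national dietary survey intakes.
PINNED_FRUIT <- c(
  bananas = 23.84, apples = 18.27, pears = 5.64, oranges = 5.32,
  tangerines = 5.32, grapes = 5.12, strawberries = 4.72,
  canned_fruit = 1.91, melons = 1.83, pineapple = 1.61, blueberries = 1.44,
  mangoes = 1.43, nectarines = 1.29, plums = 1.20)
PINNED_FRUIT_UK <- c("apples", "pears", "strawberries", "blueberries",
                     "plums")
PINNED_VEG <- c(
  tomatoes = 24.93, onions = 13.88, carrots = 13.57, peas = 8.18,
  broccoli = 6.57, peppers = 5.85, cucumber = 4.83, mushrooms = 4.56,
  lettuce = 4.14, cabbage = 3.72, cauliflower = 2.93, green_beans = 2.74,
  sweet_corn = 2.46, sweet_potato = 1.63, spinach = 1.51, parsnips = 1.50,
  mixed_leaf_salad = 1.44, leeks = 1.42)
PINNED_VEG_NON_UK <- c("peppers", "sweet_potato")
PINNED_LEGUME <- c(baked_beans = 15.47, other_beans = 2.47, lentils = 1.55)

# Energy-density ranges (kcal/g), price medians (GBP/kg) and footprint
# factor levels (kg CO2eq/kg; L/kg for UK vs foreign origins) by category.
# Documented assumptions on the order of magnitude of LCA literature; the
# whole-diet totals are subsequently calibrated exactly, so only the
# relative structure of these levels matters.
GEN_ENERGY_RANGE <- list(
  fruit = c(0.3, 0.9), vegetable = c(0.2, 0.8), legume = c(0.7, 1.2),
  sweet_snack = c(3.5, 5.5), red_meat = c(1.8, 3.0),
  processed_meat = c(2.0, 3.5), poultry = c(1.5, 2.5), other = c(0.5, 3.5))
GEN_PRICE_MEDIAN <- c(
  fruit = 2.5, vegetable = 2.0, legume = 1.5, sweet_snack = 6,
  red_meat = 8, processed_meat = 7, poultry = 5, other = 4)
GEN_GHGE_BASE <- c(
  fruit = 1.1, vegetable = 1.7, legume = 1.0, sweet_snack = 3,
  red_meat = 25, processed_meat = 12, poultry = 6, other = 2)
GEN_WF_UK <- c(
  fruit = 60, vegetable = 40, legume = 120, sweet_snack = 350,
  red_meat = 450, processed_meat = 400, poultry = 280, other = 180)
GEN_WF_FOREIGN <- c(
  fruit = 300, vegetable = 200, legume = 350, sweet_snack = 450,
  red_meat = 600, processed_meat = 520, poultry = 380, other = 260)

# Daily energy budgets (kcal/person/day) for the substitution pools; sized
# so sweet snacks and meat can absorb the fruit/vegetable energy swaps with
# headroom, as in observed national diets.
GEN_ENERGY_BUDGET <- c(sweet_snack = 170, red_meat = 120,
                       processed_meat = 80, poultry = 70)

#' Configuration for the synthetic input generator
#'
#' Defaults state the emulated world: 48 fruit, 64 vegetable (including
#' legumes) and 153 other food groups, and baseline whole-diet aggregates
#' of 88 g fruit, 140 g vegetables, 1744 kcal, 6.78 GBP, 6.2 kg CO2eq and
#' 611.4 L of blue water per person per day.
#'
#' @param seed integer seed; the same seed and configuration produce
#'   bit-identical outputs.
#' @param n_fruit,n_veg,n_other food-group counts per block (`n_veg`
#'   includes the legume groups).
#' @param targets named list of baseline aggregates to calibrate to:
#'   `fruit_g`, `veg_g` (vegetables including legumes), `energy_kcal`,
#'   `cost_gbp`, `ghge_kg`, `wf_l`.
#' @param calibration `"paper"` pins the named major fruit and vegetable
#'   groups at their published intakes; `"none"` draws all intakes.
#' @param uk_capable_fraction probability that an unnamed fruit
#'   (resp. vegetable) group is UK-capable.
#' @param max_foreign_origins foreign origins per fruit/vegetable food
#'   (1 to this many, plus the UK).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_fruit = 48L, n_veg = 64L,
                             n_other = 153L,
                             targets = list(fruit_g = 88, veg_g = 140,
                                            energy_kcal = 1744,
                                            cost_gbp = 6.78, ghge_kg = 6.2,
                                            wf_l = 611.4),
                             calibration = c("paper", "none"),
                             uk_capable_fraction = c(fruit = 0.3,
                                                     vegetable = 0.7),
                             max_foreign_origins = 3L) {
  calibration <- match.arg(calibration)
  stopifnot(n_fruit >= 16, n_veg >= 24, n_other >= 10,
            all(unlist(targets) > 0))
  structure(list(seed = as.integer(seed), n_fruit = as.integer(n_fruit),
                 n_veg = as.integer(n_veg), n_other = as.integer(n_other),
                 targets = targets, calibration = calibration,
                 uk_capable_fraction = uk_capable_fraction,
                 max_foreign_origins = as.integer(max_foreign_origins)),
            class = "generator_config")
}

# Evaluate expr under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# Right-skewed positive draws summing (after rescale) to a category total.
rlnorm_scaled <- function(n, total, sdlog = 1) {
  if (n == 0L) return(numeric(0))
  x <- stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
  x / sum(x) * total
}

#' Generate a synthetic food-group table
#'
#' Draws per-food intakes (log-normal, right-skewed), energy densities
#' (uniform in category-plausible ranges), prices and footprint levels,
#' then rescales so the category and whole-diet aggregates hit the
#' configured targets exactly. The table contains a fruit-juice and a
#' potato group flagged as not counting toward 5-a-day, legume groups
#' inside the vegetable block, and sweet-snack and meat pools with enough
#' energy to absorb the pathway substitutions. Footprint columns are
#' placeholders until [generate_trade_shares()] supplies trade-weighted
#' values; [generate_inputs()] runs the full calibrated sequence.
#'
#' @param config a [generator_config()].
#' @return validated food table.
#' @export
generate_food_table <- function(config) {
  with_seed(config$seed, generate_food_table_impl(config))
}

generate_food_table_impl <- function(config) {
  tg <- config$targets
  pin <- config$calibration == "paper"

  pinned_fruit_g <- if (pin) PINNED_FRUIT else
    rlnorm_scaled(length(PINNED_FRUIT), tg$fruit_g * 0.9)
  pinned_veg_g <- if (pin) PINNED_VEG else
    rlnorm_scaled(length(PINNED_VEG), (tg$veg_g - sum(PINNED_LEGUME)) * 0.88)
  pinned_leg_g <- if (pin) PINNED_LEGUME else
    rlnorm_scaled(length(PINNED_LEGUME), sum(PINNED_LEGUME))
  names(pinned_fruit_g) <- names(PINNED_FRUIT)
  names(pinned_veg_g) <- names(PINNED_VEG)
  names(pinned_leg_g) <- names(PINNED_LEGUME)

  n_fruit_free <- config$n_fruit - length(pinned_fruit_g) - 1L  # - juice
  n_leg_free <- 2L
  n_veg_free <- config$n_veg - length(pinned_veg_g) -
    length(pinned_leg_g) - n_leg_free - 1L                      # - potato
  stopifnot(n_fruit_free > 0, n_veg_free > 0)

  free_fruit_g <- rlnorm_scaled(n_fruit_free,
                                tg$fruit_g - sum(pinned_fruit_g))
  free_veg_g <- rlnorm_scaled(
    n_veg_free, tg$veg_g - sum(pinned_leg_g) - sum(pinned_veg_g))

  row_block <- function(ids, category, counts, uk, intake) {
    data.frame(id = ids, name = gsub("_", " ", ids), category = category,
               counts_5aday = counts, uk_capable = uk,
               baseline_intake_g = intake, energy_density_kcal_per_g = 0,
               price_gbp_per_kg = 0, ghge_kgco2e_per_kg = 0,
               bluewf_l_per_kg = 0, stringsAsFactors = FALSE)
  }
  foods <- rbind(
    row_block(names(pinned_fruit_g), "fruit", TRUE,
              names(pinned_fruit_g) %in% PINNED_FRUIT_UK, pinned_fruit_g),
    row_block(sprintf("fruit_%02d", seq_len(n_fruit_free)), "fruit", TRUE,
              stats::runif(n_fruit_free) <
                config$uk_capable_fraction[["fruit"]], free_fruit_g),
    row_block("fruit_juice", "fruit", FALSE, FALSE, 70),
    row_block(names(pinned_veg_g), "vegetable", TRUE,
              !(names(pinned_veg_g) %in% PINNED_VEG_NON_UK), pinned_veg_g),
    row_block(sprintf("veg_%02d", seq_len(n_veg_free)), "vegetable", TRUE,
              stats::runif(n_veg_free) <
                config$uk_capable_fraction[["vegetable"]], free_veg_g),
    row_block("potatoes", "vegetable", FALSE, TRUE, 60),
    row_block(names(pinned_leg_g), "legume", TRUE, TRUE, pinned_leg_g),
    row_block(sprintf("legume_%02d", seq_len(n_leg_free)), "legume", TRUE,
              TRUE, 0),
    other_blocks(config)
  )
  rownames(foods) <- NULL

  rng <- function(cat) GEN_ENERGY_RANGE[[cat]]
  foods$energy_density_kcal_per_g <- vapply(seq_len(nrow(foods)),
    function(i) {
      r <- rng(foods$category[i])
      stats::runif(1, r[1], r[2])
    }, numeric(1))
  foods$energy_density_kcal_per_g[foods$id == "fruit_juice"] <- 0.45
  foods$energy_density_kcal_per_g[foods$id == "potatoes"] <- 0.80

  # Fix non-F&V intakes by category energy budget; the residual budget
  # goes to 'other' so the whole diet lands exactly on the energy target.
  e <- foods$energy_density_kcal_per_g
  fv <- foods$category %in% c("fruit", "vegetable", "legume")
  e_fv <- sum(foods$baseline_intake_g[fv] * e[fv])
  budgets <- c(GEN_ENERGY_BUDGET,
               other = tg$energy_kcal - e_fv - sum(GEN_ENERGY_BUDGET))
  if (budgets[["other"]] <= 0)
    stop("energy target unreachable: fruit and vegetable energy exceeds ",
         "the whole-diet target")
  for (cat in names(budgets)) {
    i <- foods$category == cat
    raw <- stats::rlnorm(sum(i), 0, 1)
    foods$baseline_intake_g[i] <- raw / sum(raw * e[i]) * budgets[[cat]]
  }

  foods$price_gbp_per_kg <- GEN_PRICE_MEDIAN[foods$category] *
    stats::rlnorm(nrow(foods), 0, 0.4)
  cost_raw <- sum(foods$baseline_intake_g / 1000 * foods$price_gbp_per_kg)
  foods$price_gbp_per_kg <- foods$price_gbp_per_kg * tg$cost_gbp / cost_raw

  # Provisional single-origin footprints; trade weighting and exact
  # calibration happen in generate_inputs().
  foods$ghge_kgco2e_per_kg <- GEN_GHGE_BASE[foods$category] *
    stats::rlnorm(nrow(foods), 0, 0.3)
  foods$bluewf_l_per_kg <- GEN_WF_UK[foods$category] *
    stats::rlnorm(nrow(foods), 0, 0.3)
  validate_foods(foods)
  foods
}

other_blocks <- function(config) {
  n_other_free <- config$n_other - 15L - 10L - 10L - 6L
  stopifnot(n_other_free > 0)
  blk <- function(prefix, n, category)
    data.frame(id = sprintf("%s_%02d", prefix, seq_len(n)),
               name = sprintf("%s %02d", gsub("_", " ", prefix), seq_len(n)),
               category = category, counts_5aday = FALSE, uk_capable = FALSE,
               baseline_intake_g = 1, energy_density_kcal_per_g = 0,
               price_gbp_per_kg = 0, ghge_kgco2e_per_kg = 0,
               bluewf_l_per_kg = 0, stringsAsFactors = FALSE)
  rbind(blk("sweet_snack", 15L, "sweet_snack"),
        blk("red_meat", 10L, "red_meat"),
        blk("processed_meat", 10L, "processed_meat"),
        blk("poultry", 6L, "poultry"),
        blk("other", n_other_free, "other"))
}

#' Generate synthetic trade shares and origin-specific footprints
#'
#' Fruit, vegetable and legume groups are supplied from the UK plus one to
#' three foreign origins with Dirichlet-distributed shares (UK-capable
#' foods lean domestic); other foods have a single UK or GLOBAL origin.
#' UK origins draw lower blue-water factors than foreign ones, because
#' domestic production relies more on rainfall.
#'
#' @param config a [generator_config()].
#' @param foods a generated food table.
#' @return trade-share table (`food_id`, `origin`, `share`,
#'   `ghge_kgco2e_per_kg`, `bluewf_l_per_kg`).
#' @export
generate_trade_shares <- function(config, foods) {
  with_seed(config$seed + 1L, generate_trade_shares_impl(config, foods))
}

generate_trade_shares_impl <- function(config, foods) {
  origin_pool <- c("ES", "NL", "FR", "IT", "MA", "ZA", "PE", "CR")
  rows <- lapply(seq_len(nrow(foods)), function(i) {
    cat <- foods$category[i]
    fid <- foods$id[i]
    if (!(cat %in% c("fruit", "vegetable", "legume")))
      return(data.frame(food_id = fid,
                        origin = if (cat == "other") "GLOBAL" else "UK",
                        share = 1,
                        ghge_kgco2e_per_kg = foods$ghge_kgco2e_per_kg[i],
                        bluewf_l_per_kg = foods$bluewf_l_per_kg[i],
                        stringsAsFactors = FALSE))
    k <- sample(seq_len(config$max_foreign_origins), 1L)
    origins <- c("UK", sample(origin_pool, k))
    alpha <- c(if (foods$uk_capable[i]) 4 else 0.8, rep(1.5, k))
    g <- stats::rgamma(k + 1L, shape = alpha)
    share <- g / sum(g)
    ghge <- GEN_GHGE_BASE[[cat]] * stats::rlnorm(k + 1L, 0, 0.25)
    wf <- c(GEN_WF_UK[[cat]] * stats::rlnorm(1, 0, 0.25),
            GEN_WF_FOREIGN[[cat]] * stats::rlnorm(k, 0, 0.25))
    data.frame(food_id = fid, origin = origins, share = share,
               ghge_kgco2e_per_kg = ghge, bluewf_l_per_kg = wf,
               stringsAsFactors = FALSE)
  })
  trade <- do.call(rbind, rows)
  rownames(trade) <- NULL
  validate_trade(trade)
  trade
}

#' Generate a synthetic age/sex population with mortality rates
#'
#' Ages 0-100 per sex. All-cause mortality follows a Gompertz-Makeham law
#' with sex-specific parameters tuned to a life expectancy at birth near
#' 79.5 years (males) and 83 years (females). Cause-specific rates for the
#' six modeled outcomes are smooth, age-increasing fractions of all-cause
#' mortality (normal-CDF ramps) whose maxima sum to about 0.31, so the
#' cause-sum constraint holds at every age. Population counts follow the
#' stationary (survival-proportional) age structure scaled to a 66.65
#' million total, with mild log-normal jitter.
#'
#' @param config a [generator_config()].
#' @param total_population persons across both sexes (default 66,650,000).
#' @return population table passing [validate_population()].
#' @export
generate_population <- function(config, total_population = 66650000) {
  with_seed(config$seed + 2L, {
    ages <- 0:100
    gm <- function(a, A, B, G) A + B * exp(G * a)
    fractions <- function(a) cbind(
      IHD = 0.15 * stats::pnorm((a - 60) / 15),
      ischemic_stroke = 0.05 * stats::pnorm((a - 70) / 12),
      T2D = 0.015 * stats::pnorm((a - 60) / 15),
      colorectal_cancer = 0.027 * stats::pnorm((a - 55) / 12),
      lung_cancer = 0.055 * stats::pnorm((a - 55) / 10),
      esophageal_cancer = 0.013 * stats::pnorm((a - 60) / 12))
    one_sex <- function(sex, A, B, G) {
      m <- gm(ages, A, B, G)
      lx <- cumprod(c(1, exp(-m[-length(m)])))   # survival to each age
      n_raw <- lx * stats::rlnorm(length(ages), 0, 0.02)
      pop <- n_raw / sum(n_raw) * total_population / 2
      cr <- fractions(ages) * m
      cbind(data.frame(sex = sex, age = ages, population = pop,
                       all_cause_rate = m, stringsAsFactors = FALSE),
            as.data.frame(cr))
    }
    pop <- rbind(one_sex("male", 2.5e-4, 1.6e-5, 0.103),
                 one_sex("female", 1.6e-4, 1.0e-5, 0.105))
    rownames(pop) <- NULL
    validate_population(pop)
    pop
  })
}

#' Generate the full calibrated synthetic input set
#'
#' Runs the whole generator sequence: food table, trade shares, trade
#' weighting of the footprint columns, exact multiplicative calibration of
#' the GHGE and blue-water totals to the configured targets (applied to
#' both the food table and the origin factors, so they stay consistent),
#' and the population table. The baseline aggregates of the result
#' reproduce the configured targets to floating-point accuracy.
#'
#' @param config a [generator_config()].
#' @param total_population persons across both sexes.
#' @return list with elements `foods`, `trade`, `population`, `er`
#'   (the packaged exposure-response table) and `config`.
#' @export
generate_inputs <- function(config = generator_config(),
                            total_population = 66650000) {
  foods <- generate_food_table(config)
  trade <- generate_trade_shares(config, foods)
  foods <- apply_trade_weights(foods, trade)

  base <- baseline_diet(foods)
  s <- summarize_diet(base, foods)
  g_scale <- config$targets$ghge_kg / s$ghge_kg
  w_scale <- config$targets$wf_l / s$blue_wf_l
  foods$ghge_kgco2e_per_kg <- foods$ghge_kgco2e_per_kg * g_scale
  foods$bluewf_l_per_kg <- foods$bluewf_l_per_kg * w_scale
  trade$ghge_kgco2e_per_kg <- trade$ghge_kgco2e_per_kg * g_scale
  trade$bluewf_l_per_kg <- trade$bluewf_l_per_kg * w_scale

  list(foods = foods, trade = trade,
       population = generate_population(config, total_population),
       er = exposure_response(), config = config)
}

#' Write a generated input set to CSV files
#'
#' Writes `foods.csv`, `trade.csv`, `population.csv` and
#' `exposure_response.csv` into a directory, each with a `#` comment
#' header recording the generator seed, readable back with [read_foods()],
#' [read_trade()] and [read_population()].
#'
#' @param inputs result of [generate_inputs()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_inputs <- function(inputs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# fiveaday synthetic inputs; seed=%d; calibration=%s",
                 inputs$config$seed, inputs$config$calibration)
  w <- function(df, file) {
    path <- file.path(dir, file)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  foods_out <- inputs$foods
  w(foods_out, "foods.csv")
  w(inputs$trade, "trade.csv")
  w(inputs$population, "population.csv")
  w(inputs$er, "exposure_response.csv")
  invisible(dir)
}
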