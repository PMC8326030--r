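FOOD_CATEGORIES <- c("fruit", "vegetable", "legume", "red_meat",
                     "processed_meat", "poultry", "sweet_snack", "other")

FOODS_COLUMNS <- c(
  id = "character", name = "character", category = "character",
  counts_5aday = "logical", uk_capable = "logical",
  baseline_intake_g = "numeric", energy_density_kcal_per_g = "numeric",
  price_gbp_per_kg = "numeric", ghge_kgco2e_per_kg = "numeric",
  bluewf_l_per_kg = "numeric"
)

TRADE_COLUMNS <- c(
  food_id = "character", origin = "character", share = "numeric",
  ghge_kgco2e_per_kg = "numeric", bluewf_l_per_kg = "numeric"
)

#' Validate a food-group table
#'
#' Checks that a food table carries the required columns with the required
#' types and that every row satisfies the domain invariants: known category,
#' non-negative intake, energy density, price and footprints, and that
#' 5-a-day eligibility is restricted to fruit, vegetable and legume groups.
#'
#' @param foods data.frame with columns `id`, `name`, `category`,
#'   `counts_5aday`, `uk_capable`, `baseline_intake_g`,
#'   `energy_density_kcal_per_g`, `price_gbp_per_kg`, `ghge_kgco2e_per_kg`,
#'   `bluewf_l_per_kg`.
#' @return `foods`, invisibly, after validation.
#' @export
validate_foods <- function(foods) {
  stopifnot(is.data.frame(foods))
  missing <- setdiff(names(FOODS_COLUMNS), names(foods))
  if (length(missing) > 0L)
    stop("foods table is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(foods$id))
    stop("foods table has duplicated ids: ",
         paste(unique(foods$id[duplicated(foods$id)]), collapse = ", "))
  bad_cat <- setdiff(unique(foods$category), FOOD_CATEGORIES)
  if (length(bad_cat) > 0L)
    stop("unknown food categories: ", paste(bad_cat, collapse = ", "))
  num_cols <- names(FOODS_COLUMNS)[FOODS_COLUMNS == "numeric"]
  for (col in num_cols) {
    v <- foods[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0))
      stop("column '", col, "' must be numeric, non-missing and >= 0")
  }
  for (col in c("counts_5aday", "uk_capable"))
    if (!is.logical(foods[[col]]) || anyNA(foods[[col]]))
      stop("column '", col, "' must be logical and non-missing")
  offside <- foods$counts_5aday &
    !(foods$category %in% c("fruit", "vegetable", "legume"))
  if (any(offside))
    stop("counts_5aday is TRUE outside fruit/vegetable/legume for: ",
         paste(foods$id[offside], collapse = ", "))
  invisible(foods)
}

#' Read a food-group table from CSV
#'
#' Strict schema reader for `foods.csv` (UTF-8, "." decimal, `#` comment
#' lines permitted for provenance headers). Errors name the offending
#' column and, for value failures, the first offending data line.
#'
#' @param path path to a CSV file with the columns listed in
#'   [validate_foods()].
#' @return validated food table (data.frame).
#' @export
read_foods <- function(path) {
  foods <- read_schema_csv(path, FOODS_COLUMNS)
  validate_foods(foods)
  foods
}

#' Read a trade-share table from CSV
#'
#' Columns `food_id,origin,share,ghge_kgco2e_per_kg,bluewf_l_per_kg`.
#' Shares for each food must sum to 1 (tolerance 1e-9); violations are
#' reported with the food id.
#'
#' @param path path to `trade.csv`.
#' @return validated trade table (data.frame).
#' @export
read_trade <- function(path) {
  trade <- read_schema_csv(path, TRADE_COLUMNS)
  validate_trade(trade)
  trade
}

#' @rdname read_trade
#' @param trade trade-share data.frame.
#' @export
validate_trade <- function(trade) {
  missing <- setdiff(names(TRADE_COLUMNS), names(trade))
  if (length(missing) > 0L)
    stop("trade table is missing columns: ", paste(missing, collapse = ", "))
  if (any(trade$share < 0 | trade$share > 1))
    stop("trade shares must lie in [0, 1]")
  sums <- tapply(trade$share, trade$food_id, sum)
  off <- abs(sums - 1) > 1e-9
  if (any(off))
    stop("trade shares do not sum to 1 for food(s): ",
         paste(names(sums)[off], collapse = ", "))
  invisible(trade)
}

# Shared strict CSV reader: checks header set, coerces types, reports the
# first bad line (1-based, counting the header) on type failure.
read_schema_csv <- function(path, schema) {
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing <- setdiff(names(schema), names(raw))
  if (length(missing) > 0L)
    stop(basename(path), ": missing column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(raw), names(schema))
  if (length(extra) > 0L)
    stop(basename(path), ": unexpected column(s): ",
         paste(extra, collapse = ", "))
  out <- raw
  for (col in names(schema)) {
    v <- raw[[col]]
    conv <- switch(schema[[col]],
      character = v,
      numeric = suppressWarnings(as.numeric(v)),
      logical = parse_logical(v)
    )
    bad <- which(is.na(conv) & !is.na(v) & nzchar(v))
    if (schema[[col]] != "character" && length(bad) > 0L)
      stop(basename(path), ": line ", bad[1L] + 1L, ": cannot parse '",
           v[bad[1L]], "' as ", schema[[col]], " in column '", col, "'")
    if (anyNA(conv))
      stop(basename(path), ": column '", col, "' has missing values")
    out[[col]] <- conv
  }
  out
}

parse_logical <- function(x) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Coerce and align a diet vector to a food table
#'
#' A diet vector stores per-food intake in g/person/day, named by food id
#' and aligned to one food table: every food id present, no extras, all
#' entries non-negative.
#'
#' @param x named numeric vector of intakes (g/person/day).
#' @param foods validated food table.
#' @return numeric vector in `foods$id` order, class `diet_vector`.
#' @export
as_diet <- function(x, foods) {
  if (is.null(names(x)) || !is.numeric(x))
    stop("a diet must be a named numeric vector of g/person/day")
  extra <- setdiff(names(x), foods$id)
  if (length(extra) > 0L)
    stop("diet has intakes for unknown foods: ", paste(extra, collapse = ", "))
  missing <- setdiff(foods$id, names(x))
  if (length(missing) > 0L)
    stop("diet is missing foods: ", paste(missing, collapse = ", "))
  if (anyNA(x) || any(x < 0))
    stop("diet intakes must be non-negative and non-missing")
  out <- x[foods$id]
  class(out) <- c("diet_vector", "numeric")
  out
}

#' Baseline diet of a food table
#'
#' @param foods validated food table.
#' @return the `baseline_intake_g` column as a [as_diet()] vector.
#' @export
baseline_diet <- function(foods) {
  as_diet(stats::setNames(foods$baseline_intake_g, foods$id), foods)
}

#' Supply-weighted footprint factors for one food
#'
#' Combines origin-specific greenhouse-gas and blue-water factors into a
#' single per-kg factor, weighted by each origin's share of current supply.
#' "GLOBAL" rows act as fallback factors where no country-specific estimate
#' exists and are weighted like any other origin.
#'
#' @param shares data.frame of trade rows for a single food (`origin`,
#'   `share`, `ghge_kgco2e_per_kg`, `bluewf_l_per_kg`).
#' @param food_id optional id used in error messages.
#' @return list with elements `ghge` (kg CO2eq/kg) and `wf` (L/kg).
#' @export
weighted_footprint <- function(shares, food_id = NULL) {
  if (NROW(shares) == 0L) stop("no trade shares supplied")
  if (abs(sum(shares$share) - 1) > 1e-9)
    stop("trade shares do not sum to 1 for food ",
         if (is.null(food_id)) "<unnamed>" else food_id,
         " (sum = ", format(sum(shares$share), digits = 12), ")")
  list(ghge = sum(shares$share * shares$ghge_kgco2e_per_kg),
       wf = sum(shares$share * shares$bluewf_l_per_kg))
}

#' Replace food footprints by trade-weighted values
#'
#' For every food present in the trade table, overwrite its `ghge` and
#' `blue_wf` columns with the supply-weighted combination of the origin
#' factors. Foods absent from the trade table keep their direct
#' (single-origin) values.
#'
#' @param foods validated food table.
#' @param trade validated trade table.
#' @return the food table with updated footprint columns.
#' @export
apply_trade_weights <- function(foods, trade) {
  validate_trade(trade)
  for (fid in unique(trade$food_id)) {
    i <- match(fid, foods$id)
    if (is.na(i)) stop("trade table references unknown food: ", fid)
    w <- weighted_footprint(trade[trade$food_id == fid, , drop = FALSE], fid)
    foods$ghge_kgco2e_per_kg[i] <- w$ghge
    foods$bluewf_l_per_kg[i] <- w$wf
  }
  foods
}

#' Summarize a diet
#'
#' Computes whole-diet energy, cost and environmental footprints plus the
#' 5-a-day category masses. Per-kg factors (price, GHGE, blue water) are
#' applied to intakes converted from grams to kilograms. Category masses
#' are restricted to foods counting toward the 5-a-day target, so fruit
#' juice and potatoes carry cost and footprints but contribute no
#' `fruit_g`/`veg_nonlegume_g`.
#'
#' @param diet diet vector aligned to `foods` (see [as_diet()]).
#' @param foods validated food table.
#' @param legume_cap_g cap on the counted legume contribution (g/day,
#'   default 80, i.e. one portion).
#' @return object of class `diet_summary`: list with `energy_kcal`,
#'   `cost_gbp`, `ghge_kg`, `blue_wf_l`, `fruit_g`, `veg_nonlegume_g`,
#'   `legume_g`, `five_a_day_g`.
#' @export
summarize_diet <- function(diet, foods, legume_cap_g = 80) {
  diet <- as_diet(diet, foods)
  x <- as.numeric(diet)
  counted <- foods$counts_5aday
  fruit_g <- sum(x[counted & foods$category == "fruit"])
  veg_g <- sum(x[counted & foods$category == "vegetable"])
  leg_g <- sum(x[counted & foods$category == "legume"])
  out <- list(
    energy_kcal = sum(x * foods$energy_density_kcal_per_g),
    cost_gbp = sum(x / 1000 * foods$price_gbp_per_kg),
    ghge_kg = sum(x / 1000 * foods$ghge_kgco2e_per_kg),
    blue_wf_l = sum(x / 1000 * foods$bluewf_l_per_kg),
    fruit_g = fruit_g,
    veg_nonlegume_g = veg_g,
    legume_g = leg_g,
    five_a_day_g = fruit_g + veg_g + min(leg_g, legume_cap_g)
  )
  class(out) <- "diet_summary"
  out
}

#' @export
print.diet_summary <- function(x, ...) {
  cat("Diet summary (per person per day)\n")
  cat(sprintf("  energy     %8.1f kcal\n", x$energy_kcal))
  cat(sprintf("  cost       %8.2f GBP\n", x$cost_gbp))
  cat(sprintf("  GHGE       %8.2f kg CO2eq\n", x$ghge_kg))
  cat(sprintf("  blue WF    %8.1f L\n", x$blue_wf_l))
  cat(sprintf("  fruit      %8.1f g   vegetables %.1f g   legumes %.1f g\n",
              x$fruit_g, x$veg_nonlegume_g, x$legume_g))
  cat(sprintf("  5-a-day    %8.1f g  (%.1f portions)\n",
              x$five_a_day_g, portions(x$five_a_day_g)))
  invisible(x)
}

#' Count grams toward the 5-a-day target
#'
#' Sums intake over fruit and non-legume vegetable groups flagged as
#' counting (fruit juice and potatoes are excluded by flag) and adds the
#' legume contribution capped at one portion.
#'
#' @inheritParams summarize_diet
#' @return counted grams per person per day.
#' @export
count_five_a_day <- function(diet, foods, legume_cap_g = 80) {
  summarize_diet(diet, foods, legume_cap_g)$five_a_day_g
}

#' Convert grams to 80-g portions
#'
#' @param grams grams of fruit and vegetables.
#' @param portion_g grams per portion (default 80).
#' @param round round to the nearest whole portion for reporting.
#' @return portions (numeric).
#' @export
portions <- function(grams, portion_g = 80, round = FALSE) {
  stopifnot(all(grams >= 0))
  p <- grams / portion_g
  if (round) round(p) else p
}
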