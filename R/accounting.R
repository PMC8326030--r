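#' National scaling constants
#'
#' @param population persons (default 66,650,000, the UK population used
#'   for national aggregation).
#' @param days_per_year days in the aggregation year (default 365).
#' @return list of class `national_constants`.
#' @export
national_constants <- function(population = 66650000, days_per_year = 365) {
  stopifnot(population > 0, days_per_year > 0)
  structure(list(population = population, days_per_year = days_per_year),
            class = "national_constants")
}

#' National annual greenhouse-gas change
#'
#' Aggregates a per-capita daily GHGE change over the population and one
#' year: `delta_kg * population * days / 1e9` megatonnes CO2eq per year.
#'
#' @param delta_kg_per_person_day change in kg CO2eq/person/day.
#' @param constants a [national_constants()].
#' @return Mt CO2eq per year (signed).
#' @export
national_annual_ghge <- function(delta_kg_per_person_day,
                                 constants = national_constants()) {
  delta_kg_per_person_day * constants$population *
    constants$days_per_year / 1e9
}

#' National annual blue-water change
#'
#' `delta_l * population * days / 1e12` cubic kilometres per year.
#'
#' @param delta_l_per_person_day change in L/person/day.
#' @param constants a [national_constants()].
#' @return km^3 per year (signed).
#' @export
national_annual_wf <- function(delta_l_per_person_day,
                               constants = national_constants()) {
  delta_l_per_person_day * constants$population *
    constants$days_per_year / 1e12
}

#' Percent change relative to a baseline value
#'
#' Always computed on unrounded values; a zero baseline yields `NA` with a
#' warning rather than an infinity.
#'
#' @param baseline_value,new_value numeric.
#' @return percent change `100 * (new - baseline) / baseline`.
#' @export
percent_change <- function(baseline_value, new_value) {
  out <- 100 * (new_value - baseline_value) / baseline_value
  if (any(baseline_value == 0)) {
    warning("percent change undefined at zero baseline; returning NA")
    out[baseline_value == 0] <- NA_real_
  }
  out
}

#' Build a pathway comparison report row
#'
#' Collects per-capita daily levels and deltas (absolute and percent) for
#' energy, cost, GHGE and blue water, national annual footprint deltas,
#' fruit-and-vegetable grams and portions, and (optionally) the health
#' results, for one optimized pathway versus baseline. All derived
#' quantities are computed from unrounded internals.
#'
#' @param pathway_id label for the row.
#' @param baseline_summary,pathway_summary [summarize_diet()] results.
#' @param health optional [health_impact()] result.
#' @param attribution optional fruit-and-vegetable attribution fraction.
#' @param constants a [national_constants()].
#' @return one-row data.frame of class `pathway_report`.
#' @export
pathway_report <- function(pathway_id, baseline_summary, pathway_summary,
                           health = NULL, attribution = NA_real_,
                           constants = national_constants()) {
  b <- baseline_summary; p <- pathway_summary
  out <- data.frame(
    pathway = pathway_id,
    energy_kcal = p$energy_kcal,
    cost_gbp = p$cost_gbp,
    ghge_kg = p$ghge_kg,
    blue_wf_l = p$blue_wf_l,
    fv_g = p$five_a_day_g,
    fv_portions = portions(p$five_a_day_g),
    delta_cost_gbp = p$cost_gbp - b$cost_gbp,
    delta_cost_pct = percent_change(b$cost_gbp, p$cost_gbp),
    delta_ghge_kg = p$ghge_kg - b$ghge_kg,
    delta_ghge_pct = percent_change(b$ghge_kg, p$ghge_kg),
    delta_wf_l = p$blue_wf_l - b$blue_wf_l,
    delta_wf_pct = percent_change(b$blue_wf_l, p$blue_wf_l),
    national_ghge_mt_y = national_annual_ghge(p$ghge_kg - b$ghge_kg,
                                              constants),
    national_wf_km3_y = national_annual_wf(p$blue_wf_l - b$blue_wf_l,
                                           constants),
    delta_le_months = if (is.null(health)) NA_real_ else
      health$delta_le_months_combined,
    attribution_fv_pct = 100 * attribution,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pathway_report", "data.frame")
  out
}

#' Render a pathway comparison table
#'
#' Binds pathway report rows into one table and writes CSV and/or JSON
#' renderings. The machine columns keep full precision; display columns
#' (suffix `_disp`) are rounded for reading: one decimal for kg, L and
#' months, two decimals for GBP, whole percent.
#'
#' @param reports list of [pathway_report()] rows (at least one).
#' @param path base output path without extension; `NULL` renders without
#'   writing.
#' @param formats subset of `c("csv", "json")`.
#' @return the combined data.frame (invisibly when writing).
#' @export
render_report <- function(reports, path = NULL,
                          formats = c("csv", "json")) {
  if (length(reports) == 0L) stop("no pathway reports supplied")
  tab <- do.call(rbind, lapply(reports, as.data.frame))
  disp <- data.frame(
    ghge_kg_disp = round(tab$ghge_kg, 1),
    wf_l_disp = round(tab$blue_wf_l, 1),
    cost_gbp_disp = round(tab$cost_gbp, 2),
    delta_cost_gbp_disp = round(tab$delta_cost_gbp, 2),
    delta_ghge_pct_disp = round(tab$delta_ghge_pct),
    delta_wf_pct_disp = round(tab$delta_wf_pct),
    delta_cost_pct_disp = round(tab$delta_cost_pct),
    delta_le_months_disp = round(tab$delta_le_months, 1),
    attribution_fv_pct_disp = round(tab$attribution_fv_pct)
  )
  out <- cbind(tab, disp)
  if (!is.null(path)) {
    if ("csv" %in% formats)
      utils::write.csv(out, paste0(path, ".csv"), row.names = FALSE)
    if ("json" %in% formats)
      jsonlite::write_json(out, paste0(path, ".json"), dataframe = "rows",
                           digits = NA, auto_unbox = TRUE)
    return(invisible(out))
  }
  out
}
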