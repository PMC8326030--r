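PATHWAY_IDS <- c("FV_ALL", "VEG_ALL", "FV_UK", "VEG_UK")

#' Define a 5-a-day consumption pathway
#'
#' The four pathways differ in which food categories absorb the required
#' increase (fruit + vegetables + legumes for the `FV_*` pathways,
#' vegetables + legumes only for `VEG_*`) and whether eligibility is
#' restricted to varieties that could plausibly be grown to a greater
#' extent in the United Kingdom (`*_UK`).
#'
#' @param id one of `"FV_ALL"`, `"VEG_ALL"`, `"FV_UK"`, `"VEG_UK"`.
#' @param target_g total fruit-and-vegetable target, g/person/day
#'   (default 400, i.e. five 80-g portions).
#' @param legume_cap_g counted-legume cap, g/day (default 80).
#' @return object of class `pathway_spec`.
#' @export
pathway_spec <- function(id = PATHWAY_IDS, target_g = 400, legume_cap_g = 80) {
  id <- match.arg(id)
  spec <- list(
    id = id,
    increase_categories = if (startsWith(id, "FV"))
      c("fruit", "vegetable", "legume") else c("vegetable", "legume"),
    uk_only = endsWith(id, "UK"),
    target_g = target_g,
    legume_cap_g = legume_cap_g
  )
  class(spec) <- "pathway_spec"
  spec
}

#' @export
print.pathway_spec <- function(x, ...) {
  cat("Pathway", x$id, "- increase",
      paste(x$increase_categories, collapse = "+"),
      if (x$uk_only) "(UK-capable varieties only)" else "(all varieties)",
      "to", x$target_g, "g/d\n")
  invisible(x)
}

#' Foods eligible for the pathway increase
#'
#' The counting-eligible foods in the pathway's increase categories,
#' restricted to UK-capable varieties for the `*_UK` pathways. Foods with
#' zero baseline intake are excluded: the increase is proportionate to
#' current consumption, so they stay at zero.
#'
#' @param foods validated food table.
#' @param spec a [pathway_spec()].
#' @return character vector of eligible food ids.
#' @export
eligible_set <- function(foods, spec) {
  keep <- foods$counts_5aday &
    foods$category %in% spec$increase_categories &
    foods$baseline_intake_g > 0
  if (spec$uk_only) keep <- keep & foods$uk_capable
  ids <- foods$id[keep]
  if (length(ids) == 0L)
    stop("pathway ", spec$id, " has no eligible foods (infeasible)")
  ids
}

#' Common scale factor bringing the diet to the 5-a-day target
#'
#' Finds s >= 1 such that scaling every eligible food's intake by s (others
#' unchanged) makes the counted fruit-and-vegetable total equal the target.
#' The counted total is piecewise linear in s because of the legume cap;
#' each linear piece is solved in closed form.
#'
#' @param diet baseline diet vector.
#' @param foods validated food table.
#' @param spec a [pathway_spec()].
#' @return the scale factor (dimensionless, >= 1).
#' @export
solve_scale_factor <- function(diet, foods, spec) {
  diet <- as_diet(diet, foods)
  x <- as.numeric(diet)
  elig <- foods$id %in% eligible_set(foods, spec)
  counted <- foods$counts_5aday
  nonleg <- counted & foods$category %in% c("fruit", "vegetable")
  leg <- counted & foods$category == "legume"
  cap <- spec$legume_cap_g
  target <- spec$target_g

  A <- sum(x[nonleg & elig])    # scaled, uncapped mass
  B <- sum(x[nonleg & !elig])   # fixed, uncapped mass
  Le <- sum(x[leg & elig])      # scaled legume mass
  Lf <- sum(x[leg & !elig])     # fixed legume mass

  count_at <- function(s) B + A * s + min(Lf + Le * s, cap)
  if (count_at(1) >= target - 1e-9) return(1)

  # Piece 1: legumes below the cap.
  if (A + Le > 0) {
    s <- (target - B - Lf) / (A + Le)
    if (Lf + Le * s <= cap + 1e-12 && s >= 1) return(s)
  }
  # Piece 2: cap binding; only the uncapped eligible mass can still grow.
  if (A <= 0)
    stop("pathway ", spec$id, " infeasible: legume cap bounds the counted ",
         "total at ", format(count_at(Inf)), " g < target ", target, " g")
  s <- (target - B - cap) / A
  if (count_at(s) < target - 1e-9)
    stop("pathway ", spec$id, " infeasible: counted total reaches at most ",
         format(count_at(s)), " g < target ", target, " g")
  s
}

#' Energy added by the fruit and vegetable increases
#'
#' The extra dietary energy introduced by scaling eligible foods up,
#' split into the fruit side (which replaces sweet snacks) and the
#' vegetable-plus-legume side (which replaces meat), both in kcal/day.
#'
#' @param baseline,scaled baseline and scaled diet vectors.
#' @param foods validated food table.
#' @return named numeric `c(fruit = ..., veg = ...)` in kcal/day.
#' @export
substitution_requirements <- function(baseline, scaled, foods) {
  baseline <- as_diet(baseline, foods)
  scaled <- as_diet(scaled, foods)
  de <- (as.numeric(scaled) - as.numeric(baseline)) *
    foods$energy_density_kcal_per_g
  c(fruit = sum(de[foods$category == "fruit"]),
    veg = sum(de[foods$category %in% c("vegetable", "legume")]))
}

#' Optimize the baseline diet into a 5-a-day pathway diet
#'
#' Builds and solves the pathway linear program:
#' \enumerate{
#'   \item eligible fruit and vegetable intakes are scaled by a common
#'     factor until the counted total reaches the target (all other fruit
#'     and vegetables held at baseline);
#'   \item the energy added by extra fruit is removed from the sweet-snack
#'     pool and the energy added by extra vegetables and legumes from the
#'     meat pool (red, processed and poultry), each pool reduced
#'     proportionally to baseline energy contribution with per-food floors
#'     at zero;
#'   \item if a pool is exhausted the residual energy imbalance is removed
#'     through the remaining "free" foods by minimizing the total relative
#'     deviation from baseline, subject to total dietary energy equal to
#'     baseline (1744 kcal/d in the calibrated fixture) and non-negativity.
#' }
#' With the proportional-pool constraints fixed as equalities the residual
#' problem has one equality constraint, so its exact optimum concentrates
#' the adjustment on the foods with the largest energy turnover per unit of
#' relative deviation (a fractional-knapsack exchange argument); that exact
#' solution is used rather than a numerical solver, and is validated
#' against a brute-force oracle in the test suite.
#'
#' @param baseline baseline diet vector.
#' @param foods validated food table.
#' @param spec a [pathway_spec()].
#' @return object of class `pathway_optimization` with elements `diet`
#'   (optimized diet vector), `scale_factor`, `delta_e` (kcal moved into
#'   fruit and veg), `objective` (total relative deviation over free
#'   foods), `status` (`"optimal"` or `"infeasible"`), `binding_notes`.
#' @export
optimize_pathway <- function(baseline, foods, spec) {
  validate_foods(foods)
  baseline <- as_diet(baseline, foods)
  b <- as.numeric(baseline)
  e <- foods$energy_density_kcal_per_g
  notes <- character()

  s <- solve_scale_factor(baseline, foods, spec)
  elig <- foods$id %in% eligible_set(foods, spec)
  x <- b
  x[elig] <- s * b[elig]

  de <- substitution_requirements(baseline, stats::setNames(x, foods$id),
                                  foods)

  # Proportional within-pool reduction; residual carried to free foods.
  reduce_pool <- function(x, members, need, label) {
    pool_e <- sum(b[members] * e[members])
    if (need <= 0) return(list(x = x, residual = 0))
    take <- min(need, pool_e)
    if (pool_e > 0) x[members] <- x[members] * (1 - take / pool_e)
    residual <- need - take
    if (residual > 1e-12)
      notes <<- c(notes, sprintf(
        "%s pool exhausted: %.6g kcal/d rebalanced through free foods",
        label, residual))
    list(x = x, residual = residual)
  }
  sweet <- foods$category == "sweet_snack"
  meat <- foods$category %in% c("red_meat", "processed_meat", "poultry")
  r1 <- reduce_pool(x, sweet, de[["fruit"]], "sweet-snack")
  r2 <- reduce_pool(r1$x, meat, de[["veg"]], "meat")
  x <- r2$x
  residual <- r1$residual + r2$residual

  # Free foods: everything outside the directly modified categories.
  free <- !(foods$category %in% c("fruit", "vegetable", "legume",
                                  "sweet_snack", "red_meat",
                                  "processed_meat", "poultry"))
  adj <- solve_free_rebalance(b[free], e[free], residual)
  if (is.null(adj))
    return(structure(list(
      diet = as_diet(stats::setNames(x, foods$id), foods), scale_factor = s,
      delta_e = de, objective = NA_real_, status = "infeasible",
      binding_notes = c(notes, "free-food energy balance infeasible")),
      class = "pathway_optimization"))
  x[free] <- x[free] + adj

  diet <- as_diet(stats::setNames(x, foods$id), foods)
  energy0 <- sum(b * e)
  stopifnot(abs(sum(x * e) - energy0) <= 1e-6 * max(energy0, 1))
  objective <- sum(abs(adj) / ifelse(b[free] > 0, b[free], 1))
  structure(list(diet = diet, scale_factor = s, delta_e = de,
                 objective = objective, status = "optimal",
                 binding_notes = notes),
            class = "pathway_optimization")
}

# Exact solve of: min sum(|dx_i| / b_i)  s.t.  sum(e_i dx_i) = -residual,
# b_i + dx_i >= 0.  Foods with b = 0 or e = 0 are frozen (relative
# deviation undefined at zero; zero-energy foods cannot move the balance).
# Each unit of relative deviation on food i turns over e_i*b_i kcal, so the
# optimum spends deviation on foods in decreasing order of e_i*b_i;
# decreases are bounded by the zero floor, increases are unbounded (the
# first food absorbs everything).  Returns the per-food adjustment vector,
# or NULL when the required decrease exceeds the total free-food energy.
solve_free_rebalance <- function(b, e, residual) {
  adj <- numeric(length(b))
  if (abs(residual) <= 1e-12) return(adj)
  usable <- b > 0 & e > 0
  cap_e <- b * e
  ord <- order(cap_e, decreasing = TRUE)
  ord <- ord[usable[ord]]
  if (residual > 0) {              # remove energy, floors bind
    left <- residual
    for (i in ord) {
      take <- min(left, cap_e[i])
      adj[i] <- -take / e[i]
      left <- left - take
      if (left <= 1e-12) break
    }
    if (left > 1e-9) return(NULL)
  } else {                          # add energy, unbounded above
    i <- ord[1L]
    if (length(ord) == 0L) return(NULL)
    adj[i] <- -residual / e[i]
  }
  adj
}

#' @export
print.pathway_optimization <- function(x, ...) {
  cat("Pathway optimization:", x$status, "\n")
  cat(sprintf("  scale factor      %.6f\n", x$scale_factor))
  cat(sprintf("  energy moved      fruit %.1f kcal, veg %.1f kcal\n",
              x$delta_e[["fruit"]], x$delta_e[["veg"]]))
  cat(sprintf("  objective         %.6g (total relative deviation)\n",
              x$objective))
  for (n in x$binding_notes) cat("  note:", n, "\n")
  invisible(x)
}
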