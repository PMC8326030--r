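# Small in-code fixtures shared across the suite.

# A hand-sized food table. Defaults give one food per role with simple
# round-number coefficients so expectations can be hand-computed.
toy_foods <- function(intake = c(fruit_a = 88, veg_a = 120.5,
                                 legume_a = 19.5, sweet_a = 40,
                                 red_a = 50, bread = 200, milk = 300),
                      energy = c(fruit_a = 0.6, veg_a = 0.4, legume_a = 0.9,
                                 sweet_a = 4.5, red_a = 2.4, bread = 2.5,
                                 milk = 0.6),
                      category = c(fruit_a = "fruit", veg_a = "vegetable",
                                   legume_a = "legume",
                                   sweet_a = "sweet_snack",
                                   red_a = "red_meat", bread = "other",
                                   milk = "other"),
                      uk_capable = NULL, counts = NULL,
                      price = 2, ghge = 1, wf = 100) {
  ids <- names(intake)
  n <- length(ids)
  cat_ord <- unname(category[ids])
  uk_ord <- if (is.null(uk_capable)) cat_ord %in% c("vegetable", "legume")
            else unname(uk_capable[ids])
  counts_ord <- if (is.null(counts))
    cat_ord %in% c("fruit", "vegetable", "legume")
  else unname(counts[ids])
  data.frame(
    id = ids, name = ids, category = cat_ord,
    counts_5aday = counts_ord, uk_capable = uk_ord,
    baseline_intake_g = unname(intake[ids]),
    energy_density_kcal_per_g = unname(energy[ids]),
    price_gbp_per_kg = rep_len(price, n), ghge_kgco2e_per_kg = rep_len(ghge, n),
    bluewf_l_per_kg = rep_len(wf, n), stringsAsFactors = FALSE)
}

# A minimal population for one or both sexes: three closing age groups
# plus padding so validation's contiguity check passes.
toy_population <- function(m = c(0.01, 0.1, 0.5), pop = c(100, 100, 100),
                           ihd_frac = 0.2, sexes = c("male", "female")) {
  one <- function(sex) {
    d <- data.frame(sex = sex, age = seq_along(m) - 1, population = pop,
                    all_cause_rate = m, stringsAsFactors = FALSE)
    for (o in c("IHD", "ischemic_stroke", "T2D", "colorectal_cancer",
                "lung_cancer", "esophageal_cancer"))
      d[[o]] <- 0
    d$IHD <- ihd_frac * m
    d
  }
  do.call(rbind, lapply(sexes, one))
}

# The calibrated baseline fixture, generated once per test run.
paper_fixture <- local({
  cache <- NULL
  function(seed = 101) {
    if (is.null(cache))
      cache <<- generate_inputs(generator_config(seed = seed))
    cache
  }
})

# Brute-force oracle for the pathway optimization on toy instances with
# exactly two usable free foods: grid over the first free food, solve the
# second exactly from the energy-balance equality, keep the feasible point
# with the smallest total relative deviation.  Pool reductions are fixed
# as proportional equalities, mirroring the model's constraint structure.
oracle_free_rebalance <- function(b, e, residual, n_grid = 100001) {
  stopifnot(length(b) == 2)
  # target: e1*dx1 + e2*dx2 = -residual, x >= 0
  x1_grid <- seq(0, b[1] + abs(residual) / max(e[1], 1e-12),
                 length.out = n_grid)
  dx1 <- x1_grid - b[1]
  dx2 <- (-residual - e[1] * dx1) / e[2]
  x2 <- b[2] + dx2
  ok <- x2 >= -1e-12
  obj <- abs(dx1) / b[1] + abs(dx2) / b[2]
  min(obj[ok])
}
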