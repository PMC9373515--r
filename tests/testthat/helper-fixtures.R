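# Shared fixtures and independent oracles, all built in code.

# minimal composition table with round per-100-g numbers
tiny_fct <- function() {
  data.frame(
    food_code = c("staple", "sweet", "plain"),
    food_group = c("STAPLE", "SWEETS", "PLAIN"),
    energy_kcal = c(100, 400, 50),
    protein_g = c(10, 0, 2),
    fiber_g = c(2, 0, 0),
    vitamin_a_re_ug = c(0, 0, 0),
    vitamin_c_mg = c(0, 0, 0),
    vitamin_d_ug = c(0, 0, 0),
    calcium_mg = c(50, 0, 10),
    iron_mg = c(1, 0, 0),
    potassium_mg = c(100, 0, 20),
    magnesium_mg = c(20, 0, 5),
    total_sugar_g = c(0, 90, 0),
    saturated_fat_g = c(1, 5, 0),
    sodium_mg = c(10, 100, 5),
    stringsAsFactors = FALSE)
}

food_line <- function(id, day, meal, food, grams) {
  data.frame(individual_id = id, day_index = day, meal_code = meal,
             food_code = food, grams = grams, stringsAsFactors = FALSE)
}

# independent naive evaluation of the two scoring sums: explicit loops,
# sharing no code with nrf93()
oracle_nrf <- function(intake, ref, cap_nr = TRUE) {
  e <- intake[["energy_kcal"]]
  nr <- 0
  for (nut in names(ref$dv)) {
    frac <- (intake[[nut]] / e * 2000) / ref$dv[[nut]]
    if (cap_nr && frac > 1) frac <- 1
    nr <- nr + frac
  }
  lim <- 0
  for (nut in names(ref$mrv)) {
    excess <- (intake[[nut]] / e * 2000) / ref$mrv[[nut]] - 1
    if (excess > 0) lim <- lim + excess
  }
  (nr - lim) * 100
}

# random nutrient vector with positive energy; scales chosen so capped and
# uncapped, excess and non-excess branches are all exercised
random_intake <- function() {
  v <- nutrient_vector(energy_kcal = stats::runif(1, 50, 3000))
  scored <- nutrient_names("scored")
  ref <- reference_table()
  amounts <- c(ref$dv, ref$mrv)[scored]
  v[scored] <- stats::runif(length(scored), 0, 3) * amounts
  v
}

# tiny cohort: individuals table for ad-hoc recall fixtures
tiny_individuals <- function(ids, age_group = "adults_19_59",
                             weight = 1, sex = "female") {
  n <- length(ids)
  data.frame(id = ids, age_years = 30, age_group = age_group,
             sex = rep_len(sex, n), urbanity = "rural",
             wealth_quintile = "middle", education = "college",
             nutrition_status = "normal",
             sampling_weight = rep_len(weight, n),
             stringsAsFactors = FALSE)
}
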