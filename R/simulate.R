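# Synthetic two-day 24-h recall generator. It emulates the structure of a
# national dietary survey -- four age groups, meal-coded food lines, a second
# non-consecutive recall day for about half the sample, breakfast skippers --
# with known ground truth, so every downstream stage is testable without the
# survey microdata.
#
# Portion model: grams for a food line are
#   exp(mu_g + age_shift + b_i + w_id + eps),
# with b_i ~ N(0, person_effect_sd^2) shared across a person's days,
# w_id ~ N(0, day_effect_sd^2) shared across a day's lines, and
# eps ~ N(0, sigma_g^2) per line. Which foods a person eats at a given meal
# is drawn once per person (a habitual menu) and reused on both recall
# days: day-to-day variation in intake then comes from the day effect and
# portion noise, as in a repeated-recall variance-components model, rather
# than from resampling the entire plate composition every day.

#' Built-in food composition fixture
#'
#' A small synthetic food composition table (nutrients per 100 g edible
#' portion) covering 13 foods in 13 food groups typical of Philippine meals:
#' rice, coffee, sugars, cooking oil, chicken egg, fresh fish, fresh meat,
#' green leafy and other vegetables, bread/other cereal products, powdered
#' milk, cacao beverages and fruit. Amounts are plausible magnitudes, not a
#' reproduction of any published food composition table.
#'
#' @return `data.frame` with `food_code`, `food_group` and the core nutrient
#'   columns.
#' @export
default_food_composition <- function() {
  f <- function(code, group, energy, protein = 0, fiber = 0, vita = 0,
                vitc = 0, vitd = 0, ca = 0, fe = 0, k = 0, mg = 0,
                sugar = 0, satfat = 0, na = 0) {
    data.frame(food_code = code, food_group = group, energy_kcal = energy,
               protein_g = protein, fiber_g = fiber, vitamin_a_re_ug = vita,
               vitamin_c_mg = vitc, vitamin_d_ug = vitd, calcium_mg = ca,
               iron_mg = fe, potassium_mg = k, magnesium_mg = mg,
               total_sugar_g = sugar, saturated_fat_g = satfat,
               sodium_mg = na, stringsAsFactors = FALSE)
  }
  rbind(
    f("rice", "RICE", 130, protein = 2.7, fiber = 0.4, ca = 10, fe = 0.2,
      k = 35, mg = 12, sugar = 0.1, satfat = 0.1, na = 1),
    f("coffee", "COFFEE", 2, protein = 0.1, k = 49, mg = 3, na = 2),
    f("sugar", "SUGARS", 380, ca = 85, fe = 0.7, k = 133, mg = 29,
      sugar = 97, na = 28),
    f("cooking_oil", "COOKING OIL", 884, satfat = 82),
    f("egg", "CHICKEN EGG", 155, protein = 12.6, vita = 160, vitd = 2.2,
      ca = 50, fe = 1.2, k = 126, mg = 10, sugar = 1.1, satfat = 3.3,
      na = 124),
    f("fresh_fish", "FRESH FISH", 150, protein = 20, vita = 30, vitd = 5,
      ca = 51, fe = 0.7, k = 292, mg = 30, satfat = 1.3, na = 72),
    f("green_leafy_veg", "GREEN LEAFY VEGETABLES", 19, protein = 2.6,
      fiber = 2.1, vita = 315, vitc = 55, ca = 77, fe = 1.7, k = 312,
      mg = 71, sugar = 1.4, na = 113),
    f("other_veg", "OTHER VEGETABLES", 35, protein = 1.5, fiber = 2.5,
      vita = 100, vitc = 15, ca = 30, fe = 0.8, k = 250, mg = 20,
      sugar = 3, na = 5),
    f("bread", "OTHER CEREAL PRODUCTS", 280, protein = 8.5, fiber = 2.5,
      ca = 30, fe = 2.5, k = 110, mg = 25, sugar = 6, satfat = 1.5,
      na = 480),
    f("powdered_milk", "POWDERED MILK", 490, protein = 26, vita = 280,
      vitc = 8, vitd = 7, ca = 900, fe = 0.5, k = 1300, mg = 85,
      sugar = 38, satfat = 16, na = 370),
    f("cacao_beverage", "CACAO AND CHOCOLATE BASED BEVERAGES", 390,
      protein = 5, fiber = 4, ca = 150, fe = 5, k = 500, mg = 130,
      sugar = 70, satfat = 6, na = 150),
    f("fresh_meat", "FRESH MEAT", 240, protein = 17, vita = 2, vitd = 0.5,
      ca = 8, fe = 0.9, k = 300, mg = 20, satfat = 5.5, na = 60),
    f("banana", "FRUITS", 89, protein = 1.1, fiber = 2.6, vita = 3,
      vitc = 8.7, k = 358, mg = 27, sugar = 12)
  )
}

#' Built-in meal menu
#'
#' Per-food, per-meal selection probabilities and log-normal portion
#' parameters (`mu_log_g` on the log-gram scale, `sigma_log_g` the per-line
#' portion noise). Meal codes: 1 breakfast, 2 lunch, 3 supper, 4 morning
#' snack, 5 afternoon snack. Breakfast is anchored on a near-universal rice
#' staple with coffee, sugar and bread as common companions, mirroring the
#' commonly reported Filipino breakfast pattern.
#'
#' @return `data.frame` with `food_code`, `meal_code`, `prob`, `mu_log_g`,
#'   `sigma_log_g`.
#' @export
default_food_menu <- function() {
  m <- function(food, meal, prob, grams)
    data.frame(food_code = food, meal_code = meal, prob = prob,
               mu_log_g = log(grams), sigma_log_g = 0.1,
               stringsAsFactors = FALSE)
  rbind(
    # breakfast: a universal rice staple with optional companions, so the
    # between-person variance of log breakfast energy is dominated by the
    # portion-size person effect rather than by plate composition
    m("rice", 1, 1.00, 150), m("coffee", 1, 0.65, 150),
    m("sugar", 1, 0.55, 7), m("cooking_oil", 1, 0.40, 4),
    m("egg", 1, 0.25, 35), m("bread", 1, 0.25, 20),
    m("powdered_milk", 1, 0.12, 10), m("cacao_beverage", 1, 0.08, 10),
    m("fresh_fish", 1, 0.12, 30), m("fresh_meat", 1, 0.05, 25),
    m("green_leafy_veg", 1, 0.05, 25), m("other_veg", 1, 0.07, 30),
    # lunch
    m("rice", 2, 0.95, 250), m("fresh_fish", 2, 0.50, 80),
    m("fresh_meat", 2, 0.30, 70), m("green_leafy_veg", 2, 0.35, 40),
    m("other_veg", 2, 0.40, 50), m("cooking_oil", 2, 0.60, 5),
    m("banana", 2, 0.20, 80),
    # supper
    m("rice", 3, 0.95, 220), m("fresh_fish", 3, 0.45, 80),
    m("fresh_meat", 3, 0.35, 70), m("green_leafy_veg", 3, 0.30, 40),
    m("other_veg", 3, 0.35, 50), m("cooking_oil", 3, 0.55, 5),
    # snacks
    m("bread", 4, 0.50, 40), m("coffee", 4, 0.30, 150),
    m("cacao_beverage", 4, 0.10, 10), m("banana", 4, 0.25, 60),
    m("sugar", 4, 0.25, 5),
    m("bread", 5, 0.45, 40), m("coffee", 5, 0.25, 150),
    m("sugar", 5, 0.20, 5), m("banana", 5, 0.20, 60),
    m("powdered_milk", 5, 0.08, 10)
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic recall generator. Defaults: 500 individuals
#' per age group; breakfast-skipper probability 0.02 in children and
#' adolescents and 0.04 in adults and elderly (the magnitudes reported for
#' Philippine survey data); a second recall day for 50% of individuals;
#' between-person SD 0.4 and within-person (day) SD 0.3 on the log scale.
#'
#' @param n_individuals Named integer vector (one entry per age group).
#' @param skipper_probability Named numeric vector in `[0, 1]` per age group
#'   (a single unnamed value is recycled).
#' @param day2_fraction Probability an individual gets a second recall day.
#' @param person_effect_sd,day_effect_sd Log-scale between-person and
#'   within-person SDs of portion size.
#' @param seed Integer RNG seed.
#' @param food_menu Menu `data.frame`, see [default_food_menu()].
#' @param fct Food composition `data.frame`, see
#'   [default_food_composition()].
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_individuals = NULL,
                              skipper_probability = NULL,
                              day2_fraction = 0.5,
                              person_effect_sd = 0.4,
                              day_effect_sd = 0.3,
                              seed = 1L,
                              food_menu = default_food_menu(),
                              fct = default_food_composition()) {
  groups <- age_groups()
  if (is.null(n_individuals))
    n_individuals <- stats::setNames(rep(500L, 4L), groups)
  if (length(n_individuals) == 1L && is.null(names(n_individuals)))
    n_individuals <- stats::setNames(rep(n_individuals, 4L), groups)
  if (is.null(skipper_probability))
    skipper_probability <- c(children_6_12 = 0.02, adolescents_13_18 = 0.02,
                             adults_19_59 = 0.04, elderly_60_plus = 0.04)
  if (length(skipper_probability) == 1L && is.null(names(skipper_probability)))
    skipper_probability <- stats::setNames(rep(skipper_probability, 4L), groups)
  if (!all(groups %in% names(n_individuals)) ||
      !all(groups %in% names(skipper_probability)))
    stop("n_individuals and skipper_probability must name all age groups",
         call. = FALSE)
  if (any(skipper_probability < 0) || any(skipper_probability > 1) ||
      day2_fraction < 0 || day2_fraction > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (person_effect_sd <= 0 || day_effect_sd <= 0)
    stop("effect SDs must be > 0", call. = FALSE)
  if (any(n_individuals < 1))
    stop("n_individuals must be positive", call. = FALSE)
  if (nrow(food_menu) == 0L)
    stop("food menu must be nonempty", call. = FALSE)
  n_groups <- length(unique(fct$food_group[fct$food_code %in%
                                             food_menu$food_code]))
  if (n_groups < 10L)
    stop("food menu must cover at least 10 food groups (has ", n_groups, ")",
         call. = FALSE)
  structure(list(n_individuals = n_individuals[groups],
                 skipper_probability = skipper_probability[groups],
                 day2_fraction = day2_fraction,
                 person_effect_sd = person_effect_sd,
                 day_effect_sd = day_effect_sd,
                 seed = as.integer(seed),
                 food_menu = food_menu, fct = fct),
            class = "simulation_config")
}

# log-gram shift per age group: children eat smaller portions, adults larger
.AGE_SHIFT <- c(children_6_12 = -0.30, adolescents_13_18 = 0.05,
                adults_19_59 = 0.10, elderly_60_plus = -0.10)

.AGE_RANGE <- list(children_6_12 = c(6, 12), adolescents_13_18 = c(13, 18),
                   adults_19_59 = c(19, 59), elderly_60_plus = c(60, 90))

#' Simulate a survey-like recall dataset
#'
#' Draws individuals with demographic covariates and sampling weights, a
#' habitual per-meal food menu per person, and one or two days of meal-coded
#' food lines under the log-normal portion model described in
#' [simulation_config()]. Individuals flagged as breakfast skippers have
#' their breakfast lines thinned (grams scaled down) so that breakfast
#' supplies under 50 kcal on every recorded day -- the skipping is energy
#' based, not just a missing meal record. Sampling weights are drawn from a
#' shifted gamma distribution and rescaled to mean one.
#'
#' @param config A [simulation_config()].
#' @return List with `individuals`, `recalls` (food-line `data.frame`),
#'   `fct`, and `truth` (config echo plus the per-person drawn parameters:
#'   person effect, skipper flag, day-2 flag).
#' @examples
#' sim <- simulate_survey(simulation_config(n_individuals = 20, seed = 7))
#' head(sim$recalls)
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  groups <- age_groups()
  n_per <- config$n_individuals
  n <- sum(n_per)
  age_group <- rep(groups, times = n_per)
  id <- sprintf("%s_%05d", substr(gsub("_.*$", "", age_group), 1, 5), seq_len(n))

  age_years <- vapply(age_group, function(g) {
    r <- .AGE_RANGE[[g]]
    stats::runif(1, r[1], r[2] + 1)
  }, numeric(1))
  age_years <- floor(age_years)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  urbanity <- sample(c("rural", "urban"), n, replace = TRUE,
                     prob = c(0.65, 0.35))
  wealth <- sample(c("poorest", "poor", "middle", "rich", "richest"), n,
                   replace = TRUE)
  adult <- age_group %in% c("adults_19_59", "elderly_60_plus")
  education <- rep(NA_character_, n)
  education[adult] <- sample(c("elementary", "high_school", "college",
                               "vocational"),
                             sum(adult), replace = TRUE,
                             prob = c(0.45, 0.35, 0.15, 0.05))
  nutrition_status <- sample(c("underweight", "normal", "overweight",
                               "obese"),
                             n, replace = TRUE,
                             prob = c(0.12, 0.62, 0.2, 0.06))
  w <- 0.2 + stats::rgamma(n, shape = 2, scale = 0.4)
  w <- w / mean(w)

  individuals <- data.frame(id = id, age_years = age_years,
                            age_group = age_group, sex = sex,
                            urbanity = urbanity, wealth_quintile = wealth,
                            education = education,
                            nutrition_status = nutrition_status,
                            sampling_weight = w, stringsAsFactors = FALSE)

  b <- stats::rnorm(n, 0, config$person_effect_sd)
  skipper <- stats::rbinom(n, 1, config$skipper_probability[age_group]) == 1
  has_day2 <- stats::rbinom(n, 1, config$day2_fraction) == 1
  w_day <- matrix(stats::rnorm(2 * n, 0, config$day_effect_sd), ncol = 2)

  menu <- config$food_menu
  n_menu <- nrow(menu)
  # habitual menu: one Bernoulli per person x menu row, reused on both days
  keep <- stats::rbinom(n * n_menu, 1, rep(menu$prob, each = n)) == 1
  # a non-skipper must have a breakfast to eat: anyone who drew no
  # breakfast item at all gets the most common one (the staple)
  bkf_rows <- which(menu$meal_code == 1)
  keep_mat <- matrix(keep, nrow = n)
  none <- rowSums(keep_mat[, bkf_rows, drop = FALSE]) == 0L
  if (any(none)) {
    staple <- bkf_rows[which.max(menu$prob[bkf_rows])]
    keep_mat[none, staple] <- TRUE
    keep <- as.vector(keep_mat)
  }
  person_idx <- rep(seq_len(n), times = n_menu)[keep]
  menu_idx <- rep(seq_len(n_menu), each = n)[keep]

  day_list <- lapply(1:2, function(d) {
    sel <- if (d == 1L) rep(TRUE, length(person_idx)) else has_day2[person_idx]
    p <- person_idx[sel]
    m <- menu_idx[sel]
    grams <- exp(menu$mu_log_g[m] + .AGE_SHIFT[age_group[p]] + b[p] +
                   w_day[cbind(p, d)] +
                   stats::rnorm(length(p), 0, menu$sigma_log_g[m]))
    data.frame(individual_id = id[p], day_index = d,
               meal_code = menu$meal_code[m],
               food_code = menu$food_code[m],
               grams = grams, person = p, stringsAsFactors = FALSE)
  })
  recalls <- rbind(day_list[[1]], day_list[[2]])

  # thin skipper breakfasts: scale grams so breakfast energy lands at a
  # random 5-30 kcal on every recorded day (< 50 kcal by construction)
  bkf <- recalls$meal_code == 1 & skipper[recalls$person]
  if (any(bkf)) {
    e100 <- config$fct$energy_kcal[match(recalls$food_code[bkf],
                                         config$fct$food_code)]
    line_energy <- recalls$grams[bkf] * e100 / 100
    key <- paste(recalls$person[bkf], recalls$day_index[bkf])
    day_energy <- tapply(line_energy, key, sum)
    target <- stats::runif(length(day_energy), 5, 30)
    names(target) <- names(day_energy)
    factor <- pmin(1, target[key] / pmax(day_energy[key], 1e-9))
    recalls$grams[bkf] <- recalls$grams[bkf] * factor
  }

  # conversely a non-skipper's breakfast is a real meal: the rare draw that
  # lands under 50 kcal (e.g. a habitual menu of coffee alone) is scaled up
  # to a modest breakfast so the skipper flag is the sole source of truth
  nbk <- recalls$meal_code == 1 & !skipper[recalls$person]
  if (any(nbk)) {
    e100 <- config$fct$energy_kcal[match(recalls$food_code[nbk],
                                         config$fct$food_code)]
    line_energy <- recalls$grams[nbk] * e100 / 100
    key <- paste(recalls$person[nbk], recalls$day_index[nbk])
    day_energy <- tapply(line_energy, key, sum)
    low <- day_energy < 50
    if (any(low)) {
      target <- stats::setNames(stats::runif(sum(low), 55, 85),
                                names(day_energy)[low])
      factor <- rep(1, length(key))
      idx <- key %in% names(target)
      factor[idx] <- target[key[idx]] / pmax(day_energy[key[idx]], 1e-9)
      recalls$grams[nbk] <- recalls$grams[nbk] * factor
    }
  }
  recalls$person <- NULL
  rownames(recalls) <- NULL

  truth <- list(config = config,
                individuals = data.frame(id = id, age_group = age_group,
                                         person_effect = b,
                                         skipper = skipper,
                                         has_day2 = has_day2,
                                         stringsAsFactors = FALSE))
  list(individuals = individuals, recalls = recalls, fct = config$fct,
       truth = truth)
}

#' Write a simulated dataset to a directory
#'
#' Writes `individuals.csv`, `recalls.csv`, `food_composition.csv` and
#' `truth.json` under `dir`.
#'
#' @param sim Output of [simulate_survey()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_individuals(sim$individuals, file.path(dir, "individuals.csv"))
  write_recalls(sim$recalls, file.path(dir, "recalls.csv"))
  write_food_composition(sim$fct, file.path(dir, "food_composition.csv"))
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  truth$config$food_menu <- NULL
  truth$config$fct <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
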