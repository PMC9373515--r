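test_that("percent of daily intake handles boundaries and errors", {
  expect_equal(pct_daily(20, 80), 25)
  expect_equal(pct_daily(80, 80), 100)
  expect_true(is.na(pct_daily(0, 0)))
  expect_error(pct_daily(5, 0), "zero daily")
})

test_that("percent of recommendation is uncapped with printed DVs", {
  ref <- reference_table()
  expect_equal(pct_recommendation(13.5, ref$dv[["protein_g"]]), 27)
  expect_equal(pct_recommendation(0, 50), 0)
  expect_error(pct_recommendation(10, 0), "> 0")
  # a vector at exactly the DV amounts is 100% for all nine nutrients
  expect_equal(unname(pct_recommendation(ref$dv, ref$dv)), rep(100, 9))
})

test_that("aggregate percentages equal the raw-totals oracle", {
  sim <- simulate_survey(simulation_config(n_individuals = 40, seed = 43))
  sc <- nrf_scores(sim$recalls, sim$fct, sim$individuals)
  ag <- "adults_19_59"
  rep_df <- benchmark_report(sim$recalls, sim$fct, sim$individuals, sc,
                             age_group = ag, restrict_tertile = NULL,
                             weighted = TRUE)
  # oracle: weighted sums of per-individual window intakes, ratio taken once
  ids <- sc$individual_id[sc$age_group == ag]
  w <- sim$individuals$sampling_weight[match(ids, sim$individuals$id)]
  bkf <- window_intake(sim$recalls, sim$fct, ids = ids, meals = 1)
  day <- window_intake(sim$recalls, sim$fct, ids = ids, meals = NULL)
  for (nut in c("energy_kcal", "protein_g", "calcium_mg")) {
    oracle <- 100 * sum(w * bkf[[nut]]) / sum(w * day[[nut]])
    expect_equal(rep_df$pct_of_daily_intake[rep_df$nutrient == nut],
                 oracle, tolerance = 1e-12)
    rec <- reference_table()$recommendation[[nut]]
    oracle_rec <- 100 * (sum(w * bkf[[nut]]) / sum(w)) / rec
    expect_equal(
      rep_df$pct_of_recommendation_breakfast[rep_df$nutrient == nut],
      oracle_rec, tolerance = 1e-12)
  }
})

test_that("breakfast contribution never exceeds the daily contribution", {
  sim <- simulate_survey(simulation_config(n_individuals = 40, seed = 47))
  sc <- nrf_scores(sim$recalls, sim$fct, sim$individuals)
  for (ag in unique(sc$age_group)) {
    for (restrict in list(NULL, "T3")) {
      rep_df <- benchmark_report(sim$recalls, sim$fct, sim$individuals, sc,
                                 age_group = ag,
                                 restrict_tertile = restrict)
      expect_true(all(rep_df$pct_of_recommendation_breakfast <=
                        rep_df$pct_of_recommendation_daily + 1e-9))
      expect_true(all(rep_df$pct_of_daily_intake <= 100 + 1e-9))
    }
  }
})

test_that("the 20% benchmark flags exactly the nutrients at or above it", {
  fct <- tiny_fct()
  ref <- reference_table()
  # three individuals eating only 'staple' at breakfast, sized so protein
  # per day = 25% of its DV; daily = breakfast (no other meals)
  ids <- c("a", "b", "c")
  grams <- 100 * 0.25 * ref$dv[["protein_g"]] / 10  # 10 g protein / 100 g
  rec <- food_line(ids, 1, 1, "staple", grams)
  ind <- tiny_individuals(ids)
  sc <- nrf_scores(rec, fct, ind)
  rep_df <- benchmark_report(rec, fct, ind, sc, "adults_19_59",
                             restrict_tertile = NULL, ref = ref)
  prot <- rep_df[rep_df$nutrient == "protein_g", ]
  expect_equal(prot$pct_of_recommendation_breakfast, 25)
  expect_true(prot$meets_20pct)
  # fiber: staple has 2 g / 100 g -> 2.5 g vs DV 25 g = 10% -> flagged FALSE
  fib <- rep_df[rep_df$nutrient == "fiber_g", ]
  expect_equal(fib$pct_of_recommendation_breakfast,
               100 * grams / 100 * 2 / 25)
  expect_false(fib$meets_20pct)
  expect_equal(rep_df$meets_20pct,
               rep_df$pct_of_recommendation_breakfast >= 20)
})

test_that("an empty restricted population errors", {
  fct <- tiny_fct()
  rec <- food_line(c("a", "b", "c"), 1, 1, "staple", 100)
  ind <- tiny_individuals(c("a", "b", "c"))
  sc <- nrf_scores(rec, fct, ind)
  expect_error(benchmark_report(rec, fct, ind, sc, "children_6_12"),
               "empty")
})
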