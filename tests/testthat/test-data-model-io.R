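test_that("recall files parse, reject bad rows, and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,day_index,meal_code,food_code,grams",
               "a,1,1,staple,150", "a,1,2,plain,80", "b,1,3,sweet,10"),
             path)
  rec <- read_recalls(path)
  expect_equal(nrow(rec), 3)
  expect_equal(sum(rec$meal_code == 1), 1)

  writeLines("individual_id,day_index,meal_code,food_code,grams", path)
  expect_equal(nrow(read_recalls(path)), 0)

  writeLines(c("individual_id,day_index,meal_code,food_code,grams",
               "a,1,1,staple,-5"), path)
  expect_error(read_recalls(path), "negative grams.*row")

  writeLines(c("individual_id,day_index,meal_code,grams",
               "a,1,1,10"), path)
  expect_error(read_recalls(path), "food_code")

  writeLines(c("individual_id,day_index,meal_code,food_code,grams",
               "a,1,1,staple,ten"), path)
  expect_error(read_recalls(path), "unparseable.*row")

  # round-trip identity, comma and tab
  rec <- food_line(c("a", "a", "b"), c(1, 2, 1), c(1, 1, 2),
                   c("staple", "sweet", "plain"), c(150.5, 10, 80))
  for (sep in c(",", "\t")) {
    write_recalls(rec, path, sep = sep)
    expect_equal(read_recalls(path), rec)
  }
})

test_that("intake computation scales per 100 g and is linear", {
  fct <- tiny_fct()
  one <- compute_intake(food_line("a", 1, 1, "staple", 150), fct)
  expect_equal(one[["protein_g"]], 15)
  expect_equal(one[["energy_kcal"]], 150)

  empty <- compute_intake(food_line("a", 1, 1, "x", 1)[0, ], fct)
  expect_true(all(empty == 0))

  split2 <- compute_intake(
    rbind(food_line("a", 1, 1, "staple", 50),
          food_line("a", 1, 1, "staple", 100)), fct)
  expect_equal(split2, one)

  expect_error(compute_intake(food_line("a", 1, 1, "nope", 10), fct),
               "nope")

  # linearity over random partitions and scalings
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    lines <- food_line(rep("a", n), 1, 1,
                       sample(fct$food_code, n, replace = TRUE),
                       runif(n, 0, 300))
    cut <- sample(n - 1, 1)
    a <- lines[seq_len(cut), ]; b <- lines[-seq_len(cut), ]
    expect_equal(compute_intake(lines, fct),
                 compute_intake(a, fct) + compute_intake(b, fct))
    alpha <- runif(1, 0.1, 5)
    scaled <- lines; scaled$grams <- scaled$grams * alpha
    expect_equal(compute_intake(scaled, fct),
                 alpha * compute_intake(lines, fct))
  }
})

test_that("reference table holds the printed amounts and validates", {
  ref <- reference_table()
  expect_equal(unname(ref$dv[c("protein_g", "fiber_g", "iron_mg")]),
               c(50, 25, 18))
  expect_equal(unname(ref$mrv[c("total_sugar_g", "saturated_fat_g",
                                "sodium_mg")]),
               c(50, 20, 2400))
  expect_setequal(names(ref$dv), nutrient_names("qualifying"))
  expect_setequal(names(ref$mrv), nutrient_names("limiting"))
  expect_error(reference_table(dv = c(protein_g = 50)), "nine qualifying")
  expect_error(reference_table(mrv = c(total_sugar_g = -1,
                                       saturated_fat_g = 20,
                                       sodium_mg = 2400)),
               "positive|limiting")
})

test_that("reference yaml overrides work per stratum", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "dv:", "  protein_g: 50", "  fiber_g: 25", "  vitamin_a_re_ug: 1500",
    "  vitamin_c_mg: 60", "  vitamin_d_ug: 10", "  calcium_mg: 1000",
    "  iron_mg: 18", "  potassium_mg: 3500", "  magnesium_mg: 400",
    "mrv:", "  total_sugar_g: 50", "  saturated_fat_g: 20",
    "  sodium_mg: 2400",
    "children_6_12:", "  dv:", "    protein_g: 30"), path)
  ref <- read_reference_yaml(path)
  expect_equal(ref$dv[["protein_g"]], 50)
  ref_child <- read_reference_yaml(path, age_group = "children_6_12")
  expect_equal(ref_child$dv[["protein_g"]], 30)
  expect_equal(ref_child$dv[["fiber_g"]], 25)
})

test_that("nutrient vectors enforce the controlled vocabulary", {
  v <- nutrient_vector(energy_kcal = 100, protein_g = 5)
  expect_equal(sort(names(v)), sort(nutrient_names("core")))
  expect_equal(v[["fiber_g"]], 0)
  expect_error(nutrient_vector(protein = 5), "unknown nutrient")
  expect_error(nutrient_vector(protein_g = -1), ">= 0")
})
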