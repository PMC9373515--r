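test_that("the 50 kcal rule sits exactly on the boundary", {
  fct <- tiny_fct()  # staple: 100 kcal / 100 g
  st <- classify_breakfast(food_line("a", 1, 1, "staple", 49.9), fct)
  expect_equal(st$status, "skipper")
  st <- classify_breakfast(food_line("a", 1, 1, "staple", 50), fct)
  expect_equal(st$breakfast_energy_kcal, 50)
  expect_equal(st$status, "consumer")
})

test_that("a recorded day without breakfast lines counts as 0 kcal", {
  fct <- tiny_fct()
  # only lunch recorded: still classified, as a skipper at 0 kcal
  st <- classify_breakfast(food_line("a", 1, 2, "staple", 200), fct)
  expect_equal(st$breakfast_energy_kcal, 0)
  expect_equal(st$energy_day1, 0)
  expect_equal(st$status, "skipper")
  # no lines at all (id supplied explicitly)
  st <- classify_breakfast(food_line("b", 1, 2, "staple", 200), fct,
                           ids = c("a", "b"))
  expect_equal(st$status[st$individual_id == "a"], "skipper")
  expect_equal(st$breakfast_energy_kcal[st$individual_id == "a"], 0)
})

test_that("two-day averaging and the day-1-only flag behave as documented", {
  fct <- tiny_fct()
  rec <- rbind(food_line("a", 1, 1, "staple", 80),   # 80 kcal day 1
               food_line("a", 2, 1, "staple", 10),   # 10 kcal day 2
               food_line("a", 2, 2, "plain", 100))
  st <- classify_breakfast(rec, fct)
  expect_equal(st$breakfast_energy_kcal, 45)  # (80 + 10) / 2
  expect_equal(st$status, "skipper")
  st1 <- classify_breakfast(rec, fct, day1_only = TRUE)
  expect_equal(st1$breakfast_energy_kcal, 80)
  expect_equal(st1$status, "consumer")
})

test_that("classification is monotone in breakfast energy", {
  fct <- tiny_fct()
  set.seed(7)
  for (i in 1:25) {
    g <- runif(1, 0, 120)
    base <- classify_breakfast(food_line("a", 1, 1, "staple", g), fct)
    more <- classify_breakfast(food_line("a", 1, 1, "staple",
                                         g + runif(1, 0, 100)), fct)
    expect_false(base$status == "consumer" && more$status == "skipper")
  }
})

test_that("regularity table matches the hand-computed chi-square", {
  fct <- tiny_fct()
  # 2x2 table (10,20; 20,10): chi-square = 6.6667
  n <- 60
  ids <- sprintf("i%02d", 1:n)
  sex <- rep(c("male", "female"), each = 30)
  consumer <- c(rep(c(TRUE, FALSE), c(10, 20)), rep(c(TRUE, FALSE), c(20, 10)))
  grams <- ifelse(consumer, 100, 10)  # 100 or 10 kcal of staple
  rec <- food_line(ids, 1, 1, "staple", grams)
  ind <- tiny_individuals(ids, sex = sex)
  st <- classify_breakfast(rec, fct, ids = ids)
  rt <- regularity_table(st, ind, "sex", weighted = FALSE)
  expect_equal(rt$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(rt$p_value, stats::pchisq(20 / 3, 1, lower.tail = FALSE))
  # row percentages sum to 100 within every stratum
  sums <- tapply(rt$table$percent, rt$table$stratum, sum)
  expect_equal(as.vector(sums), rep(100, 2))
})

test_that("a degenerate margin reports an undefined p-value", {
  fct <- tiny_fct()
  ids <- sprintf("i%02d", 1:10)
  rec <- food_line(ids, 1, 1, "staple", 100)
  ind <- tiny_individuals(ids, sex = rep(c("male", "female"), 5))
  st <- classify_breakfast(rec, fct, ids = ids)
  rt <- regularity_table(st, ind, "sex")
  expect_true(is.na(rt$p_value))
  expect_error(regularity_table(st, ind, "shoe_size"), "covariate")
})

test_that("weights shift the table but normalisation keeps scale", {
  fct <- tiny_fct()
  ids <- c("a", "b", "c", "d")
  rec <- food_line(ids, 1, 1, "staple", c(100, 100, 10, 10))
  ind <- tiny_individuals(ids, sex = c("male", "male", "female", "female"),
                          weight = c(3, 1, 1, 1))
  st <- classify_breakfast(rec, fct, ids = ids)
  rt <- regularity_table(st, ind, "sex", weighted = TRUE)
  tab <- rt$table
  # weighted counts rescale to the sample size of 4
  expect_equal(sum(tab$weighted_n), 4)
  expect_equal(tab$weighted_n[tab$stratum == "male" &
                                tab$status == "consumer"], 8 / 3)
})
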