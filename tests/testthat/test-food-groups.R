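test_that("the 10 g consumer rule sits exactly on the boundary", {
  expect_equal(consumer_score(c(0, 9.99, 10, 10.01, 250)),
               c(0L, 0L, 1L, 1L, 1L))
  expect_error(consumer_score(-1), ">= 0")
})

test_that("group grams average over available days and fill zeros", {
  fct <- tiny_fct()
  rec <- rbind(food_line("a", 1, 1, "staple", 100),
               food_line("a", 2, 1, "staple", 50),
               food_line("a", 2, 1, "sweet", 20),
               food_line("b", 1, 1, "plain", 5))
  gg <- food_group_grams(rec, fct, ids = c("a", "b"))
  g <- function(id, grp) gg$grams[gg$individual_id == id &
                                    gg$food_group == grp]
  expect_equal(g("a", "STAPLE"), 75)   # (100 + 50) / 2 days
  expect_equal(g("a", "SWEETS"), 10)   # (0 + 20) / 2
  expect_equal(g("b", "PLAIN"), 5)
  expect_equal(g("b", "STAPLE"), 0)
  expect_equal(gg$consumer, consumer_score(gg$grams))
})

test_that("top groups rank by weighted consumer share with ties alphabetical", {
  gg <- data.frame(
    individual_id = rep(c("a", "b", "c", "d"), 3),
    food_group = rep(c("ALPHA", "BETA", "GAMMA"), each = 4),
    grams = c(20, 20, 20, 0,   20, 0, 0, 0,   0, 20, 0, 0),
    stringsAsFactors = FALSE)
  gg$consumer <- consumer_score(gg$grams)
  ind <- tiny_individuals(c("a", "b", "c", "d"))
  top <- top_groups(gg, ind, k = 2)
  expect_equal(top$food_group, c("ALPHA", "BETA"))  # 75%, then 25% tie -> alpha
  expect_warning(top_groups(gg, ind, k = 5), "only 3")
})

test_that("rice dominates breakfast in the default menu", {
  sim <- simulate_survey(simulation_config(n_individuals = 80, seed = 29))
  sc <- nrf_scores(sim$recalls, sim$fct, sim$individuals)
  gg <- food_group_grams(sim$recalls, sim$fct, ids = sc$individual_id)
  top <- top_groups(gg, sim$individuals, k = 3)
  expect_equal(top$food_group[1], "RICE")
})

test_that("tertile group table reports means among consumers", {
  fct <- tiny_fct()
  n <- 12
  ids <- sprintf("i%02d", 1:n)
  rec <- food_line(ids, 1, 1, "staple", 100)  # everyone: 100 g, 100 kcal
  ind <- tiny_individuals(ids)
  sc <- nrf_scores(rec, fct, ind)
  tg <- tertile_group_table(rec, fct, sc, ind)
  staple <- tg$summary[tg$summary$food_group == "STAPLE", ]
  expect_equal(staple$mean_intake_g, rep(100, 3))
  expect_equal(staple$percent_consumers, rep(100, 3))
  # mean among consumers is >= 10 g by construction
  ok <- !is.na(tg$summary$mean_intake_g)
  expect_true(all(tg$summary$mean_intake_g[ok] >= 10))
  # percent consumers equals the weighted mean of the 0/1 score x 100
  gg <- food_group_grams(rec, fct, ids = sc$individual_id)
  pct <- 100 * mean(gg$consumer[gg$food_group == "SWEETS"])
  expect_equal(tg$summary$percent_consumers[
    tg$summary$food_group == "SWEETS"], rep(pct, 3))
})

test_that("a group eaten only by T3 separates with a small p-value", {
  fct <- tiny_fct()
  n <- 30
  ids <- sprintf("i%02d", 1:n)
  # staple grams increase with index -> score varies; sweet only for top third
  rec <- food_line(ids, 1, 1, "staple", 60 + seq_len(n))
  # sweets raise LIM so give them to the individuals with most staple
  top_ids <- ids[(n - 9):n]
  rec2 <- rbind(rec, food_line(top_ids, 1, 1, "sweet", 30))
  ind <- tiny_individuals(ids)
  sc <- nrf_scores(rec2, fct, ind)
  tg <- tertile_group_table(rec2, fct, sc, ind)
  sw <- tg$summary[tg$summary$food_group == "SWEETS", ]
  expect_true(any(sw$percent_consumers == 0) &&
                any(sw$percent_consumers > 0))
  p <- tg$tests$p_value[tg$tests$food_group == "SWEETS"]
  expect_lt(p, 0.01)
})

test_that("tertile group table refuses results without tertiles", {
  fct <- tiny_fct()
  rec <- food_line(c("a", "b", "c"), 1, 1, "staple", 100)
  ind <- tiny_individuals(c("a", "b", "c"))
  sc <- nrf_scores(rec, fct, ind)
  sc$tertile <- NULL
  expect_error(tertile_group_table(rec, fct, sc, ind), "tertile")
})
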