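# NRF9.3 nutrient profiling. The score of an intake window is
#   NRF9.3 = (NR - LIM) * 100
# with NR the sum over the nine qualifying nutrients of the fraction of the
# daily value supplied per 2000 kcal of the window, each fraction capped at
# 1 (an extreme intake of one nutrient cannot compensate a deficiency in
# another), and LIM the sum over the three limiting nutrients of the
# fraction of the maximum recommended value in excess of 1 (only intake
# above the ceiling is penalised, floored at zero per nutrient). The
# maximum attainable score is 900.

#' NRF9.3 score of an intake window
#'
#' Normalises the nutrient vector to 2000 kcal of its own energy, sums the
#' capped daily-value fractions of the nine qualifying nutrients (NR), the
#' excess-over-MRV fractions of the three limiting nutrients (LIM), and
#' returns `(NR - LIM) * 100`. Because the normalisation divides by the
#' window's own energy, the score is invariant under scaling the whole
#' intake by any positive constant.
#'
#' @param intake Nutrient vector (named numeric) with positive
#'   `energy_kcal`.
#' @param ref A [reference_table()].
#' @param cap_nr Cap each qualifying daily-value fraction at 1 (default
#'   `TRUE`); `FALSE` gives the uncapped variant for sensitivity analysis.
#' @return List with `nr`, `lim`, `score` and `scoring_energy_kcal`.
#' @examples
#' ref <- reference_table()
#' perfect <- nutrient_vector(energy_kcal = 2000)
#' perfect[names(ref$dv)] <- ref$dv
#' nrf93(perfect, ref)$score  # 900
#' @export
nrf93 <- function(intake, ref, cap_nr = TRUE) {
  energy <- intake[["energy_kcal"]]
  if (is.na(energy) || energy <= 0)
    stop("cannot score a window with zero or negative energy", call. = FALSE)
  scale <- 2000 / energy
  q <- intake[names(ref$dv)] * scale / ref$dv
  if (cap_nr) q <- pmin(1, q)
  l <- pmax(0, intake[names(ref$mrv)] * scale / ref$mrv - 1)
  nr <- sum(q)
  lim <- sum(l)
  list(nr = nr, lim = lim, score = (nr - lim) * 100,
       scoring_energy_kcal = energy)
}

# vectorised scoring of an intake data.frame (one row per individual)
.nrf93_rows <- function(win, ref, cap_nr = TRUE) {
  energy <- win$energy_kcal
  scale <- 2000 / energy
  qmat <- sweep(as.matrix(win[names(ref$dv)]) * scale, 2, ref$dv, "/")
  if (cap_nr) qmat <- pmin(qmat, 1)
  lmat <- pmax(sweep(as.matrix(win[names(ref$mrv)]) * scale, 2,
                     ref$mrv, "/") - 1, 0)
  nr <- rowSums(qmat)
  lim <- rowSums(lmat)
  data.frame(individual_id = win$individual_id, nr = nr, lim = lim,
             score = (nr - lim) * 100, scoring_energy_kcal = energy,
             stringsAsFactors = FALSE)
}

#' Assign within-group score tertiles
#'
#' Ranks individuals by score (ascending, ties broken by id so the split is
#' deterministic) and cuts the ranks at `ceiling(n/3)` and `ceiling(2n/3)`:
#' T1 holds the poorest-scoring third, T3 the healthiest. Tertile sizes
#' differ by at most one.
#'
#' @param results `data.frame` with `individual_id` and `score` columns,
#'   plus a grouping column when `by` is given.
#' @param by Optional name of a grouping column (e.g. `"age_group"`);
#'   tertiles are then assigned within each group.
#' @return `results` with a `tertile` column (`"T1"`, `"T2"`, `"T3"`).
#' @export
assign_tertiles <- function(results, by = NULL) {
  split_one <- function(df) {
    n <- nrow(df)
    if (n < 3L) stop("need at least 3 individuals to form tertiles",
                     call. = FALSE)
    ord <- order(df$score, df$individual_id)
    rank <- integer(n)
    rank[ord] <- seq_len(n)
    cut1 <- ceiling(n / 3)
    cut2 <- ceiling(2 * n / 3)
    df$tertile <- ifelse(rank <= cut1, "T1",
                         ifelse(rank <= cut2, "T2", "T3"))
    df
  }
  if (is.null(by)) return(split_one(results))
  parts <- split(results, results[[by]])
  out <- do.call(rbind, lapply(parts, split_one))
  rownames(out) <- NULL
  out
}

#' Score breakfast diet quality for a cohort
#'
#' Computes the breakfast intake window of every individual (meal code 1,
#' averaged over available recall days), drops breakfast skippers (window
#' energy below `min_energy_kcal`; they have no scorable breakfast), scores
#' the remaining windows with [nrf93()] and assigns within-age-group
#' tertiles.
#'
#' @param recalls Recall `data.frame`.
#' @param fct Food composition `data.frame`.
#' @param individuals Individual covariate `data.frame`.
#' @param ref A [reference_table()] (default [reference_table()]).
#' @param cap_nr See [nrf93()].
#' @param day1_only Score only the first recall day.
#' @param min_energy_kcal Exclusion threshold for skippers (default 50).
#' @return `data.frame` with `individual_id`, `age_group`, `nr`, `lim`,
#'   `score`, `scoring_energy_kcal` and `tertile`.
#' @examples
#' sim <- simulate_survey(simulation_config(n_individuals = 40, seed = 3))
#' scores <- nrf_scores(sim$recalls, sim$fct, sim$individuals)
#' aggregate(score ~ age_group, scores, mean)
#' @export
nrf_scores <- function(recalls, fct, individuals, ref = reference_table(),
                       cap_nr = TRUE, day1_only = FALSE,
                       min_energy_kcal = 50) {
  use <- if (day1_only) recalls[recalls$day_index == 1, , drop = FALSE]
         else recalls
  win <- window_intake(use, fct, ids = individuals$id, meals = 1)
  win <- win[win$energy_kcal >= min_energy_kcal & win$energy_kcal > 0, ,
             drop = FALSE]
  if (nrow(win) == 0L) stop("no scorable breakfast windows", call. = FALSE)
  res <- .nrf93_rows(win, ref, cap_nr = cap_nr)
  res$age_group <- individuals$age_group[match(res$individual_id,
                                               individuals$id)]
  res <- assign_tertiles(res, by = "age_group")
  res[c("individual_id", "age_group", "nr", "lim", "score",
        "scoring_energy_kcal", "tertile")]
}
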