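# Percentage contribution of breakfast to daily intake and to daily
# recommendations, with a 20% benchmark: a breakfast supplying roughly a
# fifth to a quarter of the day's requirement of each nutrient is the
# working definition of an adequate breakfast.

#' Percent of daily intake supplied by breakfast
#'
#' `100 * breakfast / daily`, vectorised. Both zero is undefined and
#' reported as `NA`; breakfast exceeding a zero daily intake is an
#' inconsistency (breakfast is part of the day) and errors.
#'
#' @param breakfast_intake,daily_intake Non-negative amounts (same units).
#' @return Percentages.
#' @examples
#' pct_daily(20, 80)  # 25
#' @export
pct_daily <- function(breakfast_intake, daily_intake) {
  bad <- daily_intake == 0 & breakfast_intake > 0
  if (any(bad, na.rm = TRUE))
    stop("breakfast intake positive with zero daily intake", call. = FALSE)
  out <- 100 * breakfast_intake / daily_intake
  out[daily_intake == 0 & breakfast_intake == 0] <- NA_real_
  out
}

#' Percent of a recommendation supplied by an intake
#'
#' `100 * intake / recommendation`, uncapped.
#'
#' @param intake Non-negative amount.
#' @param recommendation Positive recommended daily amount (same units).
#' @return Percentages.
#' @export
pct_recommendation <- function(intake, recommendation) {
  if (any(recommendation <= 0, na.rm = TRUE))
    stop("recommendation amounts must be > 0", call. = FALSE)
  100 * intake / recommendation
}

#' Contribution-to-recommendation report with 20% benchmarking
#'
#' For one age group -- optionally restricted to a tertile of the breakfast
#' NRF9.3 distribution, e.g. T3 = healthiest -- computes per nutrient the
#' weighted mean breakfast intake and weighted mean daily (all-meal)
#' intake, then expresses breakfast as a percent of daily intake and both
#' windows as percents of the daily recommendation, flagging nutrients
#' whose breakfast contribution falls short of the 20% benchmark.
#' Population-level percentages are ratios of weighted mean intakes by
#' default (`mode = "aggregate"`); `mode = "individual"` averages the
#' per-individual ratios instead.
#'
#' @param recalls Recall `data.frame`.
#' @param fct Food composition `data.frame`.
#' @param individuals Individual covariate `data.frame`.
#' @param nrf_results Output of [nrf_scores()].
#' @param age_group Age group to report on.
#' @param restrict_tertile Optional tertile label (e.g. `"T3"`) restricting
#'   the population; `NULL` keeps all scored individuals of the age group.
#' @param ref A [reference_table()]; its `recommendation` map supplies the
#'   denominators.
#' @param nutrients Nutrients to report (default: those present in the
#'   recommendation map and in `fct`).
#' @param weighted Use sampling weights (default `TRUE`).
#' @param mode `"aggregate"` (ratio of weighted means, default) or
#'   `"individual"` (weighted mean of per-individual ratios) for the
#'   percent-of-daily-intake column.
#' @param benchmark Benchmark percent (default 20).
#' @return `data.frame`: `age_group`, `tertile`, `nutrient`,
#'   `breakfast_intake`, `daily_intake`, `pct_of_daily_intake`,
#'   `pct_of_recommendation_breakfast`, `pct_of_recommendation_daily`,
#'   `meets_20pct`.
#' @export
benchmark_report <- function(recalls, fct, individuals, nrf_results,
                             age_group, restrict_tertile = "T3",
                             ref = reference_table(), nutrients = NULL,
                             weighted = TRUE, mode = c("aggregate",
                                                       "individual"),
                             benchmark = 20) {
  mode <- match.arg(mode)
  res <- nrf_results[nrf_results$age_group == age_group, , drop = FALSE]
  if (!is.null(restrict_tertile))
    res <- res[res$tertile == restrict_tertile, , drop = FALSE]
  if (nrow(res) == 0L)
    stop("restricted population is empty (", age_group,
         if (!is.null(restrict_tertile)) paste0(", ", restrict_tertile),
         ")", call. = FALSE)
  ids <- res$individual_id
  if (is.null(nutrients))
    nutrients <- intersect(names(ref$recommendation),
                           intersect(nutrient_names("all"), names(fct)))
  bkf <- window_intake(recalls, fct, ids = ids, meals = 1)
  day <- window_intake(recalls, fct, ids = ids, meals = NULL)
  w <- if (weighted) individuals$sampling_weight[match(ids, individuals$id)]
       else rep(1, length(ids))

  rows <- lapply(nutrients, function(nut) {
    b <- bkf[[nut]][match(ids, bkf$individual_id)]
    d <- day[[nut]][match(ids, day$individual_id)]
    mb <- weighted_mean_se(b, w)$value
    md <- weighted_mean_se(d, w)$value
    p_daily <- if (mode == "aggregate") pct_daily(mb, md)
               else weighted_mean_se(pct_daily(b, d), w)$value
    rec <- ref$recommendation[[nut]]
    pb <- pct_recommendation(mb, rec)
    pd <- pct_recommendation(md, rec)
    data.frame(age_group = age_group,
               tertile = restrict_tertile %||% "all",
               nutrient = nut, breakfast_intake = mb, daily_intake = md,
               pct_of_daily_intake = p_daily,
               pct_of_recommendation_breakfast = pb,
               pct_of_recommendation_daily = pd,
               meets_20pct = pb >= benchmark, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
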