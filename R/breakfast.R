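# Breakfast consumer vs skipper classification. A skipper is an individual
# whose breakfast (meal code 1) supplies less than 50 kcal of energy --
# including the case of no breakfast record at all. Consumers are at or
# above 50 kcal.

#' Classify individuals as breakfast consumers or skippers
#'
#' Breakfast energy is computed from meal-code-1 lines, summed over the
#' recall days an individual has on record and divided by the number of
#' those days (so one-day and two-day individuals are comparable). Status
#' is `"skipper"` when that energy is below 50 kcal, `"consumer"` at or
#' above 50 kcal. Individuals with no breakfast lines get 0 kcal and are
#' skippers.
#'
#' @param recalls Recall `data.frame`.
#' @param fct Food composition `data.frame`.
#' @param ids Individuals to classify (default: everyone in `recalls`).
#' @param day1_only Use only the first recall day instead of the per-day
#'   average over available days (default `FALSE`).
#' @param threshold_kcal Energy cutoff in kcal (default 50).
#' @return `data.frame` with `individual_id`, per-day breakfast energies
#'   (`energy_day1`, `energy_day2`), the classification energy
#'   `breakfast_energy_kcal`, `n_days` and `status`.
#' @examples
#' sim <- simulate_survey(simulation_config(n_individuals = 30, seed = 2))
#' table(classify_breakfast(sim$recalls, sim$fct)$status)
#' @export
classify_breakfast <- function(recalls, fct, ids = NULL, day1_only = FALSE,
                               threshold_kcal = 50) {
  if (is.null(ids)) ids <- sort(unique(recalls$individual_id))
  ids <- as.character(ids)
  use <- if (day1_only) recalls[recalls$day_index == 1, , drop = FALSE]
         else recalls
  win <- window_intake(use, fct, ids = ids, meals = 1)
  per_day <- .daily_totals(recalls, fct, meals = 1)
  day_energy <- function(d) {
    rows <- per_day[per_day$day_index == d, , drop = FALSE]
    e <- stats::setNames(rep(NA_real_, length(ids)), ids)
    # a recorded day with no breakfast lines is 0 kcal, not missing
    has_day <- tapply(recalls$day_index, recalls$individual_id,
                      function(x) d %in% x)
    seen <- intersect(names(has_day)[unlist(has_day)], ids)
    e[seen] <- 0
    hit <- intersect(rows$individual_id, ids)
    e[hit] <- rows$energy_kcal[match(hit, rows$individual_id)]
    e
  }
  e1 <- day_energy(1)
  e2 <- day_energy(2)
  energy <- win$energy_kcal[match(ids, win$individual_id)]
  data.frame(individual_id = ids,
             energy_day1 = unname(e1),
             energy_day2 = unname(e2),
             breakfast_energy_kcal = energy,
             n_days = win$n_days[match(ids, win$individual_id)],
             status = ifelse(energy < threshold_kcal, "skipper", "consumer"),
             stringsAsFactors = FALSE)
}

#' Breakfast regularity by a covariate stratum
#'
#' Cross-tabulates consumer/skipper status against one covariate of the
#' individual table, with weighted counts and row percentages, and tests
#' the association with a Pearson chi-square on the weighted table rescaled
#' to the unweighted sample size (weights normalised to mean one; no
#' design-based correction).
#'
#' @param statuses Output of [classify_breakfast()].
#' @param individuals Individual covariate `data.frame`.
#' @param stratifier Name of the covariate column to stratify by.
#' @param weighted Use sampling weights (default `TRUE`).
#' @return List with `table` (stratum, status, weighted n, row percent),
#'   `statistic` and `p_value` (`NA` with a degenerate margin).
#' @export
regularity_table <- function(statuses, individuals, stratifier,
                             weighted = TRUE) {
  if (!stratifier %in% names(individuals))
    stop("stratifier '", stratifier, "' is not a covariate of individuals",
         call. = FALSE)
  m <- merge(statuses[c("individual_id", "status")], individuals,
             by.x = "individual_id", by.y = "id")
  m <- m[!is.na(m[[stratifier]]), , drop = FALSE]
  if (nrow(m) == 0L) stop("no individuals with non-missing stratifier",
                          call. = FALSE)
  w <- if (weighted) m$sampling_weight else rep(1, nrow(m))
  w <- w / mean(w)
  stratum <- as.character(m[[stratifier]])
  totals <- tapply(w, stratum, sum)
  empty <- names(totals)[is.na(totals) | totals == 0]
  if (length(empty)) {
    warning("excluding empty stratum/strata: ",
            paste(empty, collapse = ", "), call. = FALSE)
    keep <- !stratum %in% empty
    m <- m[keep, , drop = FALSE]; w <- w[keep]; stratum <- stratum[keep]
  }
  counts <- tapply(w, list(stratum, m$status), sum, default = 0)
  tab <- as.data.frame(as.table(counts), stringsAsFactors = FALSE)
  names(tab) <- c("stratum", "status", "weighted_n")
  row_tot <- tapply(tab$weighted_n, tab$stratum, sum)
  tab$percent <- 100 * tab$weighted_n / row_tot[tab$stratum]
  tab <- tab[order(tab$stratum, tab$status), ]
  rownames(tab) <- NULL

  if (ncol(counts) < 2L || nrow(counts) < 2L) {
    stat <- NA_real_; p <- NA_real_
  } else {
    rescaled <- counts * nrow(m) / sum(counts)
    ht <- suppressWarnings(stats::chisq.test(rescaled, correct = FALSE))
    stat <- unname(ht$statistic); p <- ht$p.value
  }
  list(stratifier = stratifier, table = tab, statistic = stat, p_value = p)
}
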