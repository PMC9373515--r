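# Food-group consumption at breakfast. An individual is a consumer of a
# group when their (per-day average) breakfast intake of that group is at
# least 10 g; mean group intake is reported among consumers, paired with
# the percent of consumers, as in survey food-pattern tables.

#' Binary consumer score for a food group
#'
#' 1 if at least 10 g was consumed, 0 below 10 g.
#'
#' @param grams Non-negative grams (vectorised).
#' @param cutoff_g Gram cutoff (default 10).
#' @return Integer 0/1 vector.
#' @examples
#' consumer_score(c(0, 9.99, 10, 250))
#' @export
consumer_score <- function(grams, cutoff_g = 10) {
  if (any(grams < 0, na.rm = TRUE))
    stop("grams must be >= 0", call. = FALSE)
  as.integer(grams >= cutoff_g)
}

#' Per-individual food-group grams over a meal window
#'
#' Grams per food group summed over the window's meal codes and recall
#' days, divided by the number of days on record (per-day average), for
#' every individual in `ids`. Groups absent from an individual's lines are
#' reported as 0 g.
#'
#' @inheritParams window_intake
#' @return Long `data.frame`: `individual_id`, `food_group`, `grams`,
#'   `consumer` (0/1).
#' @export
food_group_grams <- function(recalls, fct, ids = NULL, meals = 1) {
  if (is.null(ids)) ids <- sort(unique(recalls$individual_id))
  ids <- as.character(ids)
  groups <- sort(unique(fct$food_group))
  k <- .days_on_record(recalls, ids)
  lines <- recalls
  if (!is.null(meals)) lines <- lines[lines$meal_code %in% meals, , drop = FALSE]
  lines <- lines[lines$individual_id %in% ids, , drop = FALSE]
  mat <- matrix(0, nrow = length(ids), ncol = length(groups),
                dimnames = list(ids, groups))
  if (nrow(lines)) {
    grp <- fct$food_group[match(lines$food_code, fct$food_code)]
    if (anyNA(grp))
      stop("food code(s) not in composition table: ",
           paste(unique(lines$food_code[is.na(grp)]), collapse = ", "),
           call. = FALSE)
    sums <- tapply(lines$grams, list(lines$individual_id, grp), sum,
                   default = 0)
    mat[rownames(sums), colnames(sums)] <- sums
  }
  mat <- mat / k[ids]
  out <- data.frame(individual_id = rep(ids, times = length(groups)),
                    food_group = rep(groups, each = length(ids)),
                    grams = as.vector(mat), stringsAsFactors = FALSE)
  out$consumer <- consumer_score(out$grams)
  out
}

#' Top consumed food groups
#'
#' Ranks food groups by overall weighted percent of consumers (descending,
#' ties broken alphabetically) and returns the first `k`.
#'
#' @param group_grams Output of [food_group_grams()].
#' @param individuals Individual covariate `data.frame` (for weights).
#' @param k Number of groups to return (default 10).
#' @param weighted Use sampling weights (default `TRUE`).
#' @return `data.frame` with `food_group` and `percent_consumers`, ranked.
#' @export
top_groups <- function(group_grams, individuals, k = 10, weighted = TRUE) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  w <- if (weighted)
    individuals$sampling_weight[match(group_grams$individual_id,
                                      individuals$id)]
  else rep(1, nrow(group_grams))
  parts <- split(seq_len(nrow(group_grams)), group_grams$food_group)
  pct <- vapply(parts, function(i)
    weighted_mean_se(group_grams$consumer[i], w[i])$value * 100, numeric(1))
  out <- data.frame(food_group = names(pct), percent_consumers = unname(pct),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percent_consumers, out$food_group), ]
  rownames(out) <- NULL
  if (nrow(out) < k)
    warning("only ", nrow(out), " food groups available (k = ", k, ")",
            call. = FALSE)
  utils::head(out, k)
}

# Mann-Whitney-style rank-biserial association between a 0/1 consumer score
# and the (ordered) tertile index. r = 1 - 2U/(n1*n0); p from the normal
# approximation with tie correction (wilcox.test).
.rank_biserial <- function(consumer, tertile_idx) {
  n1 <- sum(consumer == 1); n0 <- sum(consumer == 0)
  if (n1 == 0L || n0 == 0L)
    return(list(r = NA_real_, p_value = NA_real_))
  r <- rank(tertile_idx)
  u1 <- sum(r[consumer == 1]) - n1 * (n1 + 1) / 2
  rb <- 2 * u1 / (n1 * n0) - 1
  ht <- suppressWarnings(
    stats::wilcox.test(tertile_idx[consumer == 1],
                       tertile_idx[consumer == 0],
                       exact = FALSE, correct = FALSE))
  list(r = rb, p_value = ht$p.value)
}

#' Food-group intake by NRF9.3 tertile
#'
#' For each age group, tertile and food group: the weighted mean breakfast
#' intake in grams among consumers of the group (with standard error) and
#' the weighted percent of consumers (with standard error). The association
#' between consuming the group and the tertile is tested per age group by
#' the rank-biserial correlation of the tertile rank against the binary
#' consumer score (a Mann-Whitney-style statistic).
#'
#' @param recalls Recall `data.frame`.
#' @param fct Food composition `data.frame`.
#' @param nrf_results Output of [nrf_scores()] (tertiles assigned).
#' @param individuals Individual covariate `data.frame`.
#' @param weighted Use sampling weights (default `TRUE`).
#' @return List with `summary` (age_group, food_group, tertile,
#'   mean_intake_g, mean_se, n_consumers, percent_consumers, percent_se)
#'   and `tests` (age_group, food_group, rank_biserial, p_value).
#' @export
tertile_group_table <- function(recalls, fct, nrf_results, individuals,
                                weighted = TRUE) {
  if (!"tertile" %in% names(nrf_results))
    stop("nrf_results must carry assigned tertiles", call. = FALSE)
  gg <- food_group_grams(recalls, fct, ids = nrf_results$individual_id,
                         meals = 1)
  gg$tertile <- nrf_results$tertile[match(gg$individual_id,
                                          nrf_results$individual_id)]
  gg$age_group <- nrf_results$age_group[match(gg$individual_id,
                                              nrf_results$individual_id)]
  gg$weight <- if (weighted)
    individuals$sampling_weight[match(gg$individual_id, individuals$id)]
  else 1

  summary_rows <- list(); test_rows <- list()
  for (ag in unique(gg$age_group)) {
    sub_ag <- gg[gg$age_group == ag, , drop = FALSE]
    present <- unique(nrf_results$tertile[nrf_results$age_group == ag])
    if (!all(c("T1", "T2", "T3") %in% present))
      stop("empty tertile in age group ", ag, call. = FALSE)
    for (grp in unique(sub_ag$food_group)) {
      sub <- sub_ag[sub_ag$food_group == grp, , drop = FALSE]
      for (t in c("T1", "T2", "T3")) {
        st <- sub[sub$tertile == t, , drop = FALSE]
        cons <- st[st$consumer == 1, , drop = FALSE]
        mi <- if (nrow(cons)) weighted_mean_se(cons$grams, cons$weight)
              else list(value = NA_real_, se = NA_real_)
        pc <- weighted_mean_se(st$consumer, st$weight)
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          age_group = ag, food_group = grp, tertile = t,
          mean_intake_g = mi$value, mean_se = mi$se,
          n_consumers = nrow(cons),
          percent_consumers = pc$value * 100, percent_se = pc$se * 100,
          stringsAsFactors = FALSE)
      }
      rb <- .rank_biserial(sub$consumer,
                           match(sub$tertile, c("T1", "T2", "T3")))
      test_rows[[length(test_rows) + 1L]] <- data.frame(
        age_group = ag, food_group = grp, rank_biserial = rb$r,
        p_value = rb$p_value, stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, summary_rows),
       tests = do.call(rbind, test_rows))
}
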