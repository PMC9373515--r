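# Report assembly: runs the full pipeline and shapes its outputs into the
# five report families of a breakfast diet-quality analysis -- regularity
# by covariates, food groups by tertile, mean score and usual intakes by
# age group, nutrients by tertile with trend direction, and the
# contribution-to-recommendation long table.

.DEFAULT_STRATIFIERS <- c("sex", "urbanity", "wealth_quintile",
                          "education", "nutrition_status")

#' Run the breakfast diet-quality pipeline
#'
#' Classifies breakfast status, scores consumers with NRF9.3, assigns
#' within-age-group tertiles, and estimates usual breakfast nutrient
#' intakes (variance shrinkage within each age group). Returns all
#' intermediate artifacts for [build_reports()].
#'
#' @param recalls Recall `data.frame`.
#' @param fct Food composition `data.frame`.
#' @param individuals Individual covariate `data.frame`.
#' @param ref A [reference_table()].
#' @param weighted Use sampling weights in the report estimates.
#' @param usual_nutrients Nutrients to run usual-intake estimation for
#'   (default: the core set).
#' @return List of artifacts: `recalls`, `fct`, `individuals`, `ref`,
#'   `statuses`, `scores`, `usual`, `weighted`.
#' @export
run_breakfast_analysis <- function(recalls, fct, individuals,
                                   ref = reference_table(),
                                   weighted = TRUE,
                                   usual_nutrients = nutrient_names("core")) {
  statuses <- classify_breakfast(recalls, fct, ids = individuals$id)
  scores <- nrf_scores(recalls, fct, individuals, ref = ref)
  usual_parts <- lapply(split(scores$individual_id, scores$age_group),
                        function(ids) {
    u <- usual_intakes(recalls, fct, ids = ids,
                       nutrients = usual_nutrients, meals = 1)$usual
    u
  })
  usual <- do.call(rbind, Map(function(df, ag) {
    df$age_group <- ag; df
  }, usual_parts, names(usual_parts)))
  rownames(usual) <- NULL
  list(recalls = recalls, fct = fct, individuals = individuals, ref = ref,
       statuses = statuses, scores = scores, usual = usual,
       weighted = weighted)
}

.need <- function(analysis, what, module) {
  if (is.null(analysis[[what]]))
    stop("missing upstream artifact '", what, "' (produced by ", module,
         ")", call. = FALSE)
  analysis[[what]]
}

#' Assemble the report bundle
#'
#' Shapes the artifacts of [run_breakfast_analysis()] into five report
#' `data.frame`s: `regularity` (status by covariate strata with chi-square
#' p per age group), `food_groups` (top-10 group intake and percent
#' consumers by tertile, with rank-biserial association p), `age_summary`
#' (weighted mean NRF9.3 score and usual breakfast nutrient intakes by age
#' group), `tertile_nutrients` (usual nutrient intake by tertile with
#' weighted trend direction and p), and `contributions` (percent of daily
#' intake and of recommendation, 20% benchmark flags, for all scored
#' individuals and for the healthiest tertile).
#'
#' @param analysis Artifact list from [run_breakfast_analysis()].
#' @param stratifiers Covariates for the regularity report.
#' @param top_k Number of food groups per age group (default 10).
#' @return Named list of `data.frame`s.
#' @export
build_reports <- function(analysis, stratifiers = .DEFAULT_STRATIFIERS,
                          top_k = 10) {
  recalls <- .need(analysis, "recalls", "data input")
  fct <- .need(analysis, "fct", "data input")
  individuals <- .need(analysis, "individuals", "data input")
  ref <- .need(analysis, "ref", "reference_table")
  statuses <- .need(analysis, "statuses", "classify_breakfast")
  scores <- .need(analysis, "scores", "nrf_scores")
  usual <- .need(analysis, "usual", "usual_intakes")
  weighted <- isTRUE(analysis$weighted)
  nutrients <- setdiff(intersect(nutrient_names("core"), names(usual)),
                       character(0))

  # regularity by covariates, within each age group
  reg_rows <- list()
  for (ag in intersect(age_groups(), unique(individuals$age_group))) {
    ind_ag <- individuals[individuals$age_group == ag, , drop = FALSE]
    st_ag <- statuses[statuses$individual_id %in% ind_ag$id, , drop = FALSE]
    for (sf in intersect(stratifiers, names(ind_ag))) {
      if (all(is.na(ind_ag[[sf]]))) next
      rt <- regularity_table(st_ag, ind_ag, sf, weighted = weighted)
      tab <- rt$table
      tab$age_group <- ag; tab$stratifier <- sf; tab$p_value <- rt$p_value
      reg_rows[[length(reg_rows) + 1L]] <- tab
    }
  }
  regularity <- do.call(rbind, reg_rows)

  # food groups by tertile, top-k per age group
  fg <- tertile_group_table(recalls, fct, scores, individuals,
                            weighted = weighted)
  fg_summary <- merge(fg$summary, fg$tests,
                      by = c("age_group", "food_group"))
  keep_rows <- list()
  for (ag in unique(scores$age_group)) {
    ids <- scores$individual_id[scores$age_group == ag]
    gg <- food_group_grams(recalls, fct, ids = ids, meals = 1)
    top <- suppressWarnings(top_groups(gg, individuals, k = top_k,
                                       weighted = weighted))
    keep_rows[[ag]] <- fg_summary[fg_summary$age_group == ag &
                                    fg_summary$food_group %in%
                                      top$food_group, , drop = FALSE]
  }
  food_groups <- do.call(rbind, keep_rows)
  rownames(food_groups) <- NULL

  # mean NRF score and usual nutrient intakes by age group
  w_of <- function(ids) if (weighted)
    individuals$sampling_weight[match(ids, individuals$id)]
  else rep(1, length(ids))
  age_rows <- list()
  for (ag in unique(scores$age_group)) {
    sc <- scores[scores$age_group == ag, , drop = FALSE]
    us <- usual[usual$age_group == ag, , drop = FALSE]
    est <- weighted_mean_se(sc$score, w_of(sc$individual_id))
    age_rows[[length(age_rows) + 1L]] <- data.frame(
      age_group = ag, quantity = "nrf93_score", mean = est$value,
      se = est$se, n = est$n, stringsAsFactors = FALSE)
    for (nut in nutrients) {
      est <- weighted_mean_se(us[[nut]], w_of(us$individual_id))
      age_rows[[length(age_rows) + 1L]] <- data.frame(
        age_group = ag, quantity = nut, mean = est$value, se = est$se,
        n = est$n, stringsAsFactors = FALSE)
    }
  }
  age_summary <- do.call(rbind, age_rows)

  # usual nutrient intakes by tertile with weighted trend test
  tert_rows <- list()
  for (ag in unique(scores$age_group)) {
    us <- usual[usual$age_group == ag, , drop = FALSE]
    tert <- scores$tertile[match(us$individual_id, scores$individual_id)]
    w <- w_of(us$individual_id)
    for (nut in nutrients) {
      tt <- trend_test(us[[nut]], tert, w)
      for (t in c("T1", "T2", "T3")) {
        est <- weighted_mean_se(us[[nut]][tert == t], w[tert == t])
        tert_rows[[length(tert_rows) + 1L]] <- data.frame(
          age_group = ag, nutrient = nut, tertile = t, mean = est$value,
          se = est$se, n = est$n, trend = tt$direction,
          trend_p = tt$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  tertile_nutrients <- do.call(rbind, tert_rows)

  # contribution long table: all scored individuals and healthiest tertile
  contrib_rows <- list()
  for (ag in unique(scores$age_group)) {
    for (restrict in list(NULL, "T3")) {
      rep_df <- benchmark_report(recalls, fct, individuals, scores, ag,
                                 restrict_tertile = restrict, ref = ref,
                                 weighted = weighted)
      contrib_rows[[length(contrib_rows) + 1L]] <- rep_df
    }
  }
  contributions <- do.call(rbind, contrib_rows)
  rownames(contributions) <- NULL

  list(regularity = regularity, food_groups = food_groups,
       age_summary = age_summary, tertile_nutrients = tertile_nutrients,
       contributions = contributions)
}

#' Write the report bundle to CSV files
#'
#' @param reports Output of [build_reports()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(reports, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (name in names(reports))
    utils::write.csv(reports[[name]],
                     file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}
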