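# Tabular interchange: plain delimiter-separated text (comma by default,
# tab accepted) with required headers. These are deliberately dumb readers
# with loud, named validation errors -- dietary recall files get assembled by
# hand and the failure modes are misnamed columns and stray non-numeric cells.

.RECALL_COLS <- c("individual_id", "day_index", "meal_code", "food_code",
                  "grams")
.INDIVIDUAL_COLS <- c("id", "age_years", "age_group", "sex", "urbanity",
                      "wealth_quintile", "sampling_weight")

.AGE_GROUPS <- c("children_6_12", "adolescents_13_18", "adults_19_59",
                 "elderly_60_plus")

#' Age group labels
#'
#' The four analysis age groups, in reporting order: school-aged children
#' (6-12 y), adolescents (13-18 y), adults (19-59 y) and elderly (60+ y).
#'
#' @return Character vector of length four.
#' @export
age_groups <- function() .AGE_GROUPS

.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) return(",")
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

.read_table <- function(path, sep = c("auto", ",", "\t")) {
  sep <- match.arg(sep)
  if (sep == "auto") sep <- .sniff_sep(path)
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, colClasses = NA,
                    check.names = FALSE, comment.char = "",
                    quote = "\"", na.strings = c("NA", ""))
}

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(df)
}

.check_numeric <- function(df, col, what) {
  x <- df[[col]]
  if (is.character(x)) {
    parsed <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(parsed))
    if (length(bad))
      stop(what, ": column '", col, "' has unparseable value(s) at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    x <- parsed
  }
  x
}

#' Read 24-hour recall food lines
#'
#' One row per recorded food line: individual id, recall day (1 or 2), meal
#' code (1 = breakfast), food code, and grams as consumed.
#'
#' @param path Delimiter-separated text file with a header row.
#' @param sep Field separator: `"auto"` (default; detects tab vs comma),
#'   `","`, or `"\t"`.
#' @return `data.frame` with columns `individual_id`, `day_index`,
#'   `meal_code`, `food_code`, `grams`.
#' @export
read_recalls <- function(path, sep = "auto") {
  df <- .read_table(path, sep)
  .require_cols(df, .RECALL_COLS, "recall file")
  df$individual_id <- as.character(df$individual_id)
  df$food_code <- as.character(df$food_code)
  for (col in c("day_index", "meal_code", "grams"))
    df[[col]] <- .check_numeric(df, col, "recall file")
  bad <- which(!is.na(df$grams) & df$grams < 0)
  if (length(bad))
    stop("recall file: negative grams at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(!df$day_index %in% c(1, 2))
  if (length(bad))
    stop("recall file: day_index must be 1 or 2 (data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ")", call. = FALSE)
  if (any(df$meal_code < 1, na.rm = TRUE))
    stop("recall file: meal_code must be >= 1", call. = FALSE)
  df[.RECALL_COLS]
}

#' Write recall food lines
#'
#' @param recalls Recall `data.frame` as returned by [read_recalls()].
#' @param path Output file.
#' @param sep Field separator (default comma).
#' @export
write_recalls <- function(recalls, path, sep = ",") {
  .require_cols(recalls, .RECALL_COLS, "recalls")
  utils::write.table(recalls[.RECALL_COLS], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a food composition table
#'
#' Nutrients per 100 g edible portion per food code, plus a food-group
#' label. Nutrient columns use the controlled vocabulary of
#' [nutrient_names()]; core nutrients absent from the file are filled with
#' zero (with a warning), so a minimal table need only carry the nutrients
#' it has values for.
#'
#' @inheritParams read_recalls
#' @return `data.frame` with `food_code`, `food_group` and one column per
#'   core nutrient (auxiliary nutrient columns are kept when present).
#' @export
read_food_composition <- function(path, sep = "auto") {
  df <- .read_table(path, sep)
  .require_cols(df, c("food_code", "food_group", "energy_kcal"),
                "food composition table")
  df$food_code <- as.character(df$food_code)
  df$food_group <- as.character(df$food_group)
  known <- intersect(names(df), nutrient_names("all"))
  for (col in known) {
    df[[col]] <- .check_numeric(df, col, "food composition table")
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop("food composition table: negative amount in '", col, "'",
           call. = FALSE)
    df[[col]][is.na(df[[col]])] <- 0
  }
  absent <- setdiff(nutrient_names("core"), known)
  if (length(absent)) {
    warning("food composition table lacks column(s) ",
            paste(absent, collapse = ", "), "; treated as zero",
            call. = FALSE)
    for (col in absent) df[[col]] <- 0
  }
  if (anyDuplicated(df$food_code))
    stop("food composition table: duplicated food_code", call. = FALSE)
  df[c("food_code", "food_group",
       intersect(nutrient_names("all"), names(df)))]
}

#' Read the individual covariate table
#'
#' @inheritParams read_recalls
#' @return `data.frame` with id, age, demographic covariates and sampling
#'   weight; optional `education` and `nutrition_status` columns are kept
#'   when present.
#' @export
read_individuals <- function(path, sep = "auto") {
  df <- .read_table(path, sep)
  .require_cols(df, .INDIVIDUAL_COLS, "individuals file")
  df$id <- as.character(df$id)
  df$age_years <- .check_numeric(df, "age_years", "individuals file")
  df$sampling_weight <- .check_numeric(df, "sampling_weight",
                                       "individuals file")
  if (any(df$sampling_weight <= 0, na.rm = TRUE))
    stop("individuals file: sampling_weight must be > 0", call. = FALSE)
  bad <- setdiff(unique(df$age_group), .AGE_GROUPS)
  if (length(bad))
    stop("individuals file: unknown age_group value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$id))
    stop("individuals file: duplicated id", call. = FALSE)
  df
}

#' Write the individual covariate table
#' @param individuals `data.frame` as from [read_individuals()].
#' @param path Output file.
#' @param sep Field separator (default comma).
#' @export
write_individuals <- function(individuals, path, sep = ",") {
  .require_cols(individuals, .INDIVIDUAL_COLS, "individuals")
  utils::write.table(individuals, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a food composition table
#' @param fct `data.frame` as from [read_food_composition()].
#' @param path Output file.
#' @param sep Field separator (default comma).
#' @export
write_food_composition <- function(fct, path, sep = ",") {
  .require_cols(fct, c("food_code", "food_group", "energy_kcal"),
                "food composition table")
  utils::write.table(fct, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
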