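# Turning food lines into nutrient intakes. All downstream windows
# (breakfast-only, full-day) are per-day averages over the days an
# individual actually has recall records for, so one-day and two-day
# individuals live on the same scale.

#' Compute the nutrient intake of a set of food lines
#'
#' Standard per-100-g scaling against the food composition table:
#' the intake is `sum over lines of grams / 100 * per-100-g vector`.
#' The operation is linear, so it is additive over any partition of the
#' lines and scales with portion size.
#'
#' @param lines Recall `data.frame` (any subset of rows).
#' @param fct Food composition `data.frame` from [read_food_composition()]
#'   or [default_food_composition()].
#' @return A nutrient vector (named numeric) over the nutrient columns of
#'   `fct`.
#' @examples
#' fct <- default_food_composition()
#' lines <- data.frame(individual_id = "a", day_index = 1, meal_code = 1,
#'                     food_code = "rice", grams = 150)
#' compute_intake(lines, fct)[["energy_kcal"]]
#' @export
compute_intake <- function(lines, fct) {
  nut_cols <- intersect(nutrient_names("all"), names(fct))
  if (nrow(lines) == 0L)
    return(stats::setNames(numeric(length(nut_cols)), nut_cols))
  idx <- match(lines$food_code, fct$food_code)
  if (anyNA(idx)) {
    unknown <- unique(lines$food_code[is.na(idx)])
    stop("food code(s) not in composition table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  per100 <- as.matrix(fct[idx, nut_cols, drop = FALSE])
  colSums(per100 * (lines$grams / 100))
}

# Per-individual, per-day nutrient totals for the requested meal codes.
# Returns one row per individual x day present in `recalls` (restricted to
# `meals` when given), with nutrient columns.
.daily_totals <- function(recalls, fct, meals = NULL) {
  nut_cols <- intersect(nutrient_names("all"), names(fct))
  lines <- recalls
  if (!is.null(meals)) lines <- lines[lines$meal_code %in% meals, , drop = FALSE]
  if (nrow(lines) == 0L) {
    out <- data.frame(individual_id = character(), day_index = numeric())
    for (col in nut_cols) out[[col]] <- numeric()
    return(out)
  }
  idx <- match(lines$food_code, fct$food_code)
  if (anyNA(idx)) {
    unknown <- unique(lines$food_code[is.na(idx)])
    stop("food code(s) not in composition table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  contrib <- as.matrix(fct[idx, nut_cols, drop = FALSE]) * (lines$grams / 100)
  key <- paste(lines$individual_id, lines$day_index, sep = "\r")
  sums <- rowsum(contrib, group = key, reorder = TRUE)
  parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
  out <- data.frame(individual_id = vapply(parts, `[[`, "", 1L),
                    day_index = as.numeric(vapply(parts, `[[`, "", 2L)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(sums, row.names = NULL))
  rownames(out) <- NULL
  out
}

# Number of recall days on record per individual (any meal), as a named
# integer vector. Individuals in `ids` with no lines get 1 so that absent
# intake averages to zero rather than dividing by zero.
.days_on_record <- function(recalls, ids) {
  if (nrow(recalls)) {
    tab <- tapply(recalls$day_index, recalls$individual_id,
                  function(d) length(unique(d)))
    k <- stats::setNames(rep(1L, length(ids)), ids)
    seen <- intersect(names(tab), ids)
    k[seen] <- as.integer(tab[seen])
    k
  } else {
    stats::setNames(rep(1L, length(ids)), ids)
  }
}

#' Per-individual intake over a meal window
#'
#' Sums nutrient intake over the requested meal codes and both recall days,
#' then divides by the number of days the individual has on record (any
#' meal), giving a per-day average. Individuals listed in `ids` with no
#' matching lines get an all-zero row, which is how a recorded-but-skipped
#' breakfast enters the skipper classification.
#'
#' @param recalls Recall `data.frame`.
#' @param fct Food composition `data.frame`.
#' @param ids Individual ids to report (default: everyone in `recalls`).
#' @param meals Meal codes defining the window; `NULL` (default) means all
#'   meals, `1` means breakfast.
#' @return `data.frame` with `individual_id`, `n_days` and one column per
#'   nutrient (per-day average amounts).
#' @export
window_intake <- function(recalls, fct, ids = NULL, meals = NULL) {
  if (is.null(ids)) ids <- sort(unique(recalls$individual_id))
  ids <- as.character(ids)
  nut_cols <- intersect(nutrient_names("all"), names(fct))
  k <- .days_on_record(recalls, ids)
  totals <- .daily_totals(recalls, fct, meals)
  mat <- matrix(0, nrow = length(ids), ncol = length(nut_cols),
                dimnames = list(ids, nut_cols))
  if (nrow(totals)) {
    summed <- rowsum(as.matrix(totals[nut_cols]), group = totals$individual_id)
    keep <- intersect(rownames(summed), ids)
    mat[keep, ] <- summed[keep, , drop = FALSE]
  }
  mat <- mat / k[ids]
  out <- data.frame(individual_id = ids, n_days = as.integer(k[ids]),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(mat, row.names = NULL))
  rownames(out) <- NULL
  out
}
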