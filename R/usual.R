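# Usual-intake estimation by two-day variance shrinkage. Short-term recalls
# mix true between-person differences with day-to-day noise; with a repeat
# day on part of the sample the within-person variance is estimable and the
# person means can be shrunk toward the grand mean by the best-linear-
# predictor factor s2_b / (s2_b + s2_w / k). This is an explicitly
# simplified estimator: it removes day-to-day variance (the defining
# behaviour of usual-intake correction) but performs no measurement-error
# deconvolution of the full intake distribution.

# one row per individual x recorded day with window nutrient totals,
# zero-filled for recorded days without lines in the window
.window_by_day <- function(recalls, fct, ids = NULL, meals = NULL) {
  if (is.null(ids)) ids <- sort(unique(recalls$individual_id))
  ids <- as.character(ids)
  nut_cols <- intersect(nutrient_names("all"), names(fct))
  days <- unique(recalls[recalls$individual_id %in% ids,
                         c("individual_id", "day_index")])
  days <- days[order(days$individual_id, days$day_index), , drop = FALSE]
  totals <- .daily_totals(recalls[recalls$individual_id %in% ids, ,
                                  drop = FALSE], fct, meals)
  key_grid <- paste(days$individual_id, days$day_index)
  key_tot <- paste(totals$individual_id, totals$day_index)
  mat <- matrix(0, nrow = nrow(days), ncol = length(nut_cols),
                dimnames = list(NULL, nut_cols))
  hit <- match(key_tot, key_grid)
  mat[hit[!is.na(hit)], ] <- as.matrix(totals[!is.na(hit), nut_cols])
  cbind(days, as.data.frame(mat, row.names = NULL))
}

.apply_transform <- function(x, transform) {
  switch(transform, log1p = log1p(x), none = x)
}

.invert_transform <- function(x, transform) {
  switch(transform, log1p = pmax(0, expm1(x)), none = x)
}

#' Decompose intake variance into between- and within-person components
#'
#' On the transformed scale, the within-person (day-to-day) variance is
#' estimated from individuals with two recall days as the mean of
#' `(x_day1 - x_day2)^2 / 2`; the between-person variance is the variance
#' of person means minus the within-person contribution
#' `s2_w * mean(1/k_i)`, floored at zero. The grand mean is the (optionally
#' weighted) mean of person means.
#'
#' @param per_day `data.frame` with `individual_id`, `day_index` and a
#'   `value` column (one row per recorded day).
#' @param transform `"log1p"` (default; intakes are skewed and may be zero)
#'   or `"none"`.
#' @param weights Optional named per-person weights (names = individual
#'   ids) for the grand mean.
#' @param nutrient Optional label carried through to reports.
#' @return Object of class `"variance_decomposition"`: `grand_mean`,
#'   `sigma2_b`, `sigma2_w`, `transform`, `n`, `n_two_day`.
#' @export
decompose_intake <- function(per_day, transform = c("log1p", "none"),
                             weights = NULL, nutrient = NULL) {
  transform <- match.arg(transform)
  x <- .apply_transform(per_day$value, transform)
  id <- as.character(per_day$individual_id)
  pm <- tapply(x, id, mean)
  k <- tapply(x, id, length)
  two <- names(k)[k == 2L]
  if (length(two) == 0L)
    stop("no individuals with two recall days; cannot estimate ",
         "within-person variance", call. = FALSE)
  if (length(two) < 30L)
    warning("only ", length(two), " individuals with two days; ",
            "variance components will be unstable", call. = FALSE)
  d <- tapply(x[id %in% two], id[id %in% two],
              function(v) (v[1] - v[2])^2 / 2)
  sigma2_w <- mean(d)
  w <- if (is.null(weights)) rep(1, length(pm)) else unname(weights[names(pm)])
  gm <- sum(w * pm) / sum(w)
  sigma2_b <- max(0, stats::var(as.vector(pm)) - sigma2_w * mean(1 / k))
  structure(list(nutrient = nutrient, grand_mean = gm,
                 sigma2_b = sigma2_b, sigma2_w = sigma2_w,
                 transform = transform, n = length(pm),
                 n_two_day = length(two)),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Variance decomposition", if (!is.null(x$nutrient)) paste0("(", x$nutrient, ")"),
      "\n  transform:", x$transform,
      "\n  grand mean:", format(x$grand_mean),
      "\n  between-person variance:", format(x$sigma2_b),
      "\n  within-person variance:", format(x$sigma2_w),
      "\n  n:", x$n, "(", x$n_two_day, "with 2 days )\n")
  invisible(x)
}

#' Shrink observed person means toward the grand mean
#'
#' On the decomposition's transformed scale,
#' `usual = gm + (pm - gm) * s2_b / (s2_b + s2_w / k)`, back-transformed to
#' the original scale. The shrinkage factor lies in `[0, 1]`: it is 1 when
#' there is no day-to-day noise (usual = observed) and 0 when there is no
#' true between-person variation (usual = grand mean for everyone).
#'
#' @param person_mean Observed per-day mean intake per person, on the
#'   original scale (vectorised).
#' @param k_days Number of recall days per person (1 or 2, vectorised).
#' @param decomposition A [decompose_intake()] result.
#' @return Usual-intake estimates on the original scale.
#' @export
shrink_usual <- function(person_mean, k_days, decomposition) {
  stopifnot(inherits(decomposition, "variance_decomposition"))
  if (!all(k_days %in% c(1, 2)))
    stop("k_days must be 1 or 2", call. = FALSE)
  s2b <- decomposition$sigma2_b
  s2w <- decomposition$sigma2_w
  f <- if (s2b == 0 && s2w == 0) rep(1, length(person_mean))
       else s2b / (s2b + s2w / k_days)
  pm_t <- .apply_transform(person_mean, decomposition$transform)
  usual_t <- decomposition$grand_mean + (pm_t - decomposition$grand_mean) * f
  .invert_transform(usual_t, decomposition$transform)
}

#' Usual nutrient intakes over a meal window
#'
#' For each requested nutrient: builds per-day window totals, decomposes
#' their variance with [decompose_intake()] and shrinks each individual's
#' observed mean with [shrink_usual()].
#'
#' @param recalls Recall `data.frame`.
#' @param fct Food composition `data.frame`.
#' @param ids Individuals to include (default: everyone in `recalls`).
#' @param nutrients Nutrient names (default: the core set).
#' @param meals Meal codes of the window (default 1 = breakfast; `NULL` for
#'   all meals).
#' @param transform See [decompose_intake()].
#' @return List with `usual` (`data.frame`: `individual_id`, `n_days`, one
#'   column per nutrient holding the usual-intake estimate) and
#'   `decompositions` (one [decompose_intake()] result per nutrient).
#' @export
usual_intakes <- function(recalls, fct, ids = NULL,
                          nutrients = nutrient_names("core"), meals = 1,
                          transform = "log1p") {
  by_day <- .window_by_day(recalls, fct, ids = ids, meals = meals)
  ids_seen <- sort(unique(by_day$individual_id))
  k <- as.vector(table(by_day$individual_id)[ids_seen])
  out <- data.frame(individual_id = ids_seen, n_days = k,
                    stringsAsFactors = FALSE)
  decomps <- list()
  for (nut in nutrients) {
    per_day <- data.frame(individual_id = by_day$individual_id,
                          day_index = by_day$day_index,
                          value = by_day[[nut]])
    dec <- decompose_intake(per_day, transform = transform, nutrient = nut)
    # person means on the decomposition's transformed scale, expressed on
    # the original scale so shrink_usual's transform recovers them exactly
    pm_t <- tapply(.apply_transform(per_day$value, dec$transform),
                   per_day$individual_id, mean)[ids_seen]
    pm <- .invert_transform(as.vector(pm_t), dec$transform)
    out[[nut]] <- shrink_usual(pm, k, dec)
    decomps[[nut]] <- dec
  }
  list(usual = out, decompositions = decomps)
}
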