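# Implausible-intake quality control. Within a sex x age-group stratum, a
# nutrient intake above 1.5 times the 99th percentile of the observed
# distribution is considered implausible and replaced by a random draw from
# Uniform(P95, 1.5 * P99), with both percentiles taken from the original
# (pre-replacement) values in a single pass. Replacement, not exclusion:
# the record stays in the sample with a plausible value.

#' Outlier substitution rule
#'
#' @param detection_multiplier Threshold multiplier on the upper reference
#'   percentile (default 1.5; must exceed 1).
#' @param upper_reference_percentile Percentile defining the detection
#'   threshold (default 99).
#' @param substitution_lower_percentile Lower bound percentile of the
#'   substitution interval (default 95).
#' @return List of class `"outlier_rule"`.
#' @export
outlier_rule <- function(detection_multiplier = 1.5,
                         upper_reference_percentile = 99,
                         substitution_lower_percentile = 95) {
  if (detection_multiplier <= 1)
    stop("detection_multiplier must be > 1", call. = FALSE)
  for (p in c(upper_reference_percentile, substitution_lower_percentile))
    if (p <= 0 || p >= 100)
      stop("percentiles must lie in (0, 100)", call. = FALSE)
  structure(list(detection_multiplier = detection_multiplier,
                 upper_reference_percentile = upper_reference_percentile,
                 substitution_lower_percentile = substitution_lower_percentile),
            class = "outlier_rule")
}

#' Substitute implausible intakes within one stratum
#'
#' Computes the detection threshold `U = multiplier * P99(values)` and the
#' substitution floor `P95(values)` from the original values (percentiles
#' by linear interpolation between order statistics, the default `quantile`
#' type 7), then replaces every value above `U` by a draw from
#' `Uniform(P95, U)`. Non-outlying values pass through unchanged.
#'
#' @param values Numeric intake vector for one nutrient within one
#'   sex x age-group stratum.
#' @param rule An [outlier_rule()].
#' @param ids Optional identifiers for the audit log (default: positions).
#' @return List with `values` (cleaned), `audit` (`data.frame`: id, old,
#'   new, threshold, lower bound; one row per replacement), `threshold`
#'   and `lower`.
#' @examples
#' set.seed(1)
#' qc <- qc_nutrient(c(1:100, 1000), outlier_rule())
#' qc$audit
#' @export
qc_nutrient <- function(values, rule = outlier_rule(), ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(values))
  p99 <- stats::quantile(values, rule$upper_reference_percentile / 100,
                         names = FALSE)
  p95 <- stats::quantile(values, rule$substitution_lower_percentile / 100,
                         names = FALSE)
  threshold <- rule$detection_multiplier * p99
  if (p95 > threshold)
    stop("substitution interval is empty: P",
         rule$substitution_lower_percentile, " = ", format(p95),
         " exceeds ", rule$detection_multiplier, " x P",
         rule$upper_reference_percentile, " = ", format(threshold),
         call. = FALSE)
  out <- values
  hit <- which(values > threshold)
  new <- stats::runif(length(hit), p95, threshold)
  out[hit] <- new
  audit <- data.frame(id = ids[hit], old = values[hit], new = new,
                      threshold = rep(threshold, length(hit)),
                      lower = rep(p95, length(hit)),
                      stringsAsFactors = FALSE)
  list(values = out, audit = audit, threshold = threshold, lower = p95)
}

#' Substitute implausible intakes across sex x age-group strata
#'
#' Applies [qc_nutrient()] to each requested nutrient column of an intake
#' table, separately within every sex x age-group stratum. Strata with
#' fewer than `min_n` individuals are skipped with a warning (percentiles
#' are unstable in tiny strata). Energy is never cleaned by this rule.
#'
#' @param intake `data.frame` with `individual_id` and nutrient columns
#'   (e.g. from [window_intake()]).
#' @param individuals Individual covariate `data.frame` (for `sex` and
#'   `age_group`).
#' @param nutrients Columns to clean (default: all scored nutrients except
#'   energy present in `intake`).
#' @param rule An [outlier_rule()].
#' @param min_n Minimum stratum size (default 20).
#' @return List with `intake` (cleaned copy) and `audit` (`data.frame`
#'   with nutrient, sex, age_group and the per-replacement columns of
#'   [qc_nutrient()]).
#' @export
qc_intakes <- function(intake, individuals,
                       nutrients = NULL, rule = outlier_rule(),
                       min_n = 20) {
  if (is.null(nutrients))
    nutrients <- setdiff(intersect(nutrient_names("all"), names(intake)),
                         "energy_kcal")
  sex <- individuals$sex[match(intake$individual_id, individuals$id)]
  ag <- individuals$age_group[match(intake$individual_id, individuals$id)]
  stratum <- paste(sex, ag, sep = ":")
  audits <- list()
  for (s in unique(stratum)) {
    rows <- which(stratum == s)
    if (length(rows) < min_n) {
      warning("stratum ", s, " has ", length(rows),
              " individuals (< ", min_n, "); skipped", call. = FALSE)
      next
    }
    for (nut in nutrients) {
      qc <- qc_nutrient(intake[[nut]][rows], rule,
                        ids = intake$individual_id[rows])
      intake[[nut]][rows] <- qc$values
      if (nrow(qc$audit)) {
        qc$audit$nutrient <- nut
        qc$audit$sex <- strsplit(s, ":", fixed = TRUE)[[1]][1]
        qc$audit$age_group <- strsplit(s, ":", fixed = TRUE)[[1]][2]
        audits[[length(audits) + 1L]] <- qc$audit
      }
    }
  }
  audit <- if (length(audits)) do.call(rbind, audits)
           else data.frame(id = character(), old = numeric(),
                           new = numeric(), threshold = numeric(),
                           lower = numeric(), nutrient = character(),
                           sex = character(), age_group = character(),
                           stringsAsFactors = FALSE)
  list(intake = intake, audit = audit)
}
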