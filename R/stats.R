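# Survey-weighted descriptive statistics. Weights are expansion factors
# normalised to mean one before use; no design-based (cluster/stratum)
# variance correction is applied.

#' Weighted mean with standard error
#'
#' Mean `sum(w x) / sum(w)` with the normalised-weight standard error
#' `sqrt(sum(w~^2 (x - mean)^2)) / sum(w~)`, where `w~` are the weights
#' rescaled to mean one. With equal weights this reduces to the ordinary
#' mean and its (n-denominator) standard error.
#'
#' @param values Numeric vector.
#' @param weights Positive weights, same length (default: equal).
#' @return List with `value`, `se`, `n`, `sum_weights`.
#' @examples
#' weighted_mean_se(c(1, 2, 3), c(1, 1, 4))
#' @export
weighted_mean_se <- function(values, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(values) != length(weights))
    stop("values and weights must have the same length", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be > 0", call. = FALSE)
  keep <- !is.na(values)
  values <- values[keep]; weights <- weights[keep]
  n <- length(values)
  if (n == 0L) return(list(value = NA_real_, se = NA_real_, n = 0L,
                           sum_weights = 0))
  wt <- weights / mean(weights)
  m <- sum(wt * values) / sum(wt)
  se <- if (n == 1L) 0 else sqrt(sum(wt^2 * (values - m)^2)) / sum(wt)
  list(value = m, se = se, n = n, sum_weights = sum(weights))
}

#' Weighted linear trend test across tertiles
#'
#' Regresses the values on the numeric tertile index (T1 = 1, T2 = 2,
#' T3 = 3) by weighted least squares and reads the direction off the slope:
#' `"increasing"` or `"decreasing"` when the two-sided slope t-test is
#' significant at `alpha`, `"none"` otherwise. Because sampling weights are
#' expansion factors, not precision weights, the slope's standard error is
#' the heteroskedasticity-robust (HC1 sandwich) one; classical WLS
#' inference would treat high-weight observations as low-variance and
#' over-reject under the null.
#'
#' @param values Numeric vector.
#' @param tertiles Character or factor vector of `"T1"`/`"T2"`/`"T3"`
#'   labels.
#' @param weights Positive weights (default: equal).
#' @param alpha Significance level (default 0.05).
#' @return List with `slope`, `p_value`, `direction`.
#' @export
trend_test <- function(values, tertiles, weights = NULL, alpha = 0.05) {
  idx <- match(as.character(tertiles), c("T1", "T2", "T3"))
  if (anyNA(idx)) stop("tertile labels must be T1/T2/T3", call. = FALSE)
  if (length(unique(idx)) < 3L)
    stop("all three tertile levels must be present", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(values))
  wt <- weights / mean(weights)
  if (stats::var(values) == 0)
    return(list(slope = 0, p_value = 1, direction = "none"))
  fit <- stats::lm(values ~ idx, weights = wt)
  slope <- stats::coef(fit)[["idx"]]
  se <- sqrt(sandwich::vcovHC(fit, type = "HC1")["idx", "idx"])
  p <- 2 * stats::pt(-abs(slope / se), df = length(values) - 2)
  direction <- if (p < alpha && slope > 0) "increasing"
               else if (p < alpha && slope < 0) "decreasing"
               else "none"
  list(slope = unname(slope), p_value = unname(p), direction = direction)
}
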