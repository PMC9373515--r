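# Controlled nutrient vocabulary. Names carry their unit so that amounts can
# never silently change unit between the food-composition table, the scoring
# reference amounts and the reports (the reference amounts mix g, mg, ug and
# retinol equivalents).

.QUALIFYING <- c("protein_g", "fiber_g", "vitamin_a_re_ug", "vitamin_c_mg",
                 "vitamin_d_ug", "calcium_mg", "iron_mg", "potassium_mg",
                 "magnesium_mg")

.LIMITING <- c("total_sugar_g", "saturated_fat_g", "sodium_mg")

.AUXILIARY <- c("total_fat_g", "mufa_g", "pufa_g", "carbohydrate_g",
                "thiamin_mg", "riboflavin_mg", "niacin_mg", "phosphorus_mg",
                "cholesterol_mg")

#' Nutrient name vocabulary
#'
#' The fixed set of nutrient column names used throughout the package.
#' Snake-case names embed the unit (g, mg, ug, RE) so that food-composition
#' entries, reference amounts and report columns cannot drift apart.
#'
#' @param which One of `"core"` (energy plus the 12 scored nutrients, the
#'   default), `"qualifying"` (the 9 nutrients credited in the NR sum),
#'   `"limiting"` (the 3 nutrients penalised in the LIM sum), `"scored"`
#'   (qualifying plus limiting), `"auxiliary"` (optional extra nutrients
#'   carried through summaries but never scored), or `"all"`.
#' @return Character vector of nutrient names.
#' @examples
#' nutrient_names("qualifying")
#' @export
nutrient_names <- function(which = c("core", "qualifying", "limiting",
                                     "scored", "auxiliary", "all")) {
  which <- match.arg(which)
  switch(which,
         qualifying = .QUALIFYING,
         limiting   = .LIMITING,
         scored     = c(.QUALIFYING, .LIMITING),
         auxiliary  = .AUXILIARY,
         core       = c("energy_kcal", .QUALIFYING, .LIMITING),
         all        = c("energy_kcal", .QUALIFYING, .LIMITING, .AUXILIARY))
}

#' Construct a nutrient vector
#'
#' A nutrient vector is a named numeric vector over the controlled
#' vocabulary: energy plus the 12 scored nutrients, with optional auxiliary
#' nutrients. Unnamed nutrients default to zero. Vectors support ordinary
#' elementwise arithmetic, so intakes add over food lines and scale with
#' portion size.
#'
#' @param ... Named nutrient amounts, e.g. `energy_kcal = 130, protein_g = 2.7`.
#'   All names must come from `nutrient_names("all")`; amounts must be
#'   non-negative and finite.
#' @param auxiliary Include the auxiliary nutrient slots (default `FALSE`).
#' @return Named numeric vector.
#' @examples
#' nutrient_vector(energy_kcal = 130, protein_g = 2.7)
#' @export
nutrient_vector <- function(..., auxiliary = FALSE) {
  slots <- nutrient_names(if (auxiliary) "all" else "core")
  out <- stats::setNames(numeric(length(slots)), slots)
  amounts <- c(...)
  if (length(amounts)) {
    if (is.null(names(amounts)) || any(!nzchar(names(amounts))))
      stop("all nutrient amounts must be named", call. = FALSE)
    bad <- setdiff(names(amounts), nutrient_names("all"))
    if (length(bad))
      stop("unknown nutrient name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    extra <- setdiff(names(amounts), slots)   # auxiliary given explicitly
    if (length(extra)) {
      out <- c(out, stats::setNames(numeric(length(extra)), extra))
    }
    if (any(!is.finite(amounts)) || any(amounts < 0))
      stop("nutrient amounts must be finite and >= 0", call. = FALSE)
    out[names(amounts)] <- amounts
  }
  out
}

#' Reference amounts for NRF9.3 scoring
#'
#' Bundles the daily values (DV) of the nine qualifying nutrients, the
#' maximum recommended values (MRV) of the three limiting nutrients, and the
#' daily recommendation amounts used for percentage-contribution reports.
#' Defaults are the Philippine Dietary Reference Intake based amounts:
#' protein 50 g, fiber 25 g, vitamin A 1500 RE, vitamin C 60 mg, vitamin D
#' 10 ug, calcium 1000 mg, iron 18 mg, potassium 3500 mg, magnesium 400 mg;
#' limiting: total sugar 50 g (standing in for added sugar), saturated fat
#' 20 g, sodium 2400 mg. The recommendation map defaults to the DV/MRV
#' amounts plus a 2000 kcal energy reference, and can be overridden per
#' age/sex stratum via [read_reference_yaml()].
#'
#' @param dv Named numeric vector of daily values; must contain exactly the
#'   nine qualifying nutrients.
#' @param mrv Named numeric vector of maximum recommended values; must
#'   contain exactly the three limiting nutrients.
#' @param recommendation Named numeric vector of daily recommendation
#'   amounts used by the contribution reports; defaults to `c(dv, mrv)` plus
#'   `energy_kcal = 2000`.
#' @return An object of class `"reference_table"` (a list with elements
#'   `dv`, `mrv`, `recommendation`).
#' @examples
#' ref <- reference_table()
#' ref$dv[["iron_mg"]]
#' @export
reference_table <- function(dv = NULL, mrv = NULL, recommendation = NULL) {
  default_dv <- c(protein_g = 50, fiber_g = 25, vitamin_a_re_ug = 1500,
                  vitamin_c_mg = 60, vitamin_d_ug = 10, calcium_mg = 1000,
                  iron_mg = 18, potassium_mg = 3500, magnesium_mg = 400)
  default_mrv <- c(total_sugar_g = 50, saturated_fat_g = 20, sodium_mg = 2400)
  if (is.null(dv)) dv <- default_dv
  if (is.null(mrv)) mrv <- default_mrv
  if (!setequal(names(dv), .QUALIFYING))
    stop("dv must name exactly the nine qualifying nutrients", call. = FALSE)
  if (!setequal(names(mrv), .LIMITING))
    stop("mrv must name exactly the three limiting nutrients", call. = FALSE)
  dv <- dv[.QUALIFYING]
  mrv <- mrv[.LIMITING]
  if (any(dv <= 0) || any(mrv <= 0))
    stop("reference amounts must be positive", call. = FALSE)
  if (is.null(recommendation))
    recommendation <- c(energy_kcal = 2000, dv, mrv)
  if (any(recommendation <= 0))
    stop("recommendation amounts must be positive", call. = FALSE)
  structure(list(dv = dv, mrv = mrv, recommendation = recommendation),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat("Reference table for NRF9.3 scoring\n")
  cat("  DV (qualifying):\n")
  print(x$dv)
  cat("  MRV (limiting):\n")
  print(x$mrv)
  invisible(x)
}

#' Read reference amounts from a YAML file
#'
#' The file carries `dv`, `mrv` and optionally `recommendation` maps keyed by
#' nutrient name, either at top level or nested under `<age_group>/<sex>`
#' strata. When `age_group`/`sex` are supplied and a matching stratum exists
#' its values override the top-level ones, which lets stratum-specific
#' recommendation tables be supplied without changing the scoring code.
#'
#' @param path Path to a YAML file.
#' @param age_group,sex Optional stratum selectors.
#' @return A [reference_table()].
#' @export
read_reference_yaml <- function(path, age_group = NULL, sex = NULL) {
  raw <- yaml::read_yaml(path)
  pick <- raw
  if (!is.null(age_group) && !is.null(raw[[age_group]])) {
    stratum <- raw[[age_group]]
    if (!is.null(sex) && !is.null(stratum[[sex]])) stratum <- stratum[[sex]]
    for (slot in c("dv", "mrv", "recommendation"))
      if (!is.null(stratum[[slot]]))
        pick[[slot]] <- utils::modifyList(as.list(pick[[slot]] %||% list()),
                                          as.list(stratum[[slot]]))
  }
  as_named <- function(x) if (is.null(x)) NULL else unlist(x)
  reference_table(dv = as_named(pick$dv), mrv = as_named(pick$mrv),
                  recommendation = as_named(pick$recommendation))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
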