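#' Folic acid added by fortifying corn masa flour
#'
#' Computes the folic acid (ug) a food occurrence would gain if the corn masa
#' flour it contains were fortified at `level_ug_per_100g`.  The food's
#' non-wholegrain gram content serves as the proxy for its corn masa flour
#' content, so the added amount is `nonwholegrain_g * level / 100`.  For
#' example, 32 g of non-wholegrain at 140 ug/100 g yields 44.8 ug.
#'
#' @param nonwholegrain_g grams of non-wholegrain content (>= 0).
#' @param level_ug_per_100g fortification level in ug folic acid per 100 g of
#'   corn masa flour (>= 0); 140 is the level modeled for corn masa flour.
#' @return ug of added folic acid (vectorized).
#' @examples
#' added_folic_acid(32, 140)  # 44.8
#' @export
added_folic_acid <- function(nonwholegrain_g, level_ug_per_100g) {
  if (any(nonwholegrain_g < 0) || any(level_ug_per_100g < 0))
    stop("nonwholegrain_g and level_ug_per_100g must be >= 0",
         call. = FALSE)
  nonwholegrain_g * level_ug_per_100g / 100
}

#' Define a fortification scenario
#'
#' A scenario pairs a fortification level with the set of food codes whose
#' products could contain corn masa flour.  The packaged default list is a
#' synthetic stand-in for the expert-validated list of roughly 103 survey
#' food codes (tortillas, tamales, and related products; items whose
#' conventional form uses white flour are absent by construction).
#'
#' @param level_ug_per_100g ug folic acid per 100 g corn masa flour
#'   (default 140).
#' @param food_codes integer/character vector of matched food codes; defaults
#'   to the packaged list.  May be empty, giving the null scenario.
#' @return object of class `fortification_scenario`.
#' @export
fortification_scenario <- function(level_ug_per_100g = 140,
                                   food_codes = corn_masa_food_codes()$food_code) {
  if (!is.numeric(level_ug_per_100g) || length(level_ug_per_100g) != 1 ||
      level_ug_per_100g < 0)
    stop("level_ug_per_100g must be a single value >= 0", call. = FALSE)
  structure(list(level_ug_per_100g = level_ug_per_100g,
                 food_codes = food_codes),
            class = "fortification_scenario")
}

#' @export
print.fortification_scenario <- function(x, ...) {
  cat(sprintf("Fortification scenario: %g ug folic acid / 100 g corn masa flour; %d matched food codes\n",
              x$level_ug_per_100g, length(x$food_codes)))
  invisible(x)
}

#' Packaged corn-masa food-code list
#'
#' Reads the synthetic fixture shipped with the package: one row per survey
#' food code identified as potentially containing corn masa flour.
#'
#' @return data frame with columns `food_code` and `description`.
#' @export
corn_masa_food_codes <- function() {
  path <- system.file("extdata", "synthetic_corn_masa_food_codes.csv",
                      package = "masafort")
  if (path == "") {
    # during development (package not installed)
    path <- file.path("inst", "extdata",
                      "synthetic_corn_masa_food_codes.csv")
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read 24-hour recall food rows from CSV
#'
#' Expects the documented headers: `person_id, day_index, food_code,
#' amount_g, folic_acid_ug, nonwholegrain_g, day_of_week, interview_mode`.
#'
#' @param path CSV file path.
#' @return validated recall data frame.
#' @export
read_recalls <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_recalls(x)
  x
}

validate_recalls <- function(rows) {
  need <- c("person_id", "day_index", "food_code", "amount_g",
            "folic_acid_ug", "nonwholegrain_g", "day_of_week",
            "interview_mode")
  missing <- setdiff(need, names(rows))
  if (length(missing))
    stop("recall table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(rows$day_index %in% c(1L, 2L)))
    stop("recall table has day_index outside {1, 2}", call. = FALSE)
  if (any(rows$amount_g < 0) || any(rows$folic_acid_ug < 0))
    stop("recall amounts and folic acid must be >= 0", call. = FALSE)
  if (any(rows$nonwholegrain_g < 0) ||
      any(rows$nonwholegrain_g > rows$amount_g + 1e-9))
    stop("nonwholegrain_g must lie in [0, amount_g]", call. = FALSE)
  invisible(rows)
}

#' Apply a fortification scenario to recall rows
#'
#' Collapses per-food recall rows to person-day totals of reported food folic
#' acid and scenario-added folic acid.  A row contributes added folic acid
#' only when its food code is in the scenario's corn-masa set; the amount is
#' [added_folic_acid()] of its non-wholegrain grams.  Days touched by no
#' matched food carry `added_fa_ug = 0`, so an empty food-code set or a level
#' of 0 reproduces current intake exactly.
#'
#' @param recalls recall rows (see [read_recalls()] for columns).
#' @param scenario a [fortification_scenario()].
#' @return data frame with one row per person-day: `person_id, day_index,
#'   food_fa_ug, added_fa_ug, day_of_week, interview_mode`.
#' @export
apply_scenario <- function(recalls, scenario) {
  validate_recalls(recalls)
  stopifnot(inherits(scenario, "fortification_scenario"))
  matched <- recalls$food_code %in% scenario$food_codes
  add <- ifelse(matched,
                added_folic_acid(recalls$nonwholegrain_g,
                                 scenario$level_ug_per_100g),
                0)
  key <- interaction(recalls$person_id, recalls$day_index, drop = TRUE)
  first <- !duplicated(key)
  out <- data.frame(
    person_id = recalls$person_id[first],
    day_index = recalls$day_index[first],
    food_fa_ug = as.numeric(
      tapply(recalls$folic_acid_ug, key, sum)[as.character(key[first])]),
    added_fa_ug = as.numeric(
      tapply(add, key, sum)[as.character(key[first])]),
    day_of_week = recalls$day_of_week[first],
    interview_mode = recalls$interview_mode[first],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$person_id, out$day_index), ]
  rownames(out) <- NULL
  out
}

#' Flag corn masa flour consumers
#'
#' A person is a corn masa flour consumer when they report at least one food
#' from the scenario's corn-masa food-code set on either recall day.
#'
#' @param recalls recall rows.
#' @param scenario a [fortification_scenario()].
#' @return named logical vector indexed by person id (every person present in
#'   `recalls` appears).
#' @export
flag_corn_masa_consumers <- function(recalls, scenario) {
  validate_recalls(recalls)
  matched <- recalls$food_code %in% scenario$food_codes
  ids <- sort(unique(recalls$person_id))
  hit <- unique(recalls$person_id[matched])
  stats::setNames(ids %in% hit, ids)
}
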