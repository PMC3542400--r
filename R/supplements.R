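#' Average daily supplemental folic acid over the past 30 days
#'
#' Each reported product contributes `fa_per_serving_ug * servings_per_day *
#' days_taken_past30 / 30`; the per-product averages are totaled within a
#' person.  A person with no reports contributes 0.
#'
#' @param reports data frame with columns `person_id, fa_per_serving_ug,
#'   days_taken_past30, servings_per_day` (see [read_supplements()]).
#' @param person_ids optional ids to return values for (persons absent from
#'   `reports` get 0); defaults to the ids present in `reports`.
#' @return named numeric vector of ug/day per person.
#' @export
average_daily_supplement_fa <- function(reports, person_ids = NULL) {
  validate_supplements(reports)
  per_row <- reports$fa_per_serving_ug * reports$servings_per_day *
    reports$days_taken_past30 / 30
  agg <- tapply(per_row, reports$person_id, sum)
  if (is.null(person_ids)) person_ids <- sort(unique(reports$person_id))
  out <- agg[as.character(person_ids)]
  out[is.na(out)] <- 0
  stats::setNames(as.numeric(out), person_ids)
}

#' Flag folic-acid supplement users
#'
#' A user is a person reporting at least one folic-acid-containing product
#' (per-serving content > 0) taken at least once in the past 30 days.
#'
#' @inheritParams average_daily_supplement_fa
#' @return named logical vector per person id.
#' @export
flag_supplement_user <- function(reports, person_ids = NULL) {
  validate_supplements(reports)
  qual <- reports$days_taken_past30 >= 1 & reports$fa_per_serving_ug > 0
  users <- unique(reports$person_id[qual])
  if (is.null(person_ids)) person_ids <- sort(unique(reports$person_id))
  stats::setNames(person_ids %in% users, person_ids)
}

#' Add constant daily supplement intake to person-day totals
#'
#' Supplemental folic acid is treated as a per-person constant (the 30-day
#' average), added to each of the person's recall days.  Because the addition
#' is constant and non-negative it commutes with the fortification scenario.
#'
#' @param person_days person-day intakes from [apply_scenario()].
#' @param supplement_fa named vector from [average_daily_supplement_fa()].
#' @return `person_days` with a `supplement_fa_ug` column and a
#'   `total_fa_ug = food_fa_ug + added_fa_ug + supplement_fa_ug` column.
#' @export
add_supplement_to_days <- function(person_days, supplement_fa) {
  if (any(supplement_fa < 0))
    stop("supplement intake must be >= 0", call. = FALSE)
  extra <- setdiff(names(supplement_fa),
                   as.character(person_days$person_id))
  extra <- extra[supplement_fa[extra] > 0]
  if (length(extra))
    warning(length(extra),
            " person(s) with supplement reports have no recall days",
            call. = FALSE)
  s <- supplement_fa[as.character(person_days$person_id)]
  s[is.na(s)] <- 0
  person_days$supplement_fa_ug <- as.numeric(s)
  person_days$total_fa_ug <- person_days$food_fa_ug +
    person_days$added_fa_ug + person_days$supplement_fa_ug
  person_days
}

#' Read supplement reports from CSV
#'
#' Expects headers `person_id, fa_per_serving_ug, days_taken_past30,
#' servings_per_day`.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_supplements <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_supplements(x)
  x
}

validate_supplements <- function(reports) {
  need <- c("person_id", "fa_per_serving_ug", "days_taken_past30",
            "servings_per_day")
  missing <- setdiff(need, names(reports))
  if (length(missing))
    stop("supplement table lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(reports$days_taken_past30 < 0) ||
      any(reports$days_taken_past30 > 30))
    stop("days_taken_past30 must lie in [0, 30]", call. = FALSE)
  if (any(reports$fa_per_serving_ug < 0))
    stop("fa_per_serving_ug must be >= 0", call. = FALSE)
  if (any(reports$servings_per_day <= 0))
    stop("servings_per_day must be > 0", call. = FALSE)
  invisible(reports)
}
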