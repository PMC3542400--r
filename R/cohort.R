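#' Age-specific tolerable upper intake level for folic acid
#'
#' Returns the UL (ug/day of synthetic folic acid) for a given age in whole
#' years: 300 for ages 1-3, 400 for 4-8, 600 for 9-13, 800 for 14-18 and
#' 1000 for adults aged 19 and older.  The UL is not defined below age 1.
#'
#' @param age_years age in whole years (>= 1).
#' @param schedule UL schedule table (`age_min`, `cutpoint_ug` columns, rows
#'   ordered by increasing `age_min`); defaults to [ul_schedule()]. Passing
#'   an amended copy overrides individual cut-points.
#' @return the cut-point in ug/day (vectorized).
#' @export
ul_for_age <- function(age_years, schedule = ul_schedule()) {
  if (any(age_years < schedule$age_min[1]))
    stop("UL is not defined for age < ", schedule$age_min[1], " year",
         call. = FALSE)
  schedule$cutpoint_ug[findInterval(age_years, schedule$age_min)]
}

#' The UL schedule as a table
#'
#' @return data frame of age brackets and their cut-points.
#' @export
ul_schedule <- function() {
  data.frame(
    age_group = c("1-3", "4-8", "9-13", "14-18", ">=19"),
    age_min = c(1, 4, 9, 14, 19), age_max = c(3, 8, 13, 18, Inf),
    cutpoint_ug = c(300, 400, 600, 800, 1000),
    stringsAsFactors = FALSE
  )
}

#' Apply the analytic exclusion cascade
#'
#' Removes persons in this order, attributing each person to the first rule
#' that applies: (1) pregnant; (2) recall quality below the minimum standard
#' (day 1 for any cycle; day 2 additionally for two-day cycles); (3) missing
#' supplement-use information; (4) implausibly high supplemental folic acid
#' (>= 93,000 ug/day, i.e. >= 93 mg).  Returns the analytic cohort together
#' with an exclusion ledger whose counts reproduce the cascade arithmetic.
#'
#' @param demographics person table with `pregnant`,
#'   `recall_quality_ok_day1`, `recall_quality_ok_day2` (NA allowed for
#'   one-day cycles), `supplement_info_present` and `cycle` columns.
#' @param supplement_fa named vector of daily supplemental ug per person (0
#'   for non-users), as from [average_daily_supplement_fa()].
#' @param implausible_ug threshold for implausible supplemental intake
#'   (default 93,000 ug/day).
#' @return list with `cohort` (the retained rows) and `ledger` (class
#'   `exclusion_ledger`).
#' @export
apply_exclusions <- function(demographics, supplement_fa,
                             implausible_ug = 93000) {
  n0 <- nrow(demographics)
  s <- supplement_fa[as.character(demographics$person_id)]
  s[is.na(s)] <- 0

  two_day <- demographics$cycle != "2001-2002"
  bad_quality <- !demographics$recall_quality_ok_day1 |
    (two_day & !ifelse(is.na(demographics$recall_quality_ok_day2),
                       TRUE, demographics$recall_quality_ok_day2))
  rules <- list(
    pregnant = demographics$pregnant,
    `recall quality below minimum standard` = bad_quality,
    `missing supplement information` = !demographics$supplement_info_present,
    `implausibly high supplemental folic acid (>= 93 mg/day)` =
      s >= implausible_ug
  )
  remaining <- rep(TRUE, n0)
  steps <- data.frame(rule = names(rules),
                      n_removed = NA_integer_,
                      stringsAsFactors = FALSE)
  for (i in seq_along(rules)) {
    hit <- remaining & rules[[i]]
    steps$n_removed[i] <- sum(hit)
    remaining <- remaining & !hit
  }
  ledger <- structure(
    list(initial_n = n0, steps = steps, final_n = sum(remaining)),
    class = "exclusion_ledger"
  )
  list(cohort = demographics[remaining, , drop = FALSE], ledger = ledger)
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat(sprintf("Exclusion cascade: initial n = %d\n", x$initial_n))
  for (i in seq_len(nrow(x$steps)))
    cat(sprintf("  - %-55s removed %6d\n",
                x$steps$rule[i], x$steps$n_removed[i]))
  cat(sprintf("Final analytic n = %d (%.0f%% of the eligible sample)\n",
              x$final_n, 100 * x$final_n / x$initial_n))
  invisible(x)
}

#' Serialize an exclusion ledger to JSON
#'
#' @param ledger an `exclusion_ledger`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
ledger_json <- function(ledger, path = NULL) {
  obj <- list(initial_n = ledger$initial_n, steps = ledger$steps,
              final_n = ledger$final_n,
              retained_fraction = ledger$final_n / ledger$initial_n)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' Assign stratification labels
#'
#' Adds the stratification axes used in the tables: sex, race/ethnicity
#' (analyses stratified by race/ethnicity are restricted to non-Hispanic
#' white, non-Hispanic black and Mexican American persons, while totals keep
#' everyone), age group (`<1, 1-3, 4-8, 9-13, 14-18, 19-30, 31-50, 51-70,
#' >70`; closed on the left), supplement use, and corn-masa consumption.
#'
#' @param demographics person table with `sex`, `race_ethnicity` and
#'   `age_years`.
#' @param supplement_user named logical vector per person id (optional).
#' @param corn_masa_consumer named logical vector per person id (optional).
#' @return `demographics` with `age_group`, `race_stratum` (NA outside the
#'   three reported groups), and, when supplied, `supplement_user` and
#'   `corn_masa_consumer` columns.
#' @export
assign_strata <- function(demographics, supplement_user = NULL,
                          corn_masa_consumer = NULL) {
  age <- demographics$age_years
  grp <- cut(age, breaks = c(-Inf, 0, 3, 8, 13, 18, 30, 50, 70, Inf),
             labels = c("<1", "1-3", "4-8", "9-13", "14-18", "19-30",
                        "31-50", "51-70", ">70"))
  demographics$age_group <- as.character(grp)
  reported <- c("non-Hispanic white", "non-Hispanic black",
                "Mexican American")
  demographics$race_stratum <- ifelse(
    demographics$race_ethnicity %in% reported,
    demographics$race_ethnicity, NA_character_)
  ids <- as.character(demographics$person_id)
  if (!is.null(supplement_user)) {
    v <- supplement_user[ids]
    v[is.na(v)] <- FALSE
    demographics$supplement_user <- as.logical(v)
  }
  if (!is.null(corn_masa_consumer)) {
    v <- corn_masa_consumer[ids]
    v[is.na(v)] <- FALSE
    demographics$corn_masa_consumer <- as.logical(v)
  }
  demographics
}
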