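# Tiny hand-built fixtures shared across tests.

tiny_recalls <- function() {
  data.frame(
    person_id = c(1L, 1L, 1L, 2L, 2L, 3L),
    day_index = c(1L, 1L, 2L, 1L, 2L, 1L),
    food_code = c(10000000L, 56200001L, 10000000L, 10000000L,
                  56200001L, 10000000L),
    amount_g = c(250, 60, 220, 300, 40, 180),
    folic_acid_ug = c(120, 5, 110, 200, 0, 90),
    nonwholegrain_g = c(0, 32, 0, 0, 20, 0),
    day_of_week = c(2L, 2L, 7L, 3L, 1L, 5L),
    interview_mode = c("in-person", "in-person", "telephone",
                       "in-person", "telephone", "in-person"),
    stringsAsFactors = FALSE
  )
}

tiny_scenario <- function(level = 140) {
  fortification_scenario(level, food_codes = c(56200001L, 56200002L))
}

small_survey <- function(n = 600, seed = 11, ...) {
  generate_survey(generator_config(n_persons = n, n_replicates = 16,
                                   seed = seed, ...))
}

# Person-day totals for a cohort subset, plus the persons/weights frame.
cohort_days <- function(survey, scenario = fortification_scenario(0),
                        adults_only = FALSE) {
  supp <- average_daily_supplement_fa(
    survey$supplements, person_ids = survey$demographics$person_id)
  excl <- apply_exclusions(survey$demographics, supp)
  cohort <- excl$cohort
  if (adults_only) cohort <- cohort[cohort$age_years >= 19, ]
  days <- add_supplement_to_days(apply_scenario(survey$recalls, scenario),
                                 supp)
  days <- days[days$person_id %in% cohort$person_id, ]
  list(days = days,
       persons = data.frame(person_id = cohort$person_id,
                            weight = cohort$weight),
       cohort = cohort,
       repw = as.matrix(cohort[, grep("^rw", names(cohort))]))
}
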