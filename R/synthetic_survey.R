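#' Configuration for the synthetic survey generator
#'
#' Builds and validates the parameter set used by [generate_survey()].  The
#' generator emulates the statistical structure of a national dietary survey:
#' two 24-hour recalls for most persons and a single recall for the fraction
#' belonging to an early one-day cycle; log-scale between- and within-person
#' variation in food folic acid; a supplement-user subpopulation taking
#' folic-acid-containing products at per-person constant daily amounts; corn
#' masa flour consumption concentrated in one race/ethnicity stratum; and
#' positive survey weights with a full set of delete-one-group jackknife
#' replicate weights.
#'
#' Intake defaults describe a population in which food folic acid averages
#' roughly 200 ug/day (a grain-fortified food supply), about a third of
#' persons take a folic-acid supplement, and corn masa products are eaten by
#' about two thirds of the Mexican American stratum and a quarter of the
#' others.  Between- and within-person log-scale SDs default to 0.5 and 0.6:
#' in repeated 24-hour recalls the day-to-day component is typically at least
#' as large as the between-person component.  These defaults are illustrative
#' calibrations, not estimates from any survey release.
#'
#' @param n_persons number of surveyed persons.
#' @param frac_one_day proportion of persons assigned to the one-recall-day
#'   cycle (labelled `"2001-2002"`); the rest provide two days
#'   (`"2003-2008"`).
#' @param mu_log_food_fa location of usual food folic acid on the log-ug
#'   scale.
#' @param sigma_between between-person SD of usual log intake (> 0).
#' @param sigma_within within-person (day-to-day) SD of log intake (> 0).
#' @param supplement_user_prob probability a person uses a folic-acid
#'   supplement.
#' @param supplement_dose_dist list with `values` (per-serving ug) and
#'   `probs` summing to 1; each user's product is drawn from it.
#' @param corn_masa_consumer_prob_by_stratum named vector of consumption
#'   probabilities per race/ethnicity stratum; names must cover
#'   `race_levels`.
#' @param nonwholegrain_meanlog,nonwholegrain_sdlog lognormal parameters of
#'   the per-person non-wholegrain grams in one corn-masa food occurrence.
#' @param weekend_bump multiplicative intake increase on Saturday/Sunday
#'   recalls (0.10 = +10%), giving the day-of-week adjustment signal to
#'   remove.
#' @param n_replicates number of jackknife replicate weights (>= 2).
#' @param pregnant_prob probability of pregnancy among women aged 15-44.
#' @param quality_fail_prob per-day probability a recall fails the minimum
#'   data-quality standard.
#' @param missing_supp_prob probability the supplement interview is missing.
#' @param race_levels,race_probs race/ethnicity strata and their sampling
#'   probabilities (unweighted composition; minority strata oversampled as in
#'   a multistage national survey, with weights compensating).
#' @param race_weight_factors positive multipliers applied to each stratum's
#'   base weights, so weighted population shares differ from the oversampled
#'   unweighted composition.
#' @param seed integer seed; identical seed and configuration give
#'   byte-identical output tables.
#'
#' @return an object of class `generator_config` (a validated list).
#' @seealso [generate_survey()], [generate_replicate_weights()]
#' @export
generator_config <- function(n_persons = 2000,
                             frac_one_day = 0.25,
                             mu_log_food_fa = log(200),
                             sigma_between = 0.5,
                             sigma_within = 0.6,
                             supplement_user_prob = 0.342,
                             supplement_dose_dist = list(
                               values = c(200, 400, 800, 1000),
                               probs = c(0.15, 0.60, 0.15, 0.10)
                             ),
                             corn_masa_consumer_prob_by_stratum = c(
                               "non-Hispanic white" = 0.247,
                               "non-Hispanic black" = 0.250,
                               "Mexican American" = 0.646,
                               "other" = 0.300
                             ),
                             nonwholegrain_meanlog = log(30),
                             nonwholegrain_sdlog = 0.5,
                             weekend_bump = 0.10,
                             n_replicates = 122,
                             pregnant_prob = 0.14,
                             quality_fail_prob = 0.08,
                             missing_supp_prob = 0.009,
                             race_levels = c("non-Hispanic white",
                                             "non-Hispanic black",
                                             "Mexican American", "other"),
                             race_probs = c(0.41, 0.25, 0.245, 0.095),
                             race_weight_factors = c(2.2, 0.7, 0.5, 1.5),
                             seed = 1L) {
  chk_prop <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop_field(nm, "must be a proportion in [0, 1]")
  }
  if (!is.numeric(n_persons) || n_persons < 1)
    stop_field("n_persons", "must be a positive count")
  chk_prop(frac_one_day, "frac_one_day")
  chk_prop(supplement_user_prob, "supplement_user_prob")
  chk_prop(pregnant_prob, "pregnant_prob")
  chk_prop(quality_fail_prob, "quality_fail_prob")
  chk_prop(missing_supp_prob, "missing_supp_prob")
  if (!is.numeric(sigma_between) || sigma_between <= 0)
    stop_field("sigma_between", "must be > 0")
  if (!is.numeric(sigma_within) || sigma_within <= 0)
    stop_field("sigma_within", "must be > 0")
  if (!is.numeric(n_replicates) || n_replicates < 2)
    stop_field("n_replicates", "must be a count >= 2")
  if (!is.list(supplement_dose_dist) ||
      !all(c("values", "probs") %in% names(supplement_dose_dist)) ||
      length(supplement_dose_dist$values) !=
        length(supplement_dose_dist$probs) ||
      any(supplement_dose_dist$probs < 0) ||
      abs(sum(supplement_dose_dist$probs) - 1) > 1e-8)
    stop_field("supplement_dose_dist",
               "must provide matching 'values' and 'probs' summing to 1")
  if (!all(race_levels %in% names(corn_masa_consumer_prob_by_stratum)))
    stop_field("corn_masa_consumer_prob_by_stratum",
               "must name every race/ethnicity stratum")
  for (p in corn_masa_consumer_prob_by_stratum)
    chk_prop(p, "corn_masa_consumer_prob_by_stratum")
  if (length(race_probs) != length(race_levels) ||
      abs(sum(race_probs) - 1) > 1e-8)
    stop_field("race_probs", "must sum to 1 over race_levels")
  if (length(race_weight_factors) != length(race_levels) ||
      any(race_weight_factors <= 0))
    stop_field("race_weight_factors",
               "must be positive, one per race level")
  if (weekend_bump < 0)
    stop_field("weekend_bump", "must be >= 0")

  structure(list(
    n_persons = as.integer(n_persons), frac_one_day = frac_one_day,
    mu_log_food_fa = mu_log_food_fa, sigma_between = sigma_between,
    sigma_within = sigma_within,
    supplement_user_prob = supplement_user_prob,
    supplement_dose_dist = supplement_dose_dist,
    corn_masa_consumer_prob_by_stratum = corn_masa_consumer_prob_by_stratum,
    nonwholegrain_meanlog = nonwholegrain_meanlog,
    nonwholegrain_sdlog = nonwholegrain_sdlog,
    weekend_bump = weekend_bump, n_replicates = as.integer(n_replicates),
    pregnant_prob = pregnant_prob, quality_fail_prob = quality_fail_prob,
    missing_supp_prob = missing_supp_prob,
    race_levels = race_levels, race_probs = race_probs,
    race_weight_factors = race_weight_factors,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Generate a synthetic dietary survey with known ground truth
#'
#' Draws a seeded population and emits the three tables the analysis
#' consumes (demographics with analytic and replicate weights, per-food
#' 24-hour recall rows, and 30-day supplement reports) together with the
#' generating truth needed for recovery tests.
#'
#' Per person `i`, usual log food folic acid is
#' `mu_i = mu_log_food_fa + N(0, sigma_between^2)`; an observed recall day is
#' `exp(mu_i + N(0, sigma_within^2))`, multiplied by `1 + weekend_bump` on
#' Saturday/Sunday recalls.  The day-of-week-standardized true usual food
#' intake is therefore `exp(mu_i + sigma_within^2 / 2)` (the long-run mean of
#' a lognormal day around `mu_i` on a reference weekday).  Supplement users
#' carry a per-person constant daily supplemental amount (dose x days taken /
#' 30), mirroring 30-day-average supplement reporting.  Corn masa consumers
#' (probability set per race/ethnicity stratum) eat one corn-masa food per
#' recall day with a person-constant non-wholegrain gram amount; unfortified
#' corn masa contributes no folic acid, so those rows carry
#' `folic_acid_ug = 0` and the scenario engine supplies the added amount.
#'
#' @param config a [generator_config()].
#' @return a list of class `synthetic_survey` with elements
#'   `demographics` (one row per person: id, sex, race/ethnicity, age,
#'   pregnancy flag, cycle, recall-quality flags, supplement-info flag,
#'   `weight`, and replicate-weight columns `rw1..rwR`),
#'   `recalls` (one row per food per recall day),
#'   `supplements` (one row per reported product), and
#'   `truth` (class `synthetic_truth`: per-person true usual components and
#'   the true weighted exceedance fractions per age-specific cut-point under
#'   the current and 140 ug/100 g fortified scenarios).
#' @export
generate_survey <- function(config) {
  if (!inherits(config, "generator_config"))
    config <- do.call(generator_config, config)
  local_seed(config$seed, {
    n <- config$n_persons
    person_id <- seq_len(n)

    sex <- sample(c("male", "female"), n, replace = TRUE)
    race <- sample(config$race_levels, n, replace = TRUE,
                   prob = config$race_probs)
    age <- sample(0:80, n, replace = TRUE)
    pregnant <- sex == "female" & age >= 15 & age <= 44 &
      stats::runif(n) < config$pregnant_prob
    cycle <- ifelse(stats::runif(n) < config$frac_one_day,
                    "2001-2002", "2003-2008")
    n_days <- ifelse(cycle == "2001-2002", 1L, 2L)

    q1 <- stats::runif(n) >= config$quality_fail_prob
    q2 <- ifelse(n_days == 2, stats::runif(n) >= config$quality_fail_prob, NA)
    supp_present <- stats::runif(n) >= config$missing_supp_prob

    # Minority strata oversampled; weights compensate so weighted shares
    # approximate a general population.
    race_factor <- config$race_weight_factors[match(race,
                                                    config$race_levels)]
    weight <- stats::rlnorm(n, 0, 0.5) * race_factor
    repw <- generate_replicate_weights(weight, config$n_replicates,
                                       seed = config$seed + 1L)

    mu_i <- config$mu_log_food_fa +
      stats::rnorm(n, 0, config$sigma_between)
    supp_user <- supp_present & stats::runif(n) < config$supplement_user_prob
    dose <- sample(config$supplement_dose_dist$values, n, replace = TRUE,
                   prob = config$supplement_dose_dist$probs)
    days_taken <- sample(c(30L, 15L, 7L), n, replace = TRUE,
                         prob = c(0.7, 0.2, 0.1))
    consumer_p <- config$corn_masa_consumer_prob_by_stratum[race]
    masa_consumer <- stats::runif(n) < consumer_p
    nwg <- stats::rlnorm(n, config$nonwholegrain_meanlog,
                         config$nonwholegrain_sdlog)

    # --- recall rows -------------------------------------------------------
    rows <- vector("list", 2L)
    masa_codes <- corn_masa_food_codes()$food_code
    for (d in 1:2) {
      keep <- n_days >= d
      idx <- which(keep)
      dow <- sample(1:7, length(idx), replace = TRUE)
      mode <- if (d == 1) rep("in-person", length(idx)) else
        ifelse(stats::runif(length(idx)) < 0.85, "telephone", "in-person")
      eps <- stats::rnorm(length(idx), 0, config$sigma_within)
      bump <- ifelse(dow %in% c(1, 7), log1p(config$weekend_bump), 0)
      fa <- exp(mu_i[idx] + eps + bump)
      base <- data.frame(
        person_id = person_id[idx], day_index = d,
        food_code = 10000000L, amount_g = round(100 + 2 * fa, 1),
        folic_acid_ug = fa, nonwholegrain_g = 0,
        day_of_week = dow, interview_mode = mode,
        stringsAsFactors = FALSE
      )
      m_idx <- which(keep & masa_consumer)
      pos <- match(m_idx, idx)
      masa <- data.frame(
        person_id = person_id[m_idx], day_index = d,
        food_code = sample(masa_codes, length(m_idx), replace = TRUE),
        amount_g = round(1.6 * nwg[m_idx], 1),
        folic_acid_ug = 0, nonwholegrain_g = round(nwg[m_idx], 2),
        day_of_week = dow[pos], interview_mode = mode[pos],
        stringsAsFactors = FALSE
      )
      rows[[d]] <- rbind(base, masa)
    }
    recalls <- do.call(rbind, rows)
    recalls <- recalls[order(recalls$person_id, recalls$day_index,
                             recalls$food_code), ]
    rownames(recalls) <- NULL

    # --- supplements -------------------------------------------------------
    u <- which(supp_user)
    supplements <- data.frame(
      person_id = person_id[u],
      fa_per_serving_ug = dose[u],
      days_taken_past30 = days_taken[u],
      servings_per_day = rep(1, length(u)),
      stringsAsFactors = FALSE
    )
    second <- u[stats::runif(length(u)) < 0.15]
    if (length(second)) {
      supplements <- rbind(supplements, data.frame(
        person_id = person_id[second],
        fa_per_serving_ug = rep(100, length(second)),
        days_taken_past30 = rep(10L, length(second)),
        servings_per_day = rep(1, length(second)),
        stringsAsFactors = FALSE
      ))
    }
    supplements <- supplements[order(supplements$person_id), ]
    rownames(supplements) <- NULL

    demographics <- data.frame(
      person_id = person_id, sex = sex, race_ethnicity = race,
      age_years = age, pregnant = pregnant, cycle = cycle,
      recall_quality_ok_day1 = q1, recall_quality_ok_day2 = q2,
      supplement_info_present = supp_present, weight = weight,
      stringsAsFactors = FALSE
    )
    colnames(repw) <- paste0("rw", seq_len(ncol(repw)))
    demographics <- cbind(demographics, as.data.frame(repw))

    # --- ground truth ------------------------------------------------------
    true_food <- exp(mu_i + config$sigma_within^2 / 2)
    true_supp <- ifelse(supp_user, dose * days_taken / 30, 0)
    second_flag <- person_id %in% person_id[second]
    true_supp <- true_supp + ifelse(second_flag, 100 * 10 / 30, 0)
    true_nwg <- ifelse(masa_consumer, nwg, 0)

    persons <- data.frame(
      person_id = person_id, true_food_fa_ug = true_food,
      true_supplement_fa_ug = true_supp,
      corn_masa_consumer = masa_consumer,
      true_nonwholegrain_g = true_nwg, weight = weight,
      age_years = age, stringsAsFactors = FALSE
    )
    truth <- structure(
      list(persons = persons,
           exceedance = truth_exceedance(persons, level_ug_per_100g = 140)),
      class = "synthetic_truth"
    )

    structure(list(demographics = demographics, recalls = recalls,
                   supplements = supplements, truth = truth,
                   config = config),
              class = "synthetic_survey")
  })
}

# True weighted exceedance fractions per age-specific cut-point, computed
# directly from the generating usual intakes (current and fortified).
truth_exceedance <- function(persons, level_ug_per_100g) {
  p <- persons[persons$age_years >= 1, ]
  cur <- p$true_food_fa_ug + p$true_supplement_fa_ug
  mod <- cur + p$true_nonwholegrain_g * level_ug_per_100g / 100
  ul <- vapply(p$age_years, ul_for_age, numeric(1))
  sched <- ul_schedule()
  out <- lapply(seq_len(nrow(sched)), function(i) {
    sel <- p$age_years >= sched$age_min[i] & p$age_years <= sched$age_max[i]
    if (!any(sel)) return(NULL)
    w <- p$weight[sel]
    data.frame(
      age_group = sched$age_group[i], cutpoint_ug = sched$cutpoint_ug[i],
      n = sum(sel),
      current_frac = sum(w * (cur[sel] > ul[sel])) / sum(w),
      fortified_frac = sum(w * (mod[sel] > ul[sel])) / sum(w),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Delete-one-group jackknife replicate weights
#'
#' Partitions persons at random into `n_replicates` pseudo-groups and builds
#' one replicate-weight column per group: the deleted group's weights are set
#' to zero and the remaining weights are scaled up so every column preserves
#' the total of the base weights.
#'
#' @param weights positive base analytic weights.
#' @param n_replicates number of replicate columns (>= 2, at most
#'   `length(weights)`).
#' @param seed integer seed for the random partition.
#' @return a numeric matrix with `length(weights)` rows and `n_replicates`
#'   columns; every column sums to `sum(weights)`.
#' @export
generate_replicate_weights <- function(weights, n_replicates, seed = 1L) {
  if (any(weights <= 0) || any(!is.finite(weights)))
    stop("base weights must be positive and finite", call. = FALSE)
  n <- length(weights)
  if (n_replicates < 2)
    stop_field("n_replicates", "must be >= 2")
  if (n_replicates > n)
    stop_field("n_replicates", "exceeds the number of persons")
  local_seed(seed, {
    grp <- sample(rep(seq_len(n_replicates), length.out = n))
    total <- sum(weights)
    out <- matrix(0, n, n_replicates)
    for (r in seq_len(n_replicates)) {
      del <- grp == r
      w <- weights
      w[del] <- 0
      w[!del] <- w[!del] * total / sum(w[!del])
      out[, r] <- w
    }
    out
  })
}

#' Write the synthetic survey tables to disk
#'
#' Writes `demographics.csv`, `recalls.csv` and `supplements.csv` (with the
#' documented column names) plus `truth.json` into `dir`.
#'
#' @param survey a `synthetic_survey` from [generate_survey()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "synthetic_survey"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(survey$demographics, file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  utils::write.csv(survey$recalls, file.path(dir, "recalls.csv"),
                   row.names = FALSE)
  utils::write.csv(survey$supplements, file.path(dir, "supplements.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(persons = survey$truth$persons,
         exceedance = survey$truth$exceedance),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE
  )
  invisible(dir)
}

#' Read survey tables written by [write_survey()]
#'
#' @param dir directory containing `demographics.csv`, `recalls.csv` and
#'   `supplements.csv`.
#' @return a list with `demographics`, `recalls` and `supplements`
#'   data frames.
#' @export
read_survey <- function(dir) {
  list(
    demographics = utils::read.csv(file.path(dir, "demographics.csv"),
                                   stringsAsFactors = FALSE),
    recalls = utils::read.csv(file.path(dir, "recalls.csv"),
                              stringsAsFactors = FALSE),
    supplements = utils::read.csv(file.path(dir, "supplements.csv"),
                                  stringsAsFactors = FALSE)
  )
}
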