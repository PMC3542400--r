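#' Run the fortification-exceedance pipeline
#'
#' Orchestrates the full analysis: obtain survey tables (from the synthetic
#' generator or from CSV paths), compute current and modeled person-day
#' intakes under a fortification scenario, add 30-day-average supplemental
#' folic acid, apply the analytic exclusion cascade, fit the usual-intake
#' model on current intake, evaluate the fortified totals under the same fit
#' (see [scenario_exceedance()]), and estimate the weighted percentage above
#' the age-specific UL in every stratum, with jackknife replicate-weight
#' standard errors and paired two-sided t-tests of the current-vs-modeled
#' difference.
#'
#' @param config a list (or path to a JSON/YAML file) with elements:
#'   `generator` (arguments for [generator_config()]) or `input_dir` (tables
#'   written by [write_survey()]); `scenario` (list with `level_ug_per_100g`
#'   and optional `food_list_path`); `seed`; optional `axes` (subset of
#'   `"total", "sex", "race", "age"`), `populations` (subset of `"all",
#'   "corn_masa_consumers"`), `supplement_groups` (subset of `"all",
#'   "non-user", "user"`), `dow_scheme`, `min_stratum_n` (strata smaller
#'   than this are omitted with a warning; default 25), and `ul_overrides`
#'   (named list of age groups from [ul_schedule()] mapped to replacement
#'   cut-points in ug/day).
#' @return a result bundle (class `masafort_result`): `ledger`,
#'   `demographics_table`, `adult_table`, `child_table`, `scenario`, `seed`.
#'   Identical config and seed give an identical bundle.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!xor(is.null(config$generator), is.null(config$input_dir)))
    stop("config must provide exactly one of 'generator' or 'input_dir'",
         call. = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  axes <- if (is.null(config$axes)) c("total", "sex", "race", "age")
          else config$axes
  pops <- if (is.null(config$populations))
    c("all", "corn_masa_consumers") else config$populations
  supp_groups <- if (is.null(config$supplement_groups))
    c("all", "non-user", "user") else config$supplement_groups
  dow_scheme <- if (is.null(config$dow_scheme)) "weekpart"
                else config$dow_scheme
  min_n <- if (is.null(config$min_stratum_n)) 25
           else config$min_stratum_n
  sched <- ul_schedule()
  if (!is.null(config$ul_overrides)) {
    ov <- config$ul_overrides
    bad <- setdiff(names(ov), sched$age_group)
    if (length(bad))
      stop("unknown UL override age group(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    sched$cutpoint_ug[match(names(ov), sched$age_group)] <-
      as.numeric(unlist(ov))
  }

  # --- inputs --------------------------------------------------------------
  if (!is.null(config$generator)) {
    gen <- config$generator
    gen$seed <- seed
    survey <- generate_survey(do.call(generator_config, gen))
    data <- survey[c("demographics", "recalls", "supplements")]
  } else {
    data <- read_survey(config$input_dir)
  }

  sc <- config$scenario
  level <- if (is.null(sc$level_ug_per_100g)) 140 else sc$level_ug_per_100g
  codes <- if (!is.null(sc$food_list_path))
    utils::read.csv(sc$food_list_path, stringsAsFactors = FALSE)$food_code
  else corn_masa_food_codes()$food_code
  scenario <- fortification_scenario(level, codes)
  null_scenario <- fortification_scenario(0, codes)

  # --- intakes -------------------------------------------------------------
  all_ids <- data$demographics$person_id
  supp_fa <- average_daily_supplement_fa(data$supplements,
                                         person_ids = all_ids)
  supp_user <- flag_supplement_user(data$supplements, person_ids = all_ids)
  masa_flag <- flag_corn_masa_consumers(data$recalls, scenario)

  days_cur <- add_supplement_to_days(
    apply_scenario(data$recalls, null_scenario), supp_fa)
  days_mod <- add_supplement_to_days(
    apply_scenario(data$recalls, scenario), supp_fa)

  # --- cohort --------------------------------------------------------------
  excl <- apply_exclusions(data$demographics, supp_fa)
  cohort <- assign_strata(excl$cohort, supp_user, masa_flag)
  repw <- as.matrix(cohort[, grep("^rw", names(cohort)), drop = FALSE])

  keep_days <- function(days) {
    days[days$person_id %in% cohort$person_id, , drop = FALSE]
  }
  days_cur <- keep_days(days_cur)
  days_mod <- keep_days(days_mod)

  # --- demographics table --------------------------------------------------
  demo <- demographics_table(cohort, repw)

  # --- exceedance cells ----------------------------------------------------
  strata_defs <- function(pool, adult) {
    defs <- list()
    if ("total" %in% axes)
      defs[["total"]] <- list(total = rep(TRUE, nrow(pool)))
    if ("sex" %in% axes)
      defs[["sex"]] <- split_flags(pool$sex)
    if ("race" %in% axes)
      defs[["race"]] <- split_flags(pool$race_stratum, drop_na = TRUE)
    if ("age" %in% axes) {
      groups <- if (adult) c("19-30", "31-50", "51-70", ">70")
                else c("1-3", "4-8", "9-13", "14-18")
      defs[["age"]] <- split_flags(pool$age_group, keep = groups)
    }
    defs
  }

  cell <- function(pool_sel, cutpoint, population, axis, stratum, supp) {
    ids <- cohort$person_id[pool_sel]
    persons <- data.frame(person_id = ids,
                          weight = cohort$weight[pool_sel])
    rw <- repw[pool_sel, , drop = FALSE]
    dc <- days_cur[days_cur$person_id %in% ids, , drop = FALSE]
    dm <- days_mod[days_mod$person_id %in% ids, , drop = FALSE]
    out <- tryCatch({
      sx <- scenario_exceedance(dc, dm, persons, cutpoint,
                                replicate_weights = rw,
                                dow_scheme = dow_scheme)
      cur <- sx$current
      mod <- sx$modeled
      cmp <- sx$comparison
      data.frame(
        population = population, axis = axis, stratum = stratum,
        supplement_group = supp, cutpoint_ug = cutpoint,
        n_unweighted = length(ids),
        current_pct = cur$percent_above, current_se = cur$se,
        current_ci_lo = cur$ci95[1], current_ci_hi = cur$ci95[2],
        current_ne = cur$ne,
        modeled_pct = mod$percent_above, modeled_se = mod$se,
        modeled_ci_lo = mod$ci95[1], modeled_ci_hi = mod$ci95[2],
        modeled_ne = mod$ne,
        diff_pct = cmp$difference, diff_p = cmp$p,
        stringsAsFactors = FALSE
      )
    }, error = function(e) {
      warning(sprintf("cell %s/%s/%s/%s skipped: %s", population, axis,
                      stratum, supp, conditionMessage(e)), call. = FALSE)
      NULL
    })
    out
  }

  build_table <- function(adult) {
    rows <- list()
    for (population in pops) {
      pop_sel <- if (population == "all") rep(TRUE, nrow(cohort))
                 else cohort$corn_masa_consumer
      base_sel <- pop_sel &
        (if (adult) cohort$age_years >= 19
         else cohort$age_years >= 1 & cohort$age_years <= 18)
      for (supp in supp_groups) {
        supp_sel <- switch(supp,
          all = rep(TRUE, nrow(cohort)),
          `non-user` = !cohort$supplement_user,
          user = cohort$supplement_user)
        pool_sel0 <- base_sel & supp_sel
        for (axis in names(strata_defs(cohort, adult))) {
          flags <- strata_defs(cohort, adult)[[axis]]
          for (stratum in names(flags)) {
            sel <- pool_sel0 & flags[[stratum]]
            n <- sum(sel)
            if (n < min_n) {
              if (n > 0)
                warning(sprintf(
                  "stratum %s/%s/%s/%s omitted (n = %d < %d)",
                  population, axis, stratum, supp, n, min_n),
                  call. = FALSE)
              next
            }
            cut <- if (adult)
              sched$cutpoint_ug[sched$age_group == ">=19"]
            else ul_for_age(min(cohort$age_years[sel]), sched)
            rows[[length(rows) + 1]] <-
              cell(sel, cut, population, axis, stratum, supp)
          }
        }
      }
    }
    if (!length(rows)) return(NULL)
    do.call(rbind, rows)
  }

  structure(list(
    ledger = excl$ledger,
    demographics_table = demo,
    adult_table = build_table(adult = TRUE),
    child_table = build_table(adult = FALSE),
    scenario = scenario, seed = seed
  ), class = "masafort_result")
}

# One logical vector per level of a stratification variable.
split_flags <- function(x, drop_na = FALSE, keep = NULL) {
  levels <- if (is.null(keep)) sort(unique(x[!is.na(x)])) else keep
  out <- lapply(levels, function(l) !is.na(x) & x == l)
  stats::setNames(out, levels)
}

# Table-1-style demographics: unweighted n, weighted share, and weighted
# corn-masa-consumer / supplement-user percentages per stratum.
demographics_table <- function(cohort, repw) {
  axes <- list(
    total = list(total = rep(TRUE, nrow(cohort))),
    sex = split_flags(cohort$sex),
    race = split_flags(cohort$race_stratum, drop_na = TRUE),
    age = split_flags(cohort$age_group)
  )
  rows <- list()
  for (axis in names(axes)) {
    for (stratum in names(axes[[axis]])) {
      sel <- axes[[axis]][[stratum]]
      if (!any(sel)) next
      w <- cohort$weight
      share <- weighted_proportion(sel, w, repw)
      masa <- weighted_proportion(cohort$corn_masa_consumer[sel], w[sel],
                                  repw[sel, , drop = FALSE])
      supp <- weighted_proportion(cohort$supplement_user[sel], w[sel],
                                  repw[sel, , drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(
        axis = axis, stratum = stratum, n_unweighted = sum(sel),
        weighted_pct = share$percent,
        weighted_ci_lo = share$ci95[1], weighted_ci_hi = share$ci95[2],
        corn_masa_pct = masa$percent,
        corn_masa_ci_lo = masa$ci95[1], corn_masa_ci_hi = masa$ci95[2],
        supplement_user_pct = supp$percent,
        supplement_ci_lo = supp$ci95[1], supplement_ci_hi = supp$ci95[2],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Write result tables to CSV and text
#'
#' Emits the three table families (demographics; adult UL exceedance; child
#' age-specific UL exceedance) as CSV plus a human-readable text rendering in
#' which cells whose tail-instability guard fired print `NE`, together with
#' the exclusion ledger as JSON and log lines.
#'
#' @param bundle a `masafort_result` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
render_tables <- function(bundle, dir) {
  stopifnot(inherits(bundle, "masafort_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$demographics_table,
                   file.path(dir, "table1_demographics.csv"),
                   row.names = FALSE)
  fmt_cell <- function(pct, lo, hi, ne) {
    ifelse(ne, "NE [a]",
           sprintf("%.1f (%.1f, %.1f)", pct, lo, hi))
  }
  write_family <- function(tab, stem, title) {
    if (is.null(tab)) return(invisible(NULL))
    utils::write.csv(tab, file.path(dir, paste0(stem, ".csv")),
                     row.names = FALSE)
    txt <- c(
      title,
      sprintf("%-20s %-6s %-20s %-9s %7s  %-22s %-22s %8s",
              "population", "axis", "stratum", "suppl.", "n",
              "current % >= UL (CI)", "modeled % >= UL (CI)", "p"),
      sprintf("%-20s %-6s %-20s %-9s %7d  %-22s %-22s %8.3f",
              tab$population, tab$axis, tab$stratum,
              tab$supplement_group, tab$n_unweighted,
              fmt_cell(tab$current_pct, tab$current_ci_lo,
                       tab$current_ci_hi, tab$current_ne),
              fmt_cell(tab$modeled_pct, tab$modeled_ci_lo,
                       tab$modeled_ci_hi, tab$modeled_ne),
              tab$diff_p),
      "[a] NE = not estimable: fewer than 12 persons beyond the cut-point."
    )
    writeLines(txt, file.path(dir, paste0(stem, ".txt")))
  }
  write_family(bundle$adult_table, "table2_adult_ul_exceedance",
               "Percentage of adults (>= 19 y) with usual total folic acid intake >= 1,000 ug/day")
  write_family(bundle$child_table, "table3_child_ul_exceedance",
               "Percentage of children (1-18 y) exceeding the age-specific UL")
  ledger_json(bundle$ledger, file.path(dir, "exclusion_ledger.json"))
  writeLines(utils::capture.output(print(bundle$ledger)),
             file.path(dir, "exclusion_ledger.txt"))
  invisible(dir)
}
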