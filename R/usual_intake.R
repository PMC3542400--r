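#' Shifted power-family transformation
#'
#' `power_transform(x, lambda, shift)` maps intake to
#' `((x + shift)^lambda - 1) / lambda` (the natural log of `x + shift` at
#' `lambda = 0`).  The shift keeps arguments positive for data containing
#' zeros.
#'
#' @param x intake values.
#' @param lambda power parameter; 0 selects the log.
#' @param shift non-negative shift added before transforming.
#' @return transformed values.
#' @export
power_transform <- function(x, lambda, shift = 0) {
  xs <- x + shift
  if (any(xs <= 0))
    stop("power transform requires x + shift > 0", call. = FALSE)
  if (abs(lambda) < 1e-12) log(xs) else (xs^lambda - 1) / lambda
}

#' Invert the fitted transformation
#'
#' Exact inverse of the shifted power transform of a fitted model (or of a
#' bare `list(lambda, shift)`), with no bias adjustment; round-trips with
#' [power_transform()] to within 1e-10 relative tolerance.
#'
#' @param model a `usual_intake_model` or a list with `lambda` and `shift`.
#' @param value transformed-scale value(s).
#' @return original-scale intake in ug.
#' @export
back_transform <- function(model, value) {
  lambda <- model$lambda
  shift <- if (is.null(model$shift)) 0 else model$shift
  if (abs(lambda) < 1e-12) return(exp(value) - shift)
  arg <- lambda * value + 1
  if (any(arg <= 0))
    stop("value outside the range of the lambda = ", lambda,
         " transformation", call. = FALSE)
  arg^(1 / lambda) - shift
}

# Second derivative of the inverse transform, used for the second-order
# back-transform bias adjustment E[h(x + e)] ~ h(x) + h''(x) var(e) / 2.
inverse_second_deriv <- function(lambda, value) {
  if (abs(lambda) < 1e-12) return(exp(value))
  (1 - lambda) * (lambda * value + 1)^(1 / lambda - 2)
}

# Day-of-week factor under the configured scheme; reference level first.
dow_factor <- function(dow, scheme) {
  if (scheme == "full") {
    factor(dow, levels = c(2, 3, 4, 5, 6, 7, 1))
  } else {
    lev <- ifelse(dow %in% 2:5, "weekday",
                  ifelse(dow == 6, "friday", "weekend"))
    factor(lev, levels = c("weekday", "friday", "weekend"))
  }
}

#' Fit the usual-intake measurement-error model
#'
#' Estimates the distribution of usual (long-run average) daily intake from
#' one or two 24-hour recalls per person, separating within-person
#' (day-to-day) from between-person variation:
#'
#' 1. A shifted power-family transformation (lambda over a grid, log
#'    included) is selected to minimize the absolute weighted skewness of the
#'    transformed day intakes.
#' 2. Transformed intakes are regressed on day-of-week and interview-mode
#'    indicators (weighted least squares) and the estimated effects are
#'    subtracted relative to the reference recall (weekday, in person).
#' 3. The within-person variance is the weighted mean of half the squared
#'    difference between the two adjusted recalls of two-day persons — or an
#'    externally supplied value, which allows a one-day cycle to borrow the
#'    day-to-day variability estimated from two-day cycles.  The
#'    between-person variance is the weighted variance of person means minus
#'    the within-variance contribution `sigma2_within * mean(1/d_i)`, floored
#'    at zero.
#' 4. Each person's mean is shrunk toward the weighted grand mean by
#'    `F_i = sigma2_between / (sigma2_between + sigma2_within / d_i)` (the
#'    best person-level predictor).  For the population distribution the
#'    person deviations are instead scaled by `sqrt(F_i)`, which makes the
#'    transformed usual values reproduce the between-person variance exactly;
#'    usual intake on the original scale is the back-transformed value plus
#'    the second-order adjustment `h''(value) * sigma2_within / 2` for the
#'    nonlinear back-transform, so it targets the long-run mean rather than
#'    the median day.
#'
#' @param person_days data frame with `person_id`, `total_fa_ug`,
#'   `day_of_week` (1 = Sunday ... 7 = Saturday) and `interview_mode`
#'   (`"in-person"` or `"telephone"`).
#' @param persons data frame with `person_id` and `weight` (> 0 analytic
#'   weight; 0 allowed for replicate-deleted persons).
#' @param external_within_variance optional transformed-scale within-person
#'   variance to use instead of the two-day estimate.
#' @param dow_scheme `"weekpart"` (weekday / Friday / weekend; default) or
#'   `"full"` (7 levels, Monday reference).
#' @param lambda_grid candidate powers (default -1..1 by 0.05).
#' @param lambda optional fixed power, skipping selection (used when
#'   refitting under replicate weights).
#' @return object of class `usual_intake_model`: `lambda`, `shift`,
#'   `covariate_effects`, `sigma2_between`, `sigma2_within`, `grand_mean`,
#'   and a `persons` table with per-person day counts, transformed means,
#'   shrinkage factors, shrunken means and bias-adjusted usual intakes
#'   (`usual_ug`).
#' @export
fit_usual_intake <- function(person_days, persons,
                             external_within_variance = NULL,
                             dow_scheme = c("weekpart", "full"),
                             lambda_grid = seq(-1, 1, by = 0.05),
                             lambda = NULL) {
  dow_scheme <- match.arg(dow_scheme)
  need <- c("person_id", "total_fa_ug", "day_of_week", "interview_mode")
  missing_cols <- setdiff(need, names(person_days))
  if (length(missing_cols))
    stop("person_days lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (any(persons$weight < 0))
    stop("weights must be >= 0", call. = FALSE)

  w_person <- stats::setNames(persons$weight,
                              as.character(persons$person_id))
  pd <- person_days[as.character(person_days$person_id) %in%
                      names(w_person), , drop = FALSE]
  w_day <- as.numeric(w_person[as.character(pd$person_id)])
  x <- pd$total_fa_ug
  shift <- if (min(x) > 0) 0 else -min(x) + 1

  degenerate <- sqrt(wtd_var(x, pmax(w_day, 1e-12))) < 1e-10
  if (degenerate) {
    lambda <- 1
  } else if (is.null(lambda)) {
    crit <- vapply(lambda_grid, function(l)
      abs(wtd_skewness(power_transform(x, l, shift), pmax(w_day, 1e-12))),
      numeric(1))
    if (!any(is.finite(crit)))
      stop("no lambda in the grid gives a finite skewness criterion",
           call. = FALSE)
    lambda <- lambda_grid[which.min(replace(crit, !is.finite(crit), Inf))]
  }
  z <- power_transform(x, lambda, shift)

  # covariate adjustment relative to weekday / in-person reference
  dowf <- dow_factor(pd$day_of_week, dow_scheme)
  modef <- factor(pd$interview_mode, levels = c("in-person", "telephone"))
  covars <- list()
  if (nlevels(droplevels(dowf)) > 1) covars$dow <- dowf
  if (nlevels(droplevels(modef)) > 1) covars$mode <- modef
  effects <- numeric(length(z))
  coefs <- numeric(0)
  if (length(covars) && !degenerate) {
    df <- data.frame(z = z, covars)
    fit <- stats::lm(z ~ ., data = df, weights = pmax(w_day, 1e-12))
    beta <- stats::coef(fit)
    beta[is.na(beta)] <- 0
    mm <- stats::model.matrix(stats::terms(fit), df)
    effects <- as.numeric(mm[, -1, drop = FALSE] %*% beta[-1])
    coefs <- beta[-1]
  }
  z_adj <- z - effects

  # person-level means and variance components
  ids <- as.character(pd$person_id)
  zbar <- tapply(z_adj, ids, mean)
  d_i <- tapply(z_adj, ids, length)
  ord <- names(zbar)
  w_i <- as.numeric(w_person[ord])
  zbar <- as.numeric(zbar)
  d_i <- as.numeric(d_i)

  two <- d_i == 2
  if (is.null(external_within_variance)) {
    if (!any(two))
      stop("no two-day persons and no external within-person variance",
           call. = FALSE)
    z1 <- tapply(z_adj, ids, function(v) v[1])[ord]
    z2 <- tapply(z_adj, ids, function(v) v[length(v)])[ord]
    half_sq <- 0.5 * (as.numeric(z1[two]) - as.numeric(z2[two]))^2
    ww <- pmax(w_i[two], 1e-12)
    s2w <- sum(ww * half_sq) / sum(ww)
  } else {
    if (external_within_variance < 0)
      stop("external_within_variance must be >= 0", call. = FALSE)
    s2w <- external_within_variance
  }

  wpos <- pmax(w_i, 1e-12)
  grand <- wtd_mean(zbar, wpos)
  s2b <- max(0, wtd_var(zbar, wpos) - s2w * wtd_mean(1 / d_i, wpos))

  denom <- s2b + s2w / d_i
  f_i <- ifelse(denom == 0, 1, s2b / denom)
  shrunk <- grand + f_i * (zbar - grand)
  # Distribution representation: deviations scaled by sqrt(F_i) so the
  # transformed usual values reproduce the between-person variance s2b
  # exactly (full F_i shrinkage, optimal per person, would leave only
  # F_i * s2b and understate tail fractions).
  adjusted <- grand + sqrt(f_i) * (zbar - grand)
  usual <- pmax(0, back_transform(list(lambda = lambda, shift = shift),
                                  adjusted) +
                  0.5 * inverse_second_deriv(lambda, adjusted) * s2w)

  structure(list(
    lambda = lambda, shift = shift, covariate_effects = coefs,
    sigma2_between = s2b, sigma2_within = s2w, grand_mean = grand,
    dow_scheme = dow_scheme,
    persons = data.frame(
      person_id = ord, weight = w_i, n_days = d_i,
      mean_transformed = zbar, shrinkage = f_i,
      shrunk_transformed = shrunk, adjusted_transformed = adjusted,
      usual_ug = usual,
      stringsAsFactors = FALSE
    )
  ), class = "usual_intake_model")
}

#' @export
print.usual_intake_model <- function(x, ...) {
  cat(sprintf(
    "Usual-intake model: lambda = %.2f (shift %.3g), sigma2_between = %.4f, sigma2_within = %.4f, %d persons\n",
    x$lambda, x$shift, x$sigma2_between, x$sigma2_within,
    nrow(x$persons)))
  invisible(x)
}

#' Serialize a fitted usual-intake model summary to JSON
#'
#' @param model a `usual_intake_model`.
#' @param path optional output file.
#' @return JSON string (invisibly when written).
#' @export
model_json <- function(model, path = NULL) {
  obj <- list(lambda = model$lambda, shift = model$shift,
              sigma2_between = model$sigma2_between,
              sigma2_within = model$sigma2_within,
              grand_mean = model$grand_mean,
              covariate_effects = as.list(model$covariate_effects))
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' Weighted percentage of usual intake above a cut-point
#'
#' Evaluates the fitted usual-intake distribution (the weighted empirical
#' distribution of bias-adjusted back-transformed variance-matched person
#' values, see [fit_usual_intake()]) above a cut-point: `100 * sum(w * [usual > c]) / sum(w)`.  When fewer than
#' 12 (but more than 0) persons lie beyond the cut-point, the estimate is
#' flagged not-estimable (`ne`), reflecting the instability of tail estimates
#' at small effective sample sizes.
#'
#' @param model a fitted `usual_intake_model`.
#' @param cutpoint cut-point in ug/day (> 0), e.g. an age-specific UL.
#' @return object of class `exceedance_estimate` with `cutpoint_ug`,
#'   `percent_above`, `n_unweighted`, `n_beyond` and `ne`; `se` and `ci95`
#'   are `NA` until filled by replicate-weight inference.
#' @export
percent_above <- function(model, cutpoint) {
  if (!inherits(model, "usual_intake_model"))
    stop("model must be a usual_intake_model", call. = FALSE)
  if (cutpoint <= 0)
    stop("cutpoint must be > 0", call. = FALSE)
  p <- model$persons
  above <- p$usual_ug > cutpoint
  est <- 100 * sum(p$weight * above) / sum(p$weight)
  n_beyond <- sum(above)
  structure(list(
    cutpoint_ug = cutpoint, percent_above = est,
    n_unweighted = nrow(p), n_beyond = n_beyond,
    ne = n_beyond > 0 & n_beyond < 12,
    se = NA_real_, ci95 = c(NA_real_, NA_real_)
  ), class = "exceedance_estimate")
}

#' @export
print.exceedance_estimate <- function(x, ...) {
  val <- if (isTRUE(x$ne)) "NE" else sprintf("%.1f%%", x$percent_above)
  ci <- if (all(is.finite(x$ci95)))
    sprintf(" (95%% CI %.1f, %.1f)", x$ci95[1], x$ci95[2]) else ""
  cat(sprintf("%% usual intake >= %g ug/day: %s%s  [n = %d]\n",
              x$cutpoint_ug, val, ci, x$n_unweighted))
  invisible(x)
}

#' Evaluate new person-days under a fitted usual-intake model
#'
#' Holds every estimated component of `model` fixed — transformation,
#' covariate effects, variance components, grand mean and per-person
#' shrinkage — and recomputes person means from `person_days`.  This is how
#' fortification scenarios are evaluated: the scenario adds a deterministic
#' amount to reported intake without changing the recall-error structure, so
#' the measurement-error model estimated from current intake is reused and a
#' person-day total that can only increase yields a usual intake that can
#' only increase.
#'
#' @param model a fitted `usual_intake_model`.
#' @param person_days person-day totals for the same persons (same columns
#'   as in [fit_usual_intake()]).
#' @return a `usual_intake_model` with updated person means and usual
#'   intakes.
#' @export
project_usual_intake <- function(model, person_days) {
  stopifnot(inherits(model, "usual_intake_model"))
  pd <- person_days[as.character(person_days$person_id) %in%
                      model$persons$person_id, , drop = FALSE]
  z <- power_transform(pd$total_fa_ug, model$lambda, model$shift)
  z <- z - fixed_covariate_effects(model, pd$day_of_week,
                                   pd$interview_mode)
  zbar <- tapply(z, as.character(pd$person_id), mean)
  p <- model$persons
  new_mean <- as.numeric(zbar[p$person_id])
  if (any(is.na(new_mean)))
    stop("person_days must cover every person in the fitted model",
         call. = FALSE)
  p$mean_transformed <- new_mean
  p$shrunk_transformed <- model$grand_mean +
    p$shrinkage * (new_mean - model$grand_mean)
  p$adjusted_transformed <- model$grand_mean +
    sqrt(p$shrinkage) * (new_mean - model$grand_mean)
  p$usual_ug <- pmax(0, back_transform(model, p$adjusted_transformed) +
                       0.5 * inverse_second_deriv(model$lambda,
                                                  p$adjusted_transformed) *
                       model$sigma2_within)
  out <- model
  out$persons <- p
  out
}

# Covariate effects for arbitrary recall days, using the coefficients a
# model estimated (names carry the factor level: dowweekend, modetelephone).
fixed_covariate_effects <- function(model, dow, mode) {
  eff <- numeric(length(dow))
  coefs <- model$covariate_effects
  if (!length(coefs)) return(eff)
  dlev <- as.character(dow_factor(dow, model$dow_scheme))
  for (nm in names(coefs)) {
    if (startsWith(nm, "dow")) {
      eff <- eff + coefs[[nm]] * (dlev == sub("^dow", "", nm))
    } else if (startsWith(nm, "mode")) {
      eff <- eff + coefs[[nm]] * (mode == sub("^mode", "", nm))
    }
  }
  eff
}

#' Compare UL exceedance between current and modeled intake
#'
#' Fits the usual-intake model on current person-day totals, evaluates the
#' modeled (fortified) totals under that same fit via
#' [project_usual_intake()], and tests the difference with a paired
#' two-sided t-test on the jackknife replicates.
#'
#' @param days_current,days_modeled person-day totals under the current and
#'   fortified scenarios (same persons and days; modeled totals must be >=
#'   current totals).
#' @inheritParams usual_intake_exceedance
#' @return list with `current` and `modeled` (`exceedance_estimate`s) and,
#'   when replicate weights are given, `comparison` (difference, SE, t, p).
#' @export
scenario_exceedance <- function(days_current, days_modeled, persons,
                                cutpoint, replicate_weights = NULL,
                                external_within_variance = NULL,
                                dow_scheme = "weekpart") {
  full <- fit_usual_intake(days_current, persons,
                           external_within_variance = external_within_variance,
                           dow_scheme = dow_scheme)
  est_c <- percent_above(full, cutpoint)
  est_m <- percent_above(project_usual_intake(full, days_modeled), cutpoint)
  out <- list(current = est_c, modeled = est_m, comparison = NULL)
  if (is.null(replicate_weights)) return(out)
  reps <- vapply(seq_len(ncol(replicate_weights)), function(r) {
    pr <- persons
    pr$weight <- replicate_weights[, r]
    m <- fit_usual_intake(days_current, pr,
                          external_within_variance = external_within_variance,
                          dow_scheme = dow_scheme, lambda = full$lambda)
    c(percent_above(m, cutpoint)$percent_above,
      percent_above(project_usual_intake(m, days_modeled),
                    cutpoint)$percent_above)
  }, numeric(2))
  fill <- function(est, r) {
    est$se <- jackknife_se(est$percent_above, r)
    est$ci95 <- pmin(100, pmax(0, est$percent_above +
                                 c(-1.96, 1.96) * est$se))
    est$replicate_estimates <- r
    est
  }
  out$current <- fill(est_c, reps[1, ])
  out$modeled <- fill(est_m, reps[2, ])
  out$comparison <- compare_scenarios(
    list(estimate = out$current$percent_above,
         replicates = out$current$replicate_estimates),
    list(estimate = out$modeled$percent_above,
         replicates = out$modeled$replicate_estimates))
  out
}

#' Exceedance with jackknife replicate-weight inference
#'
#' Fits the usual-intake model on the full analytic weights, then refits it
#' under each replicate-weight column (holding the transformation power fixed
#' at its full-sample value) to attach a delete-one-group jackknife standard
#' error and 95% confidence interval to the exceedance percentage.
#'
#' @inheritParams fit_usual_intake
#' @param cutpoint cut-point in ug/day.
#' @param replicate_weights optional matrix (rows aligned with `persons`) of
#'   replicate weights; when `NULL` only the point estimate is returned.
#' @return an `exceedance_estimate`, with `se`, `ci95` and the vector of
#'   `replicate_estimates` filled when replicate weights are given.
#' @export
usual_intake_exceedance <- function(person_days, persons, cutpoint,
                                    replicate_weights = NULL,
                                    external_within_variance = NULL,
                                    dow_scheme = "weekpart") {
  full <- fit_usual_intake(person_days, persons,
                           external_within_variance = external_within_variance,
                           dow_scheme = dow_scheme)
  est <- percent_above(full, cutpoint)
  if (is.null(replicate_weights)) return(est)
  reps <- vapply(seq_len(ncol(replicate_weights)), function(r) {
    pr <- persons
    pr$weight <- replicate_weights[, r]
    m <- fit_usual_intake(person_days, pr,
                          external_within_variance = external_within_variance,
                          dow_scheme = dow_scheme, lambda = full$lambda)
    percent_above(m, cutpoint)$percent_above
  }, numeric(1))
  est$se <- jackknife_se(est$percent_above, reps)
  est$ci95 <- pmin(100, pmax(0, est$percent_above +
                               c(-1.96, 1.96) * est$se))
  est$replicate_estimates <- reps
  est
}
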