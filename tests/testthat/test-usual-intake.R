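test_that("power transform and its inverse round-trip", {
  expect_equal(back_transform(list(lambda = 0, shift = 0), log(1000)), 1000)
  expect_equal(back_transform(list(lambda = 1, shift = 0), 41), 42)
  expect_equal(power_transform(42, 1), 41)  # lambda = 1 is a unit shift
  set.seed(21)
  for (i in 1:25) {
    lam <- stats::runif(1, -1, 1)
    shift <- sample(c(0, 5), 1)
    x <- stats::runif(10, 1, 2000)
    y <- power_transform(x, lam, shift)
    expect_equal(back_transform(list(lambda = lam, shift = shift), y), x,
                 tolerance = 1e-10)
  }
  expect_error(back_transform(list(lambda = 0.5, shift = 0), -5),
               "outside the range")
  expect_error(power_transform(-3, 0.5, 0), "> 0")
})

make_days <- function(values, ids = seq_along(values), dow = 3,
                      mode = "in-person", day = 1L) {
  data.frame(person_id = ids, total_fa_ug = values,
             day_of_week = dow, interview_mode = mode, day_index = day,
             stringsAsFactors = FALSE)
}

test_that("constant intake collapses to zero variances and usual = c", {
  days <- rbind(make_days(rep(300, 6), ids = 1:6, day = 1L),
                make_days(rep(300, 6), ids = 1:6, day = 2L))
  persons <- data.frame(person_id = 1:6, weight = 1)
  m <- fit_usual_intake(days, persons)
  expect_equal(m$sigma2_within, 0)
  expect_equal(m$sigma2_between, 0)
  expect_equal(m$persons$shrinkage, rep(1, 6))
  expect_equal(m$persons$usual_ug, rep(300, 6))
  expect_equal(percent_above(m, 1000)$percent_above, 0)
  expect_equal(percent_above(m, 100)$percent_above, 100)
})

test_that("external within-variance reproduces the internal two-day fit", {
  cd <- cohort_days(small_survey(500, seed = 12))
  m1 <- fit_usual_intake(cd$days, cd$persons)
  m2 <- fit_usual_intake(cd$days, cd$persons,
                         external_within_variance = m1$sigma2_within)
  expect_equal(m1$persons, m2$persons)
  expect_equal(m1$sigma2_between, m2$sigma2_between)
})

test_that("a fit with only one-day persons requires an external variance", {
  days <- make_days(c(100, 200, 400), ids = 1:3)
  persons <- data.frame(person_id = 1:3, weight = 1)
  expect_error(fit_usual_intake(days, persons), "external")
  m <- fit_usual_intake(days, persons, external_within_variance = 0.2)
  expect_equal(m$sigma2_within, 0.2)
  expect_true(all(m$persons$shrinkage > 0 & m$persons$shrinkage <= 1))
})

test_that("shrinkage never increases the spread of person means", {
  for (seed in c(13, 14)) {
    cd <- cohort_days(small_survey(500, seed = seed))
    m <- fit_usual_intake(cd$days, cd$persons)
    p <- m$persons
    expect_lte(stats::var(p$shrunk_transformed),
               stats::var(p$mean_transformed))
    expect_lte(stats::var(p$adjusted_transformed),
               stats::var(p$mean_transformed))
    expect_true(all(p$shrinkage > 0 & p$shrinkage <= 1))
  }
})

test_that("percent_above is a monotone survival function of the cut-point", {
  cd <- cohort_days(small_survey(600, seed = 15))
  m <- fit_usual_intake(cd$days, cd$persons)
  cuts <- c(100, 300, 600, 800, 1000, 1500, 3000)
  pct <- vapply(cuts, function(c) percent_above(m, c)$percent_above,
                numeric(1))
  expect_true(all(diff(pct) <= 0))
  expect_true(all(pct >= 0 & pct <= 100))
  expect_error(percent_above(m, 0), "cutpoint")
})

test_that("a symmetric distribution straddling the cut-point gives ~50%", {
  set.seed(30)
  vals <- 1000 * exp(stats::rnorm(4000, 0, 0.3))  # log-symmetric around 1000
  days <- rbind(make_days(vals, ids = 1:4000, day = 1L),
                make_days(vals * exp(stats::rnorm(4000, 0, 0.05)),
                          ids = 1:4000, day = 2L))
  persons <- data.frame(person_id = 1:4000, weight = 1)
  m <- fit_usual_intake(days, persons)
  est <- percent_above(m, 1000)$percent_above
  expect_lt(abs(est - 50), 3)
})

test_that("day-of-week and interview-mode effects are removed", {
  # plant a pure weekend bump; adjusted within-variance should not inflate
  set.seed(31)
  n <- 3000
  mu <- stats::rnorm(n, 5.3, 0.5)
  dow1 <- sample(1:7, n, replace = TRUE)
  dow2 <- sample(1:7, n, replace = TRUE)
  bump <- function(d) ifelse(d %in% c(1, 7), log(1.25), 0)
  v1 <- exp(mu + stats::rnorm(n, 0, 0.3) + bump(dow1))
  v2 <- exp(mu + stats::rnorm(n, 0, 0.3) + bump(dow2))
  days <- rbind(
    make_days(v1, ids = 1:n, dow = dow1, day = 1L),
    make_days(v2, ids = 1:n, dow = dow2, mode = "telephone", day = 2L))
  persons <- data.frame(person_id = 1:n, weight = 1)
  m <- fit_usual_intake(days, persons)
  expect_equal(m$lambda, 0)
  # weekend coefficient on the log scale recovers the planted +25%
  expect_lt(abs(m$covariate_effects[["dowweekend"]] - log(1.25)), 0.03)
  expect_lt(abs(m$sigma2_within - 0.09), 0.01)
  expect_lt(abs(m$sigma2_between - 0.25), 0.025)
})

test_that("the tail-instability guard flags thin tails as not estimable", {
  cd <- cohort_days(small_survey(600, seed = 16))
  m <- fit_usual_intake(cd$days, cd$persons)
  p <- sort(m$persons$usual_ug, decreasing = TRUE)
  cut_thin <- (p[3] + p[4]) / 2    # exactly 3 persons beyond
  est <- percent_above(m, cut_thin)
  expect_true(est$ne)
  expect_equal(est$n_beyond, 3)
  cut_zero <- max(p) + 1
  expect_false(percent_above(m, cut_zero)$ne)
  expect_equal(percent_above(m, cut_zero)$percent_above, 0)
})

test_that("replicate-weight exceedance attaches a finite SE and clipped CI", {
  cd <- cohort_days(small_survey(500, seed = 17), adults_only = TRUE)
  est <- usual_intake_exceedance(cd$days, cd$persons, 1000,
                                 replicate_weights = cd$repw)
  expect_true(is.finite(est$se))
  expect_length(est$replicate_estimates, ncol(cd$repw))
  expect_true(est$ci95[1] >= 0 && est$ci95[2] <= 100)
  expect_true(est$ci95[1] <= est$percent_above &&
                est$percent_above <= est$ci95[2])
})

test_that("model summaries serialize to JSON", {
  cd <- cohort_days(small_survey(400, seed = 18))
  m <- fit_usual_intake(cd$days, cd$persons)
  j <- jsonlite::fromJSON(model_json(m))
  expect_equal(j$lambda, m$lambda)
  expect_equal(j$sigma2_within, m$sigma2_within)
})

test_that("projecting the fitted model onto the same days is a no-op", {
  cd <- cohort_days(small_survey(500, seed = 13),
                    fortification_scenario(0), adults_only = TRUE)
  m <- fit_usual_intake(cd$days, cd$persons)
  expect_identical(project_usual_intake(m, cd$days)$persons, m$persons)
})

test_that("scenario projection is monotone person by person", {
  s <- small_survey(500, seed = 13)
  sc <- fortification_scenario(300)
  cd_cur <- cohort_days(s, fortification_scenario(0, sc$food_codes),
                        adults_only = TRUE)
  cd_mod <- cohort_days(s, sc, adults_only = TRUE)
  m <- fit_usual_intake(cd_cur$days, cd_cur$persons)
  p <- project_usual_intake(m, cd_mod$days)
  expect_true(all(p$persons$usual_ug >= m$persons$usual_ug))
  sx <- scenario_exceedance(cd_cur$days, cd_mod$days, cd_cur$persons,
                            1000, replicate_weights = cd_cur$repw)
  expect_gte(sx$modeled$percent_above, sx$current$percent_above)
  # monotone within every jackknife replicate as well
  expect_true(all(sx$modeled$replicate_estimates >=
                    sx$current$replicate_estimates))
  expect_equal(sx$comparison$difference,
               sx$modeled$percent_above - sx$current$percent_above)
})
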