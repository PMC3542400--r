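test_that("configuration errors name the offending field", {
  expect_error(generator_config(frac_one_day = 1.5), "frac_one_day")
  expect_error(generator_config(sigma_between = 0), "sigma_between")
  expect_error(generator_config(sigma_within = -1), "sigma_within")
  expect_error(generator_config(n_replicates = 1), "n_replicates")
  expect_error(generator_config(supplement_user_prob = 2),
               "supplement_user_prob")
  expect_error(
    generator_config(supplement_dose_dist = list(values = 400,
                                                 probs = c(0.5, 0.5))),
    "supplement_dose_dist")
})

test_that("frac_one_day = 0 gives every person exactly two recall days", {
  s <- generate_survey(generator_config(n_persons = 200, frac_one_day = 0,
                                        n_replicates = 8, seed = 2))
  days <- unique(s$recalls[c("person_id", "day_index")])
  expect_equal(as.integer(table(days$person_id)), rep(2L, 200))
})

test_that("degenerate within-person variance makes both day totals equal", {
  s <- generate_survey(generator_config(n_persons = 150, frac_one_day = 0,
                                        sigma_within = 1e-9,
                                        weekend_bump = 0,
                                        n_replicates = 8, seed = 4))
  pd <- apply_scenario(s$recalls, fortification_scenario(0))
  d1 <- pd$food_fa_ug[pd$day_index == 1]
  d2 <- pd$food_fa_ug[pd$day_index == 2]
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("observed supplement-user fraction matches the configured rate", {
  p <- 0.34
  s <- generate_survey(generator_config(n_persons = 5000,
                                        supplement_user_prob = p,
                                        missing_supp_prob = 0,
                                        n_replicates = 8, seed = 1))
  f <- flag_supplement_user(s$supplements,
                            person_ids = s$demographics$person_id)
  se <- sqrt(p * (1 - p) / 5000)
  expect_lt(abs(mean(f) - p), 3 * se)
})

test_that("identical seed and config give identical tables; new seed differs", {
  cfg <- generator_config(n_persons = 250, n_replicates = 8, seed = 42)
  a <- generate_survey(cfg)
  b <- generate_survey(cfg)
  expect_identical(a$demographics, b$demographics)
  expect_identical(a$recalls, b$recalls)
  expect_identical(a$supplements, b$supplements)
  expect_identical(a$truth, b$truth)
  d <- generate_survey(generator_config(n_persons = 250, n_replicates = 8,
                                        seed = 43))
  expect_false(identical(a$recalls, d$recalls))
  # written files are byte-identical too
  t1 <- file.path(tempdir(), "svy_a"); t2 <- file.path(tempdir(), "svy_b")
  write_survey(a, t1); write_survey(b, t2)
  for (f in c("demographics.csv", "recalls.csv", "supplements.csv",
              "truth.json"))
    expect_identical(readLines(file.path(t1, f)),
                     readLines(file.path(t2, f)))
})

test_that("generated recalls reproduce the configured variance components", {
  sb <- 0.5; sw <- 0.6
  s <- generate_survey(generator_config(n_persons = 5000,
                                        sigma_between = sb,
                                        sigma_within = sw,
                                        n_replicates = 8, seed = 6))
  pd <- apply_scenario(s$recalls, fortification_scenario(0))
  z <- log(pd$food_fa_ug) -
    ifelse(pd$day_of_week %in% c(1, 7), log1p(0.10), 0)
  d_i <- table(pd$person_id)
  two <- names(d_i[d_i == 2])
  z1 <- tapply(z, pd$person_id, function(v) v[1])[two]
  z2 <- tapply(z, pd$person_id, function(v) v[length(v)])[two]
  s2w_hat <- 0.5 * mean((z1 - z2)^2)
  n2 <- length(two)
  expect_lt(abs(s2w_hat - sw^2), 3 * sw^2 * sqrt(2 / n2))
  zbar <- tapply(z, pd$person_id, mean)
  s2b_hat <- stats::var(zbar) - s2w_hat * mean(1 / as.numeric(d_i))
  se_b <- sqrt(2 / length(zbar)) * (sb^2 + sw^2 / 2)
  expect_lt(abs(s2b_hat - sb^2), 3 * se_b)
})

test_that("truth exceedance matches direct integration of the generating model", {
  cfg <- generator_config(n_persons = 50000, n_replicates = 8, seed = 8)
  s <- generate_survey(cfg)
  tr <- s$truth$exceedance

  # Independent oracle: integrate the generating distributions directly.
  # Usual food intake is lognormal with log mean mu + sigma_w^2/2; the
  # supplement amount is a finite mixture (user, dose, days taken, second
  # product); the fortified addition integrates over the lognormal
  # non-wholegrain grams, mixed over the race strata (which carry different
  # weights and corn-masa probabilities).
  m <- cfg$mu_log_food_fa + cfg$sigma_within^2 / 2
  p_food <- function(t) ifelse(t <= 0, 1,
                               1 - stats::pnorm((log(pmax(t, 1e-300)) - m) /
                                                  cfg$sigma_between))
  # supplement states
  pu <- (1 - cfg$missing_supp_prob) * cfg$supplement_user_prob
  st <- expand.grid(dose = cfg$supplement_dose_dist$values,
                    days = c(30, 15, 7), extra = c(0, 100 * 10 / 30))
  st$p <- pu *
    cfg$supplement_dose_dist$probs[match(st$dose,
                                         cfg$supplement_dose_dist$values)] *
    c(`30` = 0.7, `15` = 0.2, `7` = 0.1)[as.character(st$days)] *
    ifelse(st$extra > 0, 0.15, 0.85)
  st <- rbind(data.frame(dose = 0, days = 0, extra = 0, p = 1 - pu), st)
  st$s_amt <- st$dose * st$days / 30 + st$extra

  p_current <- function(cut) sum(st$p * p_food(cut - st$s_amt))
  p_masa_tail <- function(cut) {
    sum(st$p * vapply(st$s_amt, function(s_amt) {
      stats::integrate(function(a)
        stats::dlnorm(a, cfg$nonwholegrain_meanlog,
                      cfg$nonwholegrain_sdlog) *
          p_food(cut - s_amt - a * 140 / 100),
        0, Inf, rel.tol = 1e-8)$value
    }, numeric(1)))
  }
  wf <- cfg$race_probs * cfg$race_weight_factors
  p_race_masa <- cfg$corn_masa_consumer_prob_by_stratum[cfg$race_levels]
  p_fortified <- function(cut) {
    sum(wf * (p_race_masa * p_masa_tail(cut) +
                (1 - p_race_masa) * p_current(cut))) / sum(wf)
  }

  for (i in seq_len(nrow(tr))) {
    cut <- tr$cutpoint_ug[i]
    # per-group sampling tolerance: the drawn cohort deviates from the
    # population integral by a weighted binomial error
    pc <- p_current(cut)
    se <- sqrt(2 * pc * (1 - pc) / tr$n[i])  # deff ~ 2 for these weights
    tol <- max(0.005, 3 * se)
    expect_lt(abs(tr$current_frac[i] - pc), tol)
    expect_lt(abs(tr$fortified_frac[i] - p_fortified(cut)), tol)
  }
  # the adult stratum is large enough to pin the integral tightly
  ad <- tr[tr$age_group == ">=19", ]
  expect_lt(abs(ad$current_frac - p_current(1000)), 0.005)
  expect_lt(abs(ad$fortified_frac - p_fortified(1000)), 0.005)
  # truth invariant: fortification can only raise the exceedance
  expect_true(all(tr$fortified_frac >= tr$current_frac))
  expect_true(all(tr$current_frac >= 0 & tr$fortified_frac <= 1))
})

test_that("replicate weights delete one group and conserve the weight total", {
  rw <- generate_replicate_weights(rep(1, 4), 2, seed = 1)
  expect_equal(dim(rw), c(4, 2))
  expect_equal(colSums(rw), c(4, 4))
  expect_equal(sort(rw[, 1]), c(0, 0, 2, 2))
  expect_equal(sort(rw[, 2]), c(0, 0, 2, 2))
  # each person deleted in exactly one replicate
  expect_equal(rowSums(rw == 0), rep(1, 4))

  w <- stats::rlnorm(200, 0, 0.4)
  rw <- generate_replicate_weights(w, 25, seed = 2)
  expect_equal(colSums(rw), rep(sum(w), 25))
  expect_error(generate_replicate_weights(w, 300), "exceeds")
  expect_error(generate_replicate_weights(c(1, -1), 2), "positive")
})

test_that("replicate means average back to the full-sample mean", {
  set.seed(10)
  n <- 2000
  w <- stats::rlnorm(n, 0, 0.4)
  x <- stats::rnorm(n, 5, 2)
  rw <- generate_replicate_weights(w, 50, seed = 3)
  full <- sum(w * x) / sum(w)
  reps <- apply(rw, 2, function(wr) sum(wr * x) / sum(wr))
  expect_lt(abs(mean(reps) - full), 0.01)
})
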