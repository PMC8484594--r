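test_that("balance report enumerates covariates and flags constants", {
  sim <- tiny_study(n = 120, seed = 141)
  d <- sim$data
  d$constant_cov <- 7
  expect_warning(
    rep <- balance_test(d, c("trust_china", "education_high",
                             "constant_cov")),
    "constant")
  expect_s3_class(rep, "diagnostic_report")
  expect_identical(rep$skipped, "constant_cov")
  # every covariate x treatment-term pair tested
  expect_equal(nrow(rep$tests), 2 * 19)
  expect_true(all(rep$tests$p_value >= 0 & rep$tests$p_value <= 1))
  expect_equal(nrow(rep$joint), 2)
  expect_error(balance_test(d, "absent_cov"), "absent_cov")
})

test_that("planted assignment imbalance is detected", {
  sim <- simulate_conjoint(n = 700, countries = c("Brazil", "Chile"),
                           seed = 142, effects = true_effects("null"))
  d <- sim$data
  # tilt: low-trust-in-China respondents are more often shown Sinovac
  pop <- sim$population
  low <- pop$respondent_id[pop$trust_china <= 2]
  flip <- d$respondent_id %in% low &
    d$producer %in% c("pfizer", "astrazeneca", "gamaleya")
  d$producer[flip] <- "sinovac"
  d$efficacy_value[flip & d$efficacy_shown == "yes"] <- 50
  rep <- balance_test(d, "trust_china")
  p_sino <- rep$tests$p_value[rep$tests$term == "producer_sinovac"]
  expect_lt(p_sino, 0.01)
  expect_lt(rep$joint$p_value, 0.01)
})

test_that("attrition test is vacuous without attrition", {
  sim <- tiny_study(n = 60, seed = 143)
  rep <- attrition_test(sim$data)
  expect_true(rep$vacuous)
  expect_match(rep$note, "vacuous")
  expect_error(attrition_test(sim$data[sim$data$round == 1, ]), "rounds")
})

test_that("attrition triggered by Sinovac exposure is detected", {
  eff <- true_effects("attrition")
  eff$attrition$sinovac <- 0.25
  sim <- simulate_conjoint(n = 900, countries = c("Mexico", "Peru"),
                           seed = 144, effects = eff)
  rep <- attrition_test(sim$data)
  expect_false(rep$vacuous)
  expect_gt(rep$dropout_rate, 0.02)
  p_sino <- rep$tests$p_value[rep$tests$term == "producer_sinovac"]
  expect_lt(p_sino, 0.01)
})

test_that("restriction to round 1 is exact when only round 1 exists", {
  sim <- tiny_study(n = 80, seed = 145)
  d1 <- sim$data[sim$data$round == 1, ]
  d1$ipw <- d1$ipw / mean(d1$ipw)
  direct <- fit_amce(d1, fe = "cell", ypre = "ypre_willing")
  wrapped <- first_round_robustness(sim$data)
  expect_equal(tidy_fit(wrapped)$estimate, tidy_fit(direct)$estimate,
               tolerance = 1e-10)
  expect_true(wrapped$meta$first_round_only)
})

test_that("planted carryover separates pooled and first-round estimates", {
  n <- 2000
  seed <- 146
  # the Sinovac effect shifts by +0.5 once a respondent has already seen a
  # Sinovac scenario; with history-dependent effects the pooled
  # within-respondent estimate no longer matches the uncontaminated
  # round-1 estimate, which is exactly what the first-round check screens
  sim_co <- suppressWarnings(
    simulate_conjoint(n = n, seed = seed,
                      effects = true_effects("carryover", carryover = 0.5)))
  pooled <- tidy_fit(fit_amce(sim_co$data))
  r1 <- tidy_fit(first_round_robustness(sim_co$data))
  gap <- pooled$estimate[pooled$term == "producer_sinovac"] -
    r1$estimate[r1$term == "producer_sinovac"]
  expect_gt(abs(gap), 0.05)
  # no carryover: same comparison stays within sampling error
  sim_ok <- simulate_conjoint(n = n, seed = seed,
                              effects = true_effects("paper"))
  pooled0 <- tidy_fit(fit_amce(sim_ok$data))
  r10 <- tidy_fit(first_round_robustness(sim_ok$data))
  gap0 <- pooled0$estimate[pooled0$term == "producer_sinovac"] -
    r10$estimate[r10$term == "producer_sinovac"]
  expect_lt(abs(gap0), 0.05)
})

test_that("diagnostics do not mutate the dataset", {
  sim <- tiny_study(n = 50, seed = 147)
  d <- sim$data
  before <- d
  invisible(balance_test(d, "trust_usa"))
  invisible(attrition_test(d))
  invisible(first_round_robustness(d))
  expect_identical(d, before)
})
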