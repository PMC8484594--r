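test_that("population generation is deterministic and configurable", {
  p1 <- generate_population(600, seed = 8)
  p2 <- generate_population(600, seed = 8)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 600 * 6)
  # Evangelical share ~25% in Brazil, lower elsewhere
  br <- p1[p1$country == "Brazil", ]
  expect_lt(abs(mean(br$religion == "evangelical") - 0.25), 0.05)
  ar <- p1[p1$country == "Argentina", ]
  expect_lt(abs(mean(ar$religion == "evangelical") - 0.15), 0.05)
  # trust scores live on the 1-4 scale
  expect_true(all(p1$trust_usa %in% 1:4))
  # degenerate trust distribution: point mass at 4
  p4 <- generate_population(50, countries = "Chile", seed = 9,
                            trust_probs = c(0, 0, 0, 1))
  expect_true(all(p4$trust_china == 4))
  expect_error(generate_population(0), "n_per_country")
  expect_error(generate_population(10, trust_probs = c(1, 1)),
               "trust_probs")
})

test_that("screening removes acceptant, minor, inattentive, fast cases", {
  pop <- generate_population(400, countries = c("Brazil", "Mexico"),
                             seed = 10)
  # plant the three canonical exclusion cases
  pop$prior_willingness[1] <- 5; pop$prior_wait[1] <- 1       # acceptant
  pop$age[2] <- 17                                            # minor
  pop$prior_willingness[2] <- 1; pop$prior_wait[2] <- 12
  pop$duration_min[3] <- 9                                    # speeder
  pop$prior_willingness[3] <- 1; pop$prior_wait[3] <- 12
  pop$age[3] <- 30; pop$attention_pass[3] <- TRUE
  scr <- apply_screening(pop)
  ret <- scr$retained
  expect_false(pop$respondent_id[1] %in% ret$respondent_id)
  expect_false(pop$respondent_id[2] %in% ret$respondent_id)
  expect_false(pop$respondent_id[3] %in% ret$respondent_id)
  # no retained respondent is acceptant
  expect_false(any(ret$prior_willingness >= 4 & ret$prior_wait <= 2))
  expect_true(all(ret$age >= 18))
  expect_true(all(ret$duration_min >= 10))
  # tally conservation: retained + excluded = input
  expect_equal(nrow(ret) + sum(scr$tally$excluded), nrow(pop))
  # roughly the study's acceptant share is screened out
  expect_equal(scr$tally$excluded[1] / nrow(pop), 0.41, tolerance = 0.06)
})

test_that("the null DGP centers willingness on one half", {
  sim <- simulate_conjoint(n = 400, countries = c("Brazil", "Peru"),
                           seed = 11, effects = true_effects("null"))
  expect_equal(mean(sim$data$y_willing), 0.5, tolerance = 0.03)
})

test_that("simulated studies are reproducible and internally consistent", {
  s1 <- tiny_study(n = 60, seed = 12)
  s2 <- tiny_study(n = 60, seed = 12)
  expect_identical(s1$data, s2$data)
  d <- s1$data
  expect_equal(nrow(d), 60 * 2 * 5)
  expect_setequal(unique(d$round), 1:5)
  expect_true(all(table(d$respondent_id) == 5))
})

test_that("months and willingness are negatively associated", {
  sim <- simulate_conjoint(n = 800, seed = 13)
  d <- sim$data
  rho <- suppressWarnings(
    cor(d$willing, d$months, method = "spearman"))
  expect_lt(rho, -0.1)
  # reversed outcome flips the sign
  expect_gt(suppressWarnings(
    cor(d$y_willing, d$y_months, method = "spearman")), 0.1)
  expect_true(all(d$months >= 0 & d$months <= 12))
  expect_true(all(d[, mechanism_outcomes()] >= 1 &
                    d[, mechanism_outcomes()] <= 5))
})

test_that("probability clipping warns and escalates to an error", {
  pop <- make_blocks(generate_population(40, countries = "Chile",
                                         seed = 14, hesitant_only = TRUE))
  asg <- assign_scenarios(pop, seed = 15)
  warn_eff <- true_effects("null", sigma_re = 0.6, clip_error_share = 1)
  expect_warning(generate_responses(pop, asg, warn_eff, seed = 16),
                 "clipping")
  err_eff <- true_effects("null", p0 = 1.5)
  expect_error(generate_responses(pop, asg, err_eff, seed = 16),
               "clipping")
})

test_that("paper preset stores the published effects as ground truth", {
  tt <- true_amce_table(true_effects("paper"))
  expect_equal(tt$true_value[tt$term == "producer_sinovac"], -0.11)
  expect_equal(tt$true_value[tt$term == "producer_gamaleya_x_efficacy"],
               0.076)
  expect_equal(tt$true_value[tt$term == "uptake_75"], 0.053)
  expect_equal(nrow(tt), 19)
  # null preset zeroes everything
  expect_true(all(true_amce_table(true_effects("null"))$true_value == 0))
})
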