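make_resp <- function(n, seed = 3, countries = c("Brazil", "Mexico")) {
  pop <- generate_population(ceiling(n / length(countries)), countries,
                             seed = seed, hesitant_only = TRUE)
  make_blocks(pop[seq_len(n), , drop = FALSE])
}

test_that("assignment is deterministic under a fixed seed", {
  resp <- make_resp(80)
  a1 <- assign_scenarios(resp, seed = 11)
  a2 <- assign_scenarios(resp, seed = 11)
  expect_identical(a1, a2)
  # and stable under input row order
  a3 <- assign_scenarios(resp[rev(seq_len(nrow(resp))), ], seed = 11)
  expect_identical(a1, a3[order(a3$respondent_id, a3$round), ] |>
                     `rownames<-`(NULL))
  a4 <- assign_scenarios(resp, seed = 12)
  expect_false(identical(a1$producer, a4$producer))
})

test_that("level frequencies match the design probabilities", {
  resp <- make_resp(3000, countries = "Chile")
  asg <- assign_scenarios(resp, n_rounds = 2L, seed = 5)
  r2 <- asg[asg$round == 2, ]
  # round 2: four specified producers, uniform
  tab2 <- table(r2$producer)
  expect_setequal(names(tab2), c("pfizer", "astrazeneca", "gamaleya",
                                 "sinovac"))
  expect_gt(chisq.test(tab2)$p.value, 0.001)
  expect_equal(as.numeric(tab2 / sum(tab2)), rep(0.25, 4),
               tolerance = 0.05)
  # round 1: all 5 uptake levels, uniform
  r1 <- asg[asg$round == 1, ]
  tab1 <- table(r1$uptake)
  expect_length(tab1, 5)
  expect_gt(chisq.test(tab1)$p.value, 0.001)
})

test_that("unspecified levels never appear after round 1", {
  sim <- tiny_study(n = 150, seed = 9)
  later <- sim$data[sim$data$round > 1, ]
  expect_false(any(later$producer == "unspecified"))
  expect_false(any(later$uptake == "unspecified"))
  expect_false(any(later$efficacy_shown == "unspecified"))
})

test_that("dimensions are assigned independently", {
  resp <- make_resp(4000, countries = "Peru")
  asg <- assign_scenarios(resp, n_rounds = 2L, seed = 21)
  r2 <- asg[asg$round == 2, ]
  expect_gt(chisq.test(table(r2$producer, r2$endorser))$p.value, 0.001)
  expect_gt(chisq.test(table(r2$distributor, r2$uptake))$p.value, 0.001)
})

test_that("efficacy disclosure is coupled to a specified producer", {
  sim <- tiny_study(n = 200, seed = 13)
  d <- sim$data
  un <- d$producer == "unspecified"
  expect_true(all(d$efficacy_shown[un] == "unspecified"))
  shown <- d$efficacy_shown == "yes"
  expect_true(all(!is.na(d$efficacy_value[shown])))
  expect_true(all(is.na(d$efficacy_value[!shown])))
  cat5 <- build_catalog()
  expect_equal(unname(d$efficacy_value[shown]),
               unname(cat5$producer$efficacy_map[d$producer[shown]]))
})

test_that("religious-leader display maps to the co-religious endorser", {
  resp <- make_resp(600)
  asg <- assign_scenarios(resp, seed = 2)
  asg$religion <- resp$religion[match(asg$respondent_id,
                                      resp$respondent_id)]
  rel <- asg$endorser == "religious_leader"
  expect_true(all(asg$endorser_displayed[rel & asg$religion == "evangelical"]
                  == "evangelical_organization"))
  expect_true(all(asg$endorser_displayed[rel & asg$religion != "evangelical"]
                  == "catholic_archbishop"))
  expect_identical(asg$endorser_displayed[!rel], asg$endorser[!rel])
  # the display mapping does not disturb the level's probability
  expect_equal(mean(rel), 1 / 6, tolerance = 0.03)
})

test_that("degenerate inputs error clearly", {
  resp <- make_resp(10)
  expect_error(assign_scenarios(resp, n_rounds = 0), "n_rounds")
  expect_error(assign_scenarios(resp[0, ]), "empty")
  expect_error(assign_scenarios(resp[, c("respondent_id", "country")]),
               "block_id")
})

test_that("vignette text follows the bracketed template", {
  cat5 <- build_catalog()
  resp <- list(country = "Colombia", religion = "catholic")
  prof <- list(round = 1L, producer = "pfizer", efficacy_shown = "yes",
               efficacy_value = 95, endorser = "president",
               distributor = "military", uptake = "75")
  txt <- render_vignette(prof, resp, cat5)
  expect_match(txt, "95% of COVID-19 infections")
  expect_match(txt, "75% of people in your community")
  expect_match(txt, "Pfizer")
  expect_match(txt, "free of charge for everyone")
  # pure-control profile: no producer clause, no efficacy sentence,
  # no uptake clause
  prof0 <- list(round = 1L, producer = "unspecified",
                efficacy_shown = "unspecified", efficacy_value = NA,
                endorser = "medical_association",
                distributor = "healthcare_system", uptake = "unspecified")
  txt0 <- render_vignette(prof0, resp, cat5)
  expect_no_match(txt0, "produced by")
  expect_no_match(txt0, "prevents")
  expect_no_match(txt0, "already been vaccinated")
  # religious leader renders as the respondent's co-religious organization
  profr <- within(as.list(prof0), endorser <- "religious_leader")
  profr$endorser_displayed <- "evangelical_organization"
  expect_match(render_vignette(profr, resp, cat5), "Evangelical")
  # missing display label errors
  cfg <- default_catalog_config()
  cfg$distributor$display <- cfg$distributor$display[-2]
  expect_error(render_vignette(prof, resp, build_catalog(cfg)),
               "display label")
})
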