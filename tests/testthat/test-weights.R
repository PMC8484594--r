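test_that("round-1 profile probabilities enumerate to one", {
  cat5 <- build_catalog()
  for (r in 1:2) {
    g <- enumerate_profiles(cat5, r)
    p <- assignment_probability(g, cat5)
    expect_true(all(p > 0 & p <= 1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("a specified profile is more probable after round 1", {
  cat5 <- build_catalog()
  prof <- data.frame(producer = "pfizer", efficacy_shown = "yes",
                     endorser = "mayor", distributor = "military",
                     uptake = "50", round = 1L,
                     stringsAsFactors = FALSE)
  p1 <- assignment_probability(prof, cat5)
  prof$round <- 2L
  p2 <- assignment_probability(prof, cat5)
  expect_gt(p2, p1)
  # hand-enumerated products: round 1 = 1/5 * 1/2 * 1/6 * 1/3 * 1/5,
  # round 2 = 1/4 * 1 * 1/6 * 1/3 * 1/4
  expect_equal(p1, 1 / 900, tolerance = 1e-12)
  expect_equal(p2, 1 / 288, tolerance = 1e-12)
  # pure-control round-1 profile: no efficacy factor (forced)
  ctrl <- data.frame(producer = "unspecified",
                     efficacy_shown = "unspecified", endorser = "mayor",
                     distributor = "military", uptake = "unspecified",
                     round = 1L, stringsAsFactors = FALSE)
  expect_equal(assignment_probability(ctrl, cat5), 1 / 450,
               tolerance = 1e-12)
})

test_that("constraint violations are rejected with the offending row", {
  cat5 <- build_catalog()
  prof <- data.frame(producer = "unspecified",
                     efficacy_shown = "unspecified", endorser = "mayor",
                     distributor = "military", uptake = "50", round = 2L,
                     stringsAsFactors = FALSE)
  expect_error(assignment_probability(prof, cat5), "round-1 only")
})

test_that("single-level dimensions contribute probability factor 1", {
  cat3 <- producer_only_catalog()
  d <- producer_only_data(20)
  p <- assignment_probability(d, cat3)
  expect_equal(p, rep(1 / 3, 20))
  # without round constraints all weights are 1 after normalization
  d5 <- rbind(d, transform(d, round = 2L))
  w <- compute_ipw(d5, cat3)
  expect_equal(w$ipw, rep(1, nrow(d5)))
})

test_that("weights invert enumerated probability ratios and average to 1", {
  sim <- tiny_study(n = 120, seed = 31)
  d <- sim$data
  expect_equal(mean(d$ipw), 1, tolerance = 1e-12)
  expect_true(all(d$ipw > 0))
  # two identical specified profiles in rounds 1 and 2 have weight ratio
  # equal to the inverse probability ratio (900 / 288)
  cat5 <- build_catalog()
  i1 <- which(d$round == 1 & d$producer == "pfizer" &
                d$efficacy_shown == "yes")[1]
  match2 <- which(d$round == 2 &
                    d$producer == d$producer[i1] &
                    d$endorser == d$endorser[i1] &
                    d$distributor == d$distributor[i1] &
                    d$uptake == d$uptake[i1])[1]
  skip_if(is.na(i1) || is.na(match2), "fixture lacks a matching pair")
  expect_equal(d$ipw[i1] / d$ipw[match2], 900 / 288, tolerance = 1e-12)
})

test_that("reweighting restores the round-1 design composition", {
  sim <- tiny_study(n = 2000, seed = 77, effects = true_effects("null"))
  d <- sim$data
  r1 <- d[d$round == 1, ]
  cells <- interaction(r1$producer, r1$efficacy_shown, drop = TRUE)
  # 9 valid producer x efficacy cells in round 1; the weighted mass is
  # uniform over them, the raw mass gives the forced pure-control cell
  # twice the share
  expect_length(levels(cells), 9)
  wmass <- tapply(r1$ipw, cells, sum)
  wcounts <- wmass / sum(wmass) * nrow(r1)
  expect_gt(chisq.test(wcounts, p = rep(1 / 9, 9))$p.value, 0.01)
  raw <- table(cells)
  un <- grepl("^unspecified", names(raw))
  expect_gt(sum(raw[un]) / mean(raw[!un]), 1.6)  # ~2x before weighting
})

test_that("empirical frequencies track the analytic design probabilities", {
  sim <- tiny_study(n = 1500, seed = 19, effects = true_effects("null"))
  fr <- empirical_assignment_freq(sim$data)
  expect_true(all(abs(fr$freq - fr$design_prob) < 0.05))
  # the marginal probability of disclosure in round 1 reflects the
  # producer coupling: 4/5 * 1/2
  e1 <- fr[fr$dimension == "efficacy_shown" & fr$round == 1 &
             fr$level == "yes", ]
  expect_equal(e1$design_prob, 0.4, tolerance = 1e-12)
})
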