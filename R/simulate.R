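#' Ground-truth effect presets for the synthetic data generator
#'
#' A `true_effects` object fully specifies the potential-outcomes model of
#' the simulator: baseline willingness among pure-control scenarios, the
#' AMCE of every non-baseline level on the probability scale, per-unit
#' trust moderator slopes, the respondent random-effect SD, the
#' months-to-wait model, mechanism-item parameters, and optional carryover
#' and attrition processes.
#'
#' @details
#' Presets:
#' * `"paper"`: level effects set to the published study's point estimates
#'   (e.g. Sinovac -0.11, Gamaleya-with-efficacy +0.076, 75% uptake
#'   +0.053, presidential endorsement -0.037, civil-society distribution
#'   -0.021, military -0.017), baseline willingness 0.52, with moderate
#'   trust moderation. Values the study does not print (uptake 25%,
#'   AstraZeneca and Sinovac efficacy-disclosure interactions, the trust
#'   slopes) are filled with plausible magnitudes consistent with its
#'   qualitative statements.
#' * `"null"`: every effect and slope zero, baseline 0.5 -- for coverage
#'   and type-I-error studies.
#' * `"carryover"`: the paper preset plus a planted stability (SUTVA)
#'   violation -- the Sinovac effect is shifted by `carryover` once a
#'   respondent has already seen a Sinovac scenario.
#' * `"attrition"`: the paper preset plus dropout after each round with a
#'   base rate and an extra Sinovac-exposure rate.
#'
#' Trust slopes multiply the deviation of the respondent's 1-4 trust score
#' from its population mean, so the level effects are exactly the
#' population-average AMCEs (the recovery target).
#'
#' @param preset One of `"paper"`, `"null"`, `"carryover"`, `"attrition"`.
#' @param ... Named overrides of any field.
#' @return A `true_effects` list.
#' @export
true_effects <- function(preset = c("paper", "null", "carryover",
                                    "attrition"), ...) {
  preset <- match.arg(preset)
  paper_amce <- list(
    producer = c(pfizer = 0.025, astrazeneca = 0.021, gamaleya = -0.054,
                 sinovac = -0.11),
    producer_x_efficacy = c(pfizer = 0.059, astrazeneca = -0.010,
                            gamaleya = 0.076, sinovac = -0.040),
    endorser = c(president = -0.037, mayor = -0.037,
                 religious_leader = -0.064, left_newspaper = -0.060,
                 right_newspaper = -0.068),
    distributor = c(military = -0.017, civil_society = -0.021),
    uptake = c(`1` = -0.027, `25` = 0.005, `50` = 0.031, `75` = 0.053)
  )
  zero_amce <- lapply(paper_amce, function(v) v * 0)
  eff <- list(
    p0 = 0.52,
    amce = paper_amce,
    slopes = c(producer = 0.06, endorser = 0.03, distributor = 0.02),
    sigma_re = 0.15,
    months = list(base_wait = 5, scale = 6, cap = 12),
    mech = list(base = 3, scale = 1.5, sd = 0.8, min = 1, max = 5),
    clip = c(0.01, 0.99),
    clip_warn_share = 0.02,
    clip_error_share = 0.10,
    carryover = 0,
    attrition = list(rate = 0, sinovac = 0)
  )
  if (preset == "null") {
    eff$p0 <- 0.5
    eff$amce <- zero_amce
    eff$slopes <- c(producer = 0, endorser = 0, distributor = 0)
  } else if (preset == "carryover") {
    eff$carryover <- 0.15
  } else if (preset == "attrition") {
    eff$attrition <- list(rate = 0.05, sinovac = 0.10)
  }
  over <- list(...)
  for (nm in names(over)) eff[[nm]] <- over[[nm]]
  structure(eff, class = "true_effects")
}

#' Ground-truth AMCE table for recovery testing
#'
#' @param effects A [true_effects()] object.
#' @param catalog The matching [attribute_catalog][build_catalog].
#' @return data.frame `term`, `true_value` in [catalog_terms()] order.
#' @export
true_amce_table <- function(effects, catalog = build_catalog()) {
  terms <- catalog_terms(catalog)
  val <- numeric(nrow(terms))
  for (k in seq_len(nrow(terms))) {
    v <- effects$amce[[terms$dimension[k]]]
    if (!is.null(v) && terms$level[k] %in% names(v)) {
      val[k] <- v[[terms$level[k]]]
    }
  }
  data.frame(term = terms$term, true_value = val, stringsAsFactors = FALSE)
}

#' Screening rules
#'
#' @param accept_levels 5-point prior-willingness responses counted as
#'   acceptance (default 4:5, agree / strongly agree).
#' @param max_accept_wait Maximum intended wait, in months, for an
#'   acceptant respondent (default 2).
#' @param min_age Minimum age (default 18).
#' @param min_duration Minimum survey duration in minutes (default 10).
#' @param attention Require the attention check to pass (default TRUE).
#' @return A `screening_rules` list.
#' @export
screening_rules <- function(accept_levels = 4:5, max_accept_wait = 2,
                            min_age = 18, min_duration = 10,
                            attention = TRUE) {
  structure(list(accept_levels = accept_levels,
                 max_accept_wait = max_accept_wait, min_age = min_age,
                 min_duration = min_duration, attention = attention),
            class = "screening_rules")
}

.default_countries <- c("Argentina", "Brazil", "Chile", "Colombia",
                        "Mexico", "Peru")

trust_actor_columns <- function() {
  unname(unlist(default_trust_map()))
}

#' Generate a synthetic respondent population
#'
#' Draws respondents with country, age, religion (configurable Evangelical
#' share), education, presidential co-partisanship, 1-4 trust scores for
#' every producer country, endorser, and distributing institution,
#' pre-treatment vaccine willingness (5-point) with intended wait in
#' months, and survey metadata (duration, attention check) for screening
#' emulation. Reproducible under `seed`.
#'
#' @param n_per_country Respondents drawn per country.
#' @param countries Character vector of countries.
#' @param seed Integer seed.
#' @param hesitant_only If TRUE, draw pre-treatment willingness/wait from
#'   the distribution conditional on failing the acceptance screen, so the
#'   returned population is entirely vaccine-hesitant (used to simulate
#'   post-screening samples of an exact size).
#' @param evangelical_share Named per-country Evangelical share; unnamed
#'   scalar applies everywhere (default: 0.25 in Brazil, 0.15 elsewhere).
#' @param trust_probs Probabilities over trust scores 1-4 applied to every
#'   actor (default `c(0.25, 0.35, 0.25, 0.15)`).
#' @param willingness_probs Probabilities over the 5-point prior
#'   acceptance item.
#' @param wait_lambda Poisson mean of the intended wait for each prior
#'   willingness level 1-5.
#' @return data.frame of respondent profiles.
#' @export
generate_population <- function(n_per_country = 2000,
                                countries = .default_countries,
                                seed = 1L,
                                hesitant_only = FALSE,
                                evangelical_share = NULL,
                                trust_probs = c(0.25, 0.35, 0.25, 0.15),
                                willingness_probs = c(0.10, 0.15, 0.16,
                                                      0.28, 0.31),
                                wait_lambda = c(9, 8, 5.5, 2.5, 1.5)) {
  if (n_per_country < 1) stop("n_per_country must be >= 1")
  if (length(trust_probs) != 4 || any(trust_probs < 0) ||
      sum(trust_probs) <= 0) {
    stop("trust_probs must be 4 nonnegative values")
  }
  if (length(willingness_probs) != 5 || any(willingness_probs < 0)) {
    stop("willingness_probs must be 5 nonnegative values")
  }
  if (is.null(evangelical_share)) {
    evangelical_share <- stats::setNames(
      ifelse(countries == "Brazil", 0.25, 0.15), countries)
  } else if (is.null(names(evangelical_share))) {
    evangelical_share <- stats::setNames(
      rep(evangelical_share[1], length(countries)), countries)
  }
  copartisan_share <- stats::setNames(
    ifelse(countries == "Brazil", 0.36,
           ifelse(countries == "Mexico", 0.31, 0.11)), countries)
  set.seed(seed %% 2147483647L)
  n <- n_per_country * length(countries)
  country <- rep(countries, each = n_per_country)
  pop <- data.frame(
    respondent_id = sprintf("R%05d", seq_len(n)),
    country = country,
    age = sample(18:80, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  # a thin sliver of minors, as reaches real screening junctures
  minors <- stats::runif(n) < 0.001
  pop$age[minors] <- sample(16:17, sum(minors), replace = TRUE)
  ev <- evangelical_share[country]
  u <- stats::runif(n)
  pop$religion <- ifelse(u < ev, "evangelical",
                         ifelse(u < ev + 0.60, "catholic", "other"))
  pop$education_high <- as.integer(stats::runif(n) < 0.30)
  pop$copartisan <- as.integer(stats::runif(n) < copartisan_share[country])
  for (tc in trust_actor_columns()) {
    pop[[tc]] <- sample(1:4, n, replace = TRUE,
                        prob = trust_probs / sum(trust_probs))
  }
  draw_prior <- function(m) {
    pw <- sample(1:5, m, replace = TRUE,
                 prob = willingness_probs / sum(willingness_probs))
    wait <- pmin(stats::rpois(m, wait_lambda[pw]), 24)
    data.frame(prior_willingness = pw, prior_wait = wait)
  }
  if (hesitant_only) {
    got <- 0L
    acc <- list()
    while (got < n) {
      cand <- draw_prior(2L * (n - got) + 16L)
      keep <- !(cand$prior_willingness >= 4 & cand$prior_wait <= 2)
      cand <- cand[keep, , drop = FALSE]
      acc[[length(acc) + 1L]] <- cand
      got <- got + nrow(cand)
    }
    pri <- do.call(rbind, acc)[seq_len(n), ]
    pop$age[pop$age < 18] <- 18L  # hesitant-only populations are post-screen
  } else {
    pri <- draw_prior(n)
  }
  pop$prior_willingness <- pri$prior_willingness
  pop$prior_wait <- pri$prior_wait
  pop$duration_min <- stats::rlnorm(n, meanlog = log(26), sdlog = 0.35)
  pop$attention_pass <- stats::runif(n) >= 0.001
  if (hesitant_only) {
    pop$duration_min <- pmax(pop$duration_min, 10)
    pop$attention_pass <- TRUE
  }
  rownames(pop) <- NULL
  pop
}

#' Apply survey screening rules
#'
#' Emulates the study's screening funnel, in order: vaccine-acceptant
#' respondents (agree/strongly agree AND intended wait within the
#' threshold) are screened out, then minors, then attention-check
#' failures, then speeders. Retained plus excluded always equals the input
#' count.
#'
#' @param population Output of [generate_population()].
#' @param rules A [screening_rules()] object.
#' @return List with `retained` (the hesitant analysis sample) and `tally`
#'   (data.frame rule / excluded / remaining).
#' @export
apply_screening <- function(population, rules = screening_rules()) {
  n0 <- nrow(population)
  tally <- data.frame(rule = character(0), excluded = integer(0),
                      remaining = integer(0), stringsAsFactors = FALSE)
  note <- function(rule, keep, df) {
    tally <<- rbind(tally, data.frame(
      rule = rule, excluded = sum(!keep), remaining = sum(keep),
      stringsAsFactors = FALSE))
    df[keep, , drop = FALSE]
  }
  acceptant <- population$prior_willingness %in% rules$accept_levels &
    population$prior_wait <= rules$max_accept_wait
  population <- note("vaccine_acceptant", !acceptant, population)
  population <- note("under_min_age", population$age >= rules$min_age,
                     population)
  if (rules$attention) {
    population <- note("attention_check_fail", population$attention_pass,
                       population)
  }
  population <- note("under_min_duration",
                     population$duration_min >= rules$min_duration,
                     population)
  list(retained = population, tally = tally)
}

#' Generate conjoint responses from the potential-outcomes model
#'
#' For each assigned scenario, draws the binary willingness outcome from a
#' linear-probability model: baseline willingness plus the level effects of
#' the realized profile, actor-matched trust moderation (slope times the
#' trust deviation from its population mean), a respondent random effect,
#' clipped to the configured probability bounds. The months-to-wait outcome
#' is a capped Poisson count whose mean moves opposite to the same linear
#' index, and the four mechanism items are the index plus item noise on a
#' 1-5 agreement scale. Optional carryover and attrition processes plant
#' SUTVA and attrition violations for diagnostic testing.
#'
#' @param population Respondent profiles ([generate_population()]).
#' @param assignments Long-format assignments ([assign_scenarios()]).
#' @param effects A [true_effects()] object.
#' @param seed Integer seed.
#' @param catalog The [attribute_catalog][build_catalog] used for the
#'   assignments.
#' @return `assignments` merged with respondent covariates plus raw
#'   response columns `willing`, `months`, and the four mechanism items
#'   (`NA` after a planted dropout). Attribute `clip_share` records the
#'   share of rows whose probability was clipped.
#' @export
generate_responses <- function(population, assignments, effects,
                               seed = 1L, catalog = build_catalog()) {
  if (!all(population$respondent_id %in% assignments$respondent_id) ||
      !all(assignments$respondent_id %in% population$respondent_id)) {
    stop("assignments must cover exactly the population's respondents")
  }
  set.seed(seed %% 2147483647L)
  dat <- merge(assignments,
               population[, setdiff(names(population),
                                    c("country", "block_id", "age_group"))],
               by = "respondent_id", sort = FALSE)
  dat <- dat[order(dat$respondent_id, dat$round), , drop = FALSE]
  n <- nrow(dat)
  tmap <- default_trust_map()
  idx <- numeric(n)
  for (d in names(effects$amce)) {
    v <- effects$amce[[d]]
    slope <- unname(effects$slopes[d])
    if (is.na(slope)) slope <- 0
    for (l in names(v)) {
      sel <- if (d == "producer_x_efficacy") {
        dat$producer == l & dat$efficacy_shown == "yes"
      } else {
        dat[[d]] == l
      }
      contrib <- v[[l]]
      if (d %in% names(tmap) && slope != 0) {
        tcol <- tmap[[d]][[l]]
        tv <- dat[[tcol]]
        contrib <- contrib + slope * (tv - mean(population[[tcol]]))
      }
      idx[sel] <- idx[sel] + if (length(contrib) > 1) contrib[sel] else
        contrib
    }
  }
  if (effects$carryover != 0) {
    prior_sino <- stats::ave(
      as.numeric(dat$producer == "sinovac"), dat$respondent_id,
      FUN = function(x) cumsum(c(0, x[-length(x)])) > 0)
    sel <- dat$producer == "sinovac" & prior_sino > 0
    idx[sel] <- idx[sel] + effects$carryover
  }
  re <- stats::rnorm(length(unique(dat$respondent_id)), 0,
                     effects$sigma_re)
  names(re) <- unique(dat$respondent_id)
  lin <- idx + re[dat$respondent_id]
  p <- effects$p0 + lin
  clipped <- p < effects$clip[1] | p > effects$clip[2]
  clip_share <- mean(clipped)
  if (clip_share > effects$clip_error_share) {
    stop(sprintf("probability clipping affects %.1f%% of rows (limit %.1f%%)",
                 100 * clip_share, 100 * effects$clip_error_share))
  }
  if (clip_share > effects$clip_warn_share) {
    warning(sprintf("probability clipping affects %.1f%% of rows",
                    100 * clip_share))
  }
  p <- pmin(pmax(p, effects$clip[1]), effects$clip[2])
  dat$willing <- stats::rbinom(n, 1, p)
  mu_m <- pmax(effects$months$base_wait - effects$months$scale * lin, 0.1)
  dat$months <- pmin(stats::rpois(n, mu_m), effects$months$cap)
  for (mc in mechanism_outcomes()) {
    latent <- effects$mech$base + effects$mech$scale * lin +
      stats::rnorm(n, 0, effects$mech$sd)
    dat[[mc]] <- pmin(pmax(round(latent), effects$mech$min),
                      effects$mech$max)
  }
  if (effects$attrition$rate > 0 || effects$attrition$sinovac > 0) {
    p_drop <- effects$attrition$rate +
      effects$attrition$sinovac * (dat$producer == "sinovac")
    drop_here <- stats::runif(n) < p_drop
    max_r <- max(dat$round)
    drop_after <- stats::ave(
      ifelse(drop_here, dat$round, max_r + 1L), dat$respondent_id,
      FUN = min)
    gone <- dat$round > drop_after
    dat$willing[gone] <- NA
    dat$months[gone] <- NA
    for (mc in mechanism_outcomes()) dat[[mc]][gone] <- NA
  }
  rownames(dat) <- NULL
  attr(dat, "clip_share") <- clip_share
  dat
}

#' Simulate a complete conjoint study
#'
#' End-to-end convenience wrapper: population generation (optionally with
#' the screening funnel), blocking, constrained scenario assignment,
#' potential-outcomes response generation, outcome construction, and
#' design-based weights.
#'
#' @param n Respondents per country after screening when `screen = FALSE`
#'   (the default, exact sample size); pre-screening panel size per country
#'   when `screen = TRUE`.
#' @param countries Countries to simulate.
#' @param n_rounds Conjoint rounds per respondent.
#' @param effects A [true_effects()] object.
#' @param catalog An [attribute_catalog][build_catalog].
#' @param seed Integer master seed; population, assignment, and response
#'   substreams are derived from it.
#' @param screen Emulate the screening funnel (default FALSE).
#' @return List: `data` (analysis-ready long format with outcomes and
#'   `ipw`), `population`, `effects`, and `tally` (screening tally or
#'   NULL).
#' @export
simulate_conjoint <- function(n = 1000, countries = .default_countries,
                              n_rounds = 5L,
                              effects = true_effects("paper"),
                              catalog = build_catalog(), seed = 1L,
                              screen = FALSE) {
  seed <- as.integer(seed %% 2147483000L)
  tally <- NULL
  if (screen) {
    pop <- generate_population(n, countries, seed = seed,
                               hesitant_only = FALSE)
    scr <- apply_screening(pop)
    pop <- scr$retained
    tally <- scr$tally
  } else {
    pop <- generate_population(n, countries, seed = seed,
                               hesitant_only = TRUE)
  }
  pop <- make_blocks(pop)
  assignments <- assign_scenarios(pop, catalog, n_rounds = n_rounds,
                                  seed = seed + 1L)
  dat <- generate_responses(pop, assignments, effects, seed = seed + 2L,
                            catalog = catalog)
  dat <- build_outcomes(dat)
  dat <- compute_ipw(dat, catalog)
  list(data = dat, population = pop, effects = effects, tally = tally)
}
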