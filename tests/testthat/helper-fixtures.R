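# Shared fixtures, all generated in code.

# Small end-to-end synthetic study (2 countries keeps blocks small).
tiny_study <- function(n = 60, seed = 42, effects = true_effects("paper"),
                       n_rounds = 5L, countries = c("Brazil", "Mexico")) {
  simulate_conjoint(n = n, countries = countries, n_rounds = n_rounds,
                    effects = effects, seed = seed)
}

# Catalog in which only the producer dimension varies (three specified
# producers, no efficacy disclosure, single-level everything else), for
# difference-in-means oracles.
producer_only_catalog <- function() {
  build_catalog(list(
    producer = list(
      levels = c("a", "b", "c"), baseline = "a",
      efficacy_map = c(a = 90, b = 80, c = 70)),
    efficacy_shown = list(levels = "unspecified", baseline = "unspecified"),
    endorser = list(levels = "medical_association",
                    baseline = "medical_association"),
    distributor = list(levels = "healthcare_system",
                       baseline = "healthcare_system"),
    uptake = list(levels = "unspecified", baseline = "unspecified")
  ))
}

# Hand-rollable dataset on the producer-only catalog: one row per
# respondent, arbitrary weights.
producer_only_data <- function(n = 30, seed = 1) {
  set.seed(seed)
  data.frame(
    respondent_id = sprintf("r%02d", seq_len(n)),
    country = "Brazil",
    block_id = "Brazil:neutral:30-44",
    round = 1L,
    producer = sample(c("a", "b", "c"), n, replace = TRUE),
    efficacy_shown = "unspecified",
    endorser = "medical_association",
    distributor = "healthcare_system",
    uptake = "unspecified",
    y = rnorm(n),
    w = runif(n, 0.5, 2),
    stringsAsFactors = FALSE
  )
}

# Enumerate every valid profile of a round under the default catalog,
# honoring the round-1-only constraint and the producer/efficacy coupling.
enumerate_profiles <- function(catalog, round) {
  grids <- lapply(names(catalog), function(d)
    levels_available(catalog, d, round))
  names(grids) <- names(catalog)
  g <- expand.grid(grids, stringsAsFactors = FALSE)
  u_prod <- catalog$producer$unspecified_level
  u_eff <- catalog$efficacy_shown$unspecified_level
  if (!is.null(u_prod) && !is.null(u_eff)) {
    ok <- !(g$producer == u_prod & g$efficacy_shown != u_eff)
    g <- g[ok, , drop = FALSE]
  }
  g$round <- round
  rownames(g) <- NULL
  g
}

# Explicit-dummy weighted least squares oracle: every fixed effect as a
# factor, fit with lm().
explicit_dummy_fit <- function(d, outcome = "y_willing") {
  enc <- encode_design(d)
  rounds <- sort(unique(d$round))
  ypx <- sapply(rounds[-1], function(r) d$ypre_willing * (d$round == r))
  colnames(ypx) <- paste0("ypre_x_round", rounds[-1])
  df <- data.frame(y = d[[outcome]], enc$X, ypx,
                   resp = factor(d$respondent_id),
                   cell = interaction(d$block_id, d$round, drop = TRUE),
                   check.names = FALSE)
  df$.w <- d$ipw
  lm(y ~ . - .w, data = df, weights = .w)
}

expect_rel_equal <- function(actual, expected, tol) {
  scale <- pmax(abs(expected), 1e-12)
  expect_lt(max(abs(actual - expected) / scale), tol)
}
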