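#' Blocked, constrained randomization of vignette profiles
#'
#' Assigns each respondent one vignette profile per round. Within every
#' block (country x prior-willingness stratum x age group) and round, each
#' dimension is assigned by a balanced random permutation over the levels
#' available in that round, independently across dimensions, so realized
#' frequencies match the design probabilities almost exactly within blocks.
#' Unspecified pure-control levels are available only in round 1. Because
#' an unspecified producer has no efficacy rate to disclose, efficacy
#' disclosure is forced to its control level whenever the producer is
#' unspecified; among specified-producer rows the disclosure draw stays
#' balanced.
#'
#' Randomness is derived from `seed` through one substream per
#' (round, dimension) pair, with respondents processed in a canonical order
#' (sorted block, then respondent id), so regenerating with the same seed
#' and inputs is bit-identical regardless of input row order.
#'
#' @param respondents A data.frame with at least `respondent_id`, `country`,
#'   and `block_id` columns (see [make_blocks()]); a `religion` column is
#'   used for the co-religious display of the religious-leader endorser.
#' @param catalog An [attribute_catalog][build_catalog].
#' @param n_rounds Number of conjoint rounds per respondent (default 5).
#' @param seed Integer master seed.
#' @return A long-format data.frame, one row per respondent x round:
#'   `respondent_id`, `country`, `block_id`, `round`, the five dimension
#'   columns, `efficacy_value` (percent, `NA` unless disclosed), and
#'   `endorser_displayed`.
#' @export
assign_scenarios <- function(respondents, catalog = build_catalog(),
                             n_rounds = 5L, seed = 1L) {
  if (n_rounds < 1L) stop("n_rounds must be >= 1")
  if (!nrow(respondents)) stop("empty respondent set")
  need <- c("respondent_id", "country", "block_id")
  miss <- setdiff(need, names(respondents))
  if (length(miss)) stop("respondents missing column(s): ",
                         paste(miss, collapse = ", "))

  ord <- order(respondents$block_id, respondents$respondent_id)
  resp <- respondents[ord, , drop = FALSE]
  n <- nrow(resp)
  block_f <- factor(resp$block_id)
  block_idx <- split(seq_len(n), block_f)

  dims <- names(catalog)
  out <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    draws <- matrix(NA_character_, n, length(dims),
                    dimnames = list(NULL, dims))
    for (j in seq_along(dims)) {
      d <- dims[j]
      set.seed(substream_seed(seed, r, j))
      avail <- levels_available(catalog, d, r)
      probs <- catalog[[d]]$probs[avail]
      probs <- probs / sum(probs)
      for (ix in block_idx) {
        draws[ix, j] <- balanced_draw(length(ix), avail, probs)
      }
    }
    draws <- as.data.frame(draws, stringsAsFactors = FALSE)
    # efficacy disclosure is undefined for an unspecified producer
    u_prod <- catalog$producer$unspecified_level
    u_eff <- catalog$efficacy_shown$unspecified_level
    if (!is.null(u_prod) && !is.null(u_eff)) {
      draws$efficacy_shown[draws$producer == u_prod] <- u_eff
    }
    eff_val <- rep(NA_real_, n)
    shown <- draws$efficacy_shown == "yes" &
      !(draws$producer %in% u_prod)
    eff_val[shown] <- catalog$producer$efficacy_map[draws$producer[shown]]
    out[[r]] <- data.frame(
      respondent_id = resp$respondent_id,
      country = resp$country,
      block_id = resp$block_id,
      round = r,
      draws,
      efficacy_value = eff_val,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res$endorser_displayed <- endorser_display(res$endorser,
                                             resp$religion[match(res$respondent_id,
                                                                 resp$respondent_id)])
  res <- res[order(res$respondent_id, res$round), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Balanced draw: a random permutation of levels repeated in (approximate)
# proportion to probs -- frequencies within the group match the design
# probabilities up to integer rounding, and draws are independent across
# dimensions because each dimension uses its own RNG substream.
balanced_draw <- function(n, levels, probs) {
  counts <- floor(n * probs)
  short <- n - sum(counts)
  if (short > 0) {
    # assign the remainder by probability-proportional sampling
    extra <- sample(levels, short, replace = TRUE, prob = probs)
    counts <- counts + tabulate(factor(extra, levels = levels),
                                nbins = length(levels))
  }
  sample(rep(levels, counts))
}

# Documented stream-splitting rule: one substream per (round, dimension),
# folded into 31 bits so set.seed() always receives a valid integer.
substream_seed <- function(seed, round, dim_index) {
  as.integer((as.numeric(seed) * 7919 + round * 104729 +
                dim_index * 15485863) %% 2147483647)
}

# Co-religious display of the religious-leader endorser: Catholics and
# non-Evangelical others see the Catholic archbishop; Evangelicals see the
# national Evangelical organization. Display only -- the underlying level
# (and its assignment probability) is unchanged.
endorser_display <- function(endorser, religion) {
  disp <- endorser
  rel <- endorser == "religious_leader"
  if (any(rel)) {
    if (is.null(religion)) religion <- rep("other", length(endorser))
    evang <- rel & !is.na(religion) & religion == "evangelical"
    disp[rel] <- "catholic_archbishop"
    disp[evang] <- "evangelical_organization"
  }
  disp
}

#' Render the vignette text for one scenario
#'
#' Produces the bracketed-template scenario text: the producer clause and
#' the efficacy sentence appear only when the corresponding level is
#' specified, and the community-uptake clause only when an uptake rate is
#' specified.
#'
#' @param profile A one-row data.frame (or list) with the five dimension
#'   columns, `round`, `efficacy_value`, and optionally
#'   `endorser_displayed`.
#' @param respondent A one-row data.frame (or list) with `country` and
#'   optionally `religion`.
#' @param catalog An [attribute_catalog][build_catalog].
#' @return A single character string.
#' @export
render_vignette <- function(profile, respondent,
                            catalog = build_catalog()) {
  get_display <- function(dimension, level) {
    dim <- catalog[[dimension]]
    lab <- NULL
    ctry <- as.character(respondent$country)
    if (!is.null(dim$country_display) &&
        !is.null(dim$country_display[[ctry]])) {
      lab <- unname(dim$country_display[[ctry]][level])
    }
    if (is.null(lab) || is.na(lab)) lab <- unname(dim$display[level])
    if (is.null(lab) || length(lab) == 0 || is.na(lab)) {
      stop("no display label for level '", level, "' of dimension '",
           dimension, "' in country '", ctry, "'")
    }
    lab
  }
  country <- as.character(respondent$country)
  if (is_unspecified(catalog, "producer", profile$producer)) {
    opener <- sprintf("Suppose that %s has obtained a vaccine.", country)
    efficacy <- ""
  } else {
    opener <- sprintf("Suppose that %s has obtained the vaccine produced by %s.",
                      country, get_display("producer", profile$producer))
    efficacy <- if (identical(profile$efficacy_shown, "yes")) {
      sprintf(" It has been demonstrated that the vaccine prevents %g%% of COVID-19 infections.",
              profile$efficacy_value)
    } else ""
  }
  end_level <- if (!is.null(profile$endorser_displayed) &&
                   profile$endorser == "religious_leader") {
    if (profile$endorser_displayed == "evangelical_organization")
      "the national Evangelical organization" else "the Catholic archbishop"
  } else {
    get_display("endorser", profile$endorser)
  }
  endorse <- sprintf(" The vaccine is free of charge for everyone and %s is recommending that everyone take the vaccine as soon as possible.",
                     end_level)
  dist <- sprintf(" The vaccine is being distributed by %s",
                  get_display("distributor", profile$distributor))
  uptake <- if (is_unspecified(catalog, "uptake", profile$uptake)) "." else
    sprintf(", and %s%% of people in your community have already been vaccinated.",
            profile$uptake)
  paste0(opener, efficacy, endorse, dist, uptake)
}

#' Derive block identifiers from respondent characteristics
#'
#' Blocks are country x prior-willingness stratum x age group. The
#' willingness stratum collapses the 5-point prior acceptance item to
#' disagree-side (1-2), neutral (3), agree-side (4-5); age groups are
#' 18-29, 30-44, 45-59, 60+ by default. Both cuts are configurable.
#'
#' @param respondents data.frame with `country`, `prior_willingness`
#'   (integer 1-5), `age` (years).
#' @param age_breaks Right-open age cut points (default
#'   `c(18, 30, 45, 60, Inf)`).
#' @param willingness_cuts Function mapping the 1-5 item to stratum labels.
#' @return The input with `age_group` and `block_id` columns added.
#' @export
make_blocks <- function(respondents,
                        age_breaks = c(18, 30, 45, 60, Inf),
                        willingness_cuts = NULL) {
  if (is.null(willingness_cuts)) {
    willingness_cuts <- function(w) {
      c("disagree", "disagree", "neutral", "agree", "agree")[w]
    }
  }
  labs <- paste0(age_breaks[-length(age_breaks)], "-",
                 c(age_breaks[-c(1, length(age_breaks))] - 1, "plus"))
  respondents$age_group <- as.character(
    cut(respondents$age, breaks = age_breaks, labels = labs,
        right = FALSE, include.lowest = TRUE))
  stratum <- willingness_cuts(respondents$prior_willingness)
  respondents$block_id <- paste(respondents$country, stratum,
                                respondents$age_group, sep = ":")
  respondents
}
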