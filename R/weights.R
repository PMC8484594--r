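#' Analytic assignment probability of a vignette profile
#'
#' The probability of a realized profile given its round, computed from the
#' catalog: the product over dimensions of the level's assignment
#' probability among the levels available in that round, with one
#' conditional factor -- efficacy disclosure is drawn only when the
#' producer is specified (it is forced to its control level otherwise), so
#' its factor is conditional on the drawn producer. Because of the round-1
#' restriction of unspecified levels, pure-control profiles are possible
#' only in round 1 and specified profiles become more probable from round 2
#' on; these probabilities are what the design-based weights invert.
#'
#' @param profiles A data.frame with `round` and one column per dimension
#'   (vectorized), as produced by [assign_scenarios()].
#' @param catalog An [attribute_catalog][build_catalog].
#' @return Numeric vector of joint assignment probabilities, one per row.
#' @export
assignment_probability <- function(profiles, catalog = build_catalog()) {
  n <- nrow(profiles)
  p <- rep(1, n)
  rounds <- sort(unique(profiles$round))
  u_prod <- catalog$producer$unspecified_level
  for (r in rounds) {
    ir <- which(profiles$round == r)
    for (d in names(catalog)) {
      lev <- profiles[[d]][ir]
      avail <- levels_available(catalog, d, r)
      bad <- !(lev %in% avail)
      if (any(bad)) {
        stop("row ", ir[which(bad)[1]], ": level '", lev[bad][1],
             "' of dimension '", d, "' is not assignable in round ", r,
             if (r > 1) " (unspecified levels are round-1 only)" else "")
      }
      probs <- catalog[[d]]$probs[avail] / sum(catalog[[d]]$probs[avail])
      if (d == "efficacy_shown" && !is.null(u_prod)) {
        # conditional on producer: forced to control when unspecified
        forced <- profiles$producer[ir] == u_prod
        fac <- probs[lev]
        fac[forced] <- 1
        p[ir] <- p[ir] * fac
      } else {
        p[ir] <- p[ir] * probs[lev]
      }
    }
  }
  unname(p)
}

#' Design-based inverse probability of treatment weights
#'
#' Attaches to each observation the inverse of its analytic assignment
#' probability, normalized to mean 1 over the dataset. The weights account
#' for differences in the probabilities of attribute assignment across
#' rounds, which arise because unspecified (pure-control) attributes can be
#' assigned only in the first conjoint round.
#'
#' @param dataset Long-format conjoint data with `round` and the dimension
#'   columns.
#' @param catalog An [attribute_catalog][build_catalog].
#' @param normalize Normalize weights to mean 1 (default TRUE).
#' @return `dataset` with columns `assign_prob` and `ipw` appended.
#' @export
compute_ipw <- function(dataset, catalog = build_catalog(),
                        normalize = TRUE) {
  p <- assignment_probability(dataset, catalog)
  if (any(!is.finite(p) | p <= 0)) {
    bad <- which(!is.finite(p) | p <= 0)[1]
    stop("row ", bad, ": zero or undefined assignment probability")
  }
  w <- 1 / p
  if (normalize) w <- w / mean(w)
  dataset$assign_prob <- p
  dataset$ipw <- w
  dataset
}

#' Empirical assignment frequencies (diagnostic)
#'
#' Observed level frequencies per dimension and round, for comparison with
#' the analytic probabilities used by [compute_ipw()]. Diagnostic only;
#' weights are always computed analytically from the catalog.
#'
#' @inheritParams compute_ipw
#' @return data.frame with `dimension`, `round`, `level`, `n`, `freq`,
#'   `design_prob`.
#' @export
empirical_assignment_freq <- function(dataset, catalog = build_catalog()) {
  out <- list()
  u_prod <- catalog$producer$unspecified_level
  for (d in names(catalog)) {
    tab <- table(dataset$round, dataset[[d]])
    for (r in rownames(tab)) {
      avail <- levels_available(catalog, d, as.integer(r))
      probs <- catalog[[d]]$probs[avail] / sum(catalog[[d]]$probs[avail])
      if (d == "efficacy_shown" && !is.null(u_prod) &&
          u_prod %in% levels_available(catalog, "producer", as.integer(r))) {
        # marginalize over the producer coupling: disclosure is drawn only
        # when the producer is specified
        pp <- catalog$producer$probs / sum(catalog$producer$probs)
        p_spec <- 1 - unname(pp[u_prod])
        u_eff <- catalog$efficacy_shown$unspecified_level
        probs <- probs * p_spec
        probs[u_eff] <- probs[u_eff] + (1 - p_spec)
      }
      nr <- sum(tab[r, ])
      for (l in colnames(tab)) {
        if (tab[r, l] == 0 && !(l %in% avail)) next
        out[[length(out) + 1L]] <- data.frame(
          dimension = d, round = as.integer(r), level = l,
          n = as.integer(tab[r, l]), freq = tab[r, l] / nr,
          design_prob = if (l %in% avail) unname(probs[l]) else 0,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
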