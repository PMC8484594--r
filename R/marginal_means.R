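#' Marginal means by attribute level
#'
#' For each level of each catalog dimension, the IPW-weighted mean outcome
#' among rows assigned that level, with a cluster-robust standard error
#' from the linearized ratio estimator. Marginal means are descriptive
#' companions to AMCEs: they show absolute outcome levels rather than
#' contrasts against a baseline. Levels with no observations are flagged
#' missing, not zero.
#'
#' @inheritParams fit_amce
#' @return data.frame with `dimension`, `level`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `n`, `missing`.
#' @export
marginal_means <- function(dataset, outcome = "y_willing",
                           catalog = build_catalog(), weights = "ipw",
                           cluster = "respondent_id", conf_level = 0.95) {
  y <- dataset[[outcome]]
  if (is.null(y)) stop("outcome column '", outcome, "' not found")
  keep <- !is.na(y)
  dataset <- dataset[keep, , drop = FALSE]
  y <- as.numeric(y[keep])
  w <- if (is.null(weights)) rep(1, nrow(dataset)) else dataset[[weights]]
  cl <- as.factor(dataset[[cluster]])
  G <- nlevels(cl)
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- list()
  for (d in names(catalog)) {
    for (l in catalog[[d]]$levels) {
      sel <- dataset[[d]] == l
      n_l <- sum(sel)
      if (n_l == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          dimension = d, level = l, estimate = NA_real_, se = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_, n = 0L, missing = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      B <- sum(w[sel])
      mm <- sum(w[sel] * y[sel]) / B
      u <- rep(0, length(y))
      u[sel] <- w[sel] * (y[sel] - mm)
      ug <- rowsum(u, cl)
      v <- G / (G - 1) * sum(ug^2) / B^2
      se <- sqrt(v)
      out[[length(out) + 1L]] <- data.frame(
        dimension = d, level = l, estimate = mm, se = se,
        ci_low = mm - crit * se, ci_high = mm + crit * se, n = n_l,
        missing = FALSE, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
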