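#' Covariate balance test for randomization validity
#'
#' Regresses each pre-treatment covariate on the full set of treatment
#' dummies (weighted, intercept included, standard errors clustered by
#' respondent) and reports per-term z-tests plus a joint Wald chi-square
#' test per covariate. Under correct randomization, attributes are
#' uncorrelated with predetermined covariates, so roughly 5% of per-term
#' tests should reject at the 5% level. Constant covariates are skipped
#' with a warning. The dataset is never modified.
#'
#' @param dataset Long-format conjoint data with weights attached.
#' @param covariates Character vector of respondent-level covariate
#'   columns.
#' @param catalog An [attribute_catalog][build_catalog].
#' @param weights Weight column (default `"ipw"`; `NULL` unweighted).
#' @param cluster Cluster id column.
#' @return A `diagnostic_report`: list with `tests` (covariate, term,
#'   estimate, se, statistic, p_value, n), `joint` (covariate, statistic,
#'   df, p_value), `skipped`, and `share_sig_05`.
#' @export
balance_test <- function(dataset, covariates, catalog = build_catalog(),
                         weights = "ipw", cluster = "respondent_id") {
  enc <- encode_design(dataset, catalog)
  n <- nrow(dataset)
  w <- if (is.null(weights)) rep(1, n) else dataset[[weights]]
  cl <- dataset[[cluster]]
  X <- cbind(`(Intercept)` = rep(1, n), enc$X)
  tests <- list()
  joint <- list()
  skipped <- character(0)
  for (cv in covariates) {
    v <- dataset[[cv]]
    if (is.null(v)) stop("covariate column '", cv, "' not found")
    v <- as.numeric(v)
    if (stats::var(v, na.rm = TRUE) == 0 || all(is.na(v))) {
      warning("covariate '", cv, "' is constant; skipped")
      skipped <- c(skipped, cv)
      next
    }
    ok <- !is.na(v)
    fit <- stats::lm.wfit(X[ok, , drop = FALSE], v[ok], w[ok])
    V <- cluster_robust_vcov(X[ok, , drop = FALSE], fit$residuals, w[ok],
                             cl[ok], df_used = ncol(X))
    b <- fit$coefficients[-1L]
    se <- sqrt(diag(V))[-1L]
    z <- b / se
    tests[[cv]] <- data.frame(
      covariate = cv, term = colnames(enc$X), estimate = unname(b),
      se = unname(se), statistic = unname(z),
      p_value = 2 * stats::pnorm(-abs(z)), n = sum(ok),
      stringsAsFactors = FALSE)
    Vt <- V[-1L, -1L, drop = FALSE]
    stat <- tryCatch(drop(t(b) %*% solve(Vt, b)), error = function(e) NA)
    joint[[cv]] <- data.frame(
      covariate = cv, statistic = stat, df = length(b),
      p_value = if (is.na(stat)) NA else
        stats::pchisq(stat, df = length(b), lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  tests <- if (length(tests)) do.call(rbind, c(tests, make.row.names = FALSE))
    else data.frame()
  joint <- if (length(joint)) do.call(rbind, c(joint, make.row.names = FALSE))
    else data.frame()
  structure(list(
    type = "balance",
    tests = tests,
    joint = joint,
    skipped = skipped,
    share_sig_05 = if (nrow(tests)) mean(tests$p_value < 0.05) else NA_real_
  ), class = "diagnostic_report")
}

#' Attrition orthogonality test
#'
#' For each non-final round, builds an indicator for dropping out after
#' that round (no response observed in the next round) and regresses it on
#' the attributes of the scenario after which attrition could occur,
#' clustered by respondent. If assignment is ignorable, attrition should be
#' orthogonal to the presented attributes. With no attrition the test is
#' vacuous and the report says so.
#'
#' @inheritParams balance_test
#' @param outcome Column whose missingness in the next round defines
#'   dropout (default `"y_willing"`); alternatively the absence of the
#'   next-round row.
#' @return A `diagnostic_report` with per-term tests on the dropout
#'   indicator, or a vacuous-test note.
#' @export
attrition_test <- function(dataset, catalog = build_catalog(),
                           weights = "ipw", cluster = "respondent_id",
                           outcome = "y_willing") {
  rounds <- sort(unique(dataset$round))
  if (length(rounds) < 2L) stop("attrition test needs at least 2 rounds")
  present <- !is.na(dataset[[outcome]])
  key <- paste(dataset$respondent_id, dataset$round, sep = "\r")
  obs <- stats::setNames(present, key)
  last <- max(rounds)
  at_risk <- dataset$round < last & present
  nxt <- paste(dataset$respondent_id, dataset$round + 1L, sep = "\r")
  nxt_obs <- obs[nxt]
  dropout <- as.numeric(is.na(nxt_obs) | !nxt_obs)[at_risk]
  if (sum(dropout) == 0) {
    return(structure(list(
      type = "attrition", vacuous = TRUE,
      note = "no attrition present; test is vacuous",
      tests = data.frame(), n = sum(at_risk)), class = "diagnostic_report"))
  }
  sub <- dataset[at_risk, , drop = FALSE]
  enc <- encode_design(sub, catalog)
  n <- nrow(sub)
  w <- if (is.null(weights)) rep(1, n) else sub[[weights]]
  X <- cbind(`(Intercept)` = rep(1, n), enc$X)
  dropped <- collinear_columns(X, w)
  if (length(dropped)) X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  fit <- stats::lm.wfit(X, dropout, w)
  V <- cluster_robust_vcov(X, fit$residuals, w, sub[[cluster]],
                           df_used = ncol(X))
  b <- fit$coefficients[-1L]
  se <- sqrt(diag(V))[-1L]
  z <- b / se
  structure(list(
    type = "attrition", vacuous = FALSE,
    tests = data.frame(term = colnames(X)[-1L], estimate = unname(b),
                       se = unname(se), statistic = unname(z),
                       p_value = 2 * stats::pnorm(-abs(z)), n = n,
                       stringsAsFactors = FALSE),
    dropout_rate = mean(dropout), n = n,
    share_sig_05 = mean(2 * stats::pnorm(-abs(z)) < 0.05)
  ), class = "diagnostic_report")
}

#' First-round-only robustness estimate
#'
#' Re-estimates the AMCE regression on first-round responses only, as a
#' check on carryover/stability (SUTVA): with one scenario per respondent
#' there is no scope for earlier scenarios to contaminate responses. With a
#' single row per respondent, respondent fixed effects are dropped (block
#' cells remain) and the pre-treatment control enters as a main effect;
#' design weights are renormalized within the subset (round-1 assignment
#' probabilities still differ across profiles because efficacy disclosure
#' is drawn only under a specified producer). Metadata flags the
#' restriction.
#'
#' @inheritParams fit_amce
#' @return A `conjoint_fit` with `meta$first_round_only = TRUE`.
#' @export
first_round_robustness <- function(dataset, outcome = "y_willing",
                                   catalog = build_catalog(),
                                   weights = "ipw", ypre = NULL,
                                   cluster = "respondent_id",
                                   conf_level = 0.95,
                                   df_method = c("normal", "t")) {
  sub <- dataset[dataset$round == 1L, , drop = FALSE]
  if (!nrow(sub)) stop("no round-1 rows in dataset")
  if (!is.null(weights)) {
    sub[[weights]] <- sub[[weights]] / mean(sub[[weights]])
  }
  if (is.null(ypre)) {
    ypre <- switch(outcome, y_willing = "ypre_willing",
                   y_months = "ypre_months", NA_character_)
    if (!is.na(ypre) && is.null(sub[[ypre]])) ypre <- NA_character_
  }
  fit <- fit_amce(sub, outcome = outcome, catalog = catalog,
                  weights = weights, fe = "cell", ypre = ypre,
                  cluster = cluster, conf_level = conf_level,
                  df_method = df_method)
  fit$meta$first_round_only <- TRUE
  fit
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("Diagnostic report:", x$type, "\n")
  if (isTRUE(x$vacuous)) {
    cat(" ", x$note, "\n")
    return(invisible(x))
  }
  if (!is.null(x$share_sig_05)) {
    cat(sprintf("  share of per-term tests with p < 0.05: %.3f\n",
                x$share_sig_05))
  }
  if (!is.null(x$joint) && nrow(x$joint)) {
    cat("  joint tests:\n")
    print(x$joint, row.names = FALSE)
  }
  if (length(x$skipped)) {
    cat("  skipped (constant):", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}
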