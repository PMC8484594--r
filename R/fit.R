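#' Cluster-robust (CR1) sandwich variance matrix
#'
#' Sandwich estimator for (weighted) least squares with scores summed
#' within clusters and the CR1 finite-cluster correction
#' `G/(G-1) * (N-1)/(N-K)`. With every observation its own cluster this
#' reduces to the heteroskedasticity-robust (HC1-type) estimator.
#'
#' @param X Model matrix (the columns actually estimated, after any
#'   fixed-effect absorption).
#' @param residuals Residual vector.
#' @param weights Observation weights (default all 1).
#' @param clusters Cluster identifiers (respondent ids).
#' @param df_used Total parameters absorbed and estimated, `K` in the CR1
#'   multiplier; defaults to `ncol(X)`.
#' @return Symmetric positive semi-definite matrix, `ncol(X)` square.
#' @export
cluster_robust_vcov <- function(X, residuals, weights = NULL, clusters,
                                df_used = ncol(X)) {
  X <- as.matrix(X)
  n <- nrow(X)
  residuals <- as.vector(residuals)
  if (is.null(weights)) weights <- rep(1, n)
  weights <- as.vector(weights)
  cl <- as.factor(clusters)
  G <- nlevels(cl)
  if (G < 2L) stop("need at least 2 clusters")
  bread <- crossprod(X * sqrt(weights))
  binv <- tryCatch(solve(bread), error = function(e) {
    stop("singular bread matrix: ", conditionMessage(e))
  })
  scores <- X * (weights * residuals)
  S <- rowsum(scores, cl, reorder = FALSE)
  meat <- crossprod(S)
  adj <- G / (G - 1) * (n - 1) / (n - df_used)
  V <- adj * binv %*% meat %*% binv
  (V + t(V)) / 2
}

# In-order greedy rank sweep on the weighted Gram matrix: a column is
# dropped when its residual variance after projecting on the columns kept
# so far is below tol relative to its own scale. Keeps earlier columns, so
# ordering encodes drop priority.
collinear_columns <- function(M, w, tol = 1e-9) {
  Gm <- crossprod(M * sqrt(w))
  p <- ncol(Gm)
  keep <- integer(0)
  dropped <- character(0)
  for (j in seq_len(p)) {
    gjj <- Gm[j, j]
    if (gjj <= 0) { dropped <- c(dropped, colnames(M)[j]); next }
    d <- if (length(keep)) {
      g <- Gm[keep, j]
      gjj - sum(g * solve(Gm[keep, keep, drop = FALSE], g))
    } else gjj
    if (d / gjj < tol) dropped <- c(dropped, colnames(M)[j])
    else keep <- c(keep, j)
  }
  dropped
}

#' Estimate average marginal component effects (AMCEs)
#'
#' Fits the pre-specified weighted least-squares regression of an outcome
#' on the treatment dummies of the conjoint design, with respondent and
#' block-by-round-by-country fixed effects absorbed by the within
#' transformation, a pre-treatment immediacy control with a round-varying
#' coefficient, design-based inverse probability weights, and standard
#' errors clustered at the respondent level (CR1). Coefficients are AMCEs
#' relative to the catalog baselines; omitted baseline levels have implicit
#' coefficient zero.
#'
#' @details
#' Because the pre-treatment control is respondent-constant, its main
#' effect is absorbed by the respondent fixed effects; its round-varying
#' part enters as interactions with round indicators (first round omitted).
#' Without respondent fixed effects (`fe = "cell"` or `"none"`) the main
#' effect is included too. Collinear control columns are dropped with a
#' warning; a collinear treatment column is an error.
#'
#' @param dataset Long-format conjoint data carrying the dimension columns,
#'   the outcome, a weight column, `respondent_id`, `block_id`, `round`.
#' @param outcome Outcome column name (default `"y_willing"`).
#' @param catalog An [attribute_catalog][build_catalog].
#' @param weights Weight column name (default `"ipw"`); `NULL` for
#'   unweighted.
#' @param fe `"both"` (respondent and block x round x country cells, the
#'   default), `"cell"` (cells only), or `"none"` (intercept only).
#' @param ypre Pre-treatment control column; `NULL` picks `ypre_willing`
#'   for the binary outcome, `ypre_months` for the months outcome, if
#'   present; `NA` disables the control.
#' @param cluster Cluster id column (default `"respondent_id"`).
#' @param conf_level Confidence level (default 0.95).
#' @param df_method `"normal"` (1.96-style critical values, default) or
#'   `"t"` (Student t with clusters - 1 df).
#' @param extra A list with `X` (matrix of additional regressors) and
#'   `terms` (bookkeeping rows), used by [fit_heterogeneous()].
#' @param on_drop_extra `"error"` or `"warn"` when an `extra` column is
#'   collinear after absorption.
#' @param df_fe How absorbed fixed effects enter the CR1 correction's `K`:
#'   `"nested"` (default) excludes factors nested within clusters, e.g.
#'   respondent effects under respondent clustering, avoiding conservative
#'   standard errors; `"all"` counts every absorbed level, matching
#'   explicit-dummy software.
#' @return A `conjoint_fit`: list with `coefficients` (term, dimension,
#'   level, baseline, estimate, se, ci_low, ci_high), `vcov`, `n`,
#'   `n_clusters`, `residuals`, `dropped`, and `meta`.
#' @export
fit_amce <- function(dataset, outcome = "y_willing",
                     catalog = build_catalog(), weights = "ipw",
                     fe = c("both", "cell", "none"), ypre = NULL,
                     cluster = "respondent_id", conf_level = 0.95,
                     df_method = c("normal", "t"), extra = NULL,
                     on_drop_extra = "error",
                     df_fe = c("nested", "all")) {
  fe <- match.arg(fe)
  df_method <- match.arg(df_method)
  df_fe <- match.arg(df_fe)
  y <- dataset[[outcome]]
  if (is.null(y)) stop("outcome column '", outcome, "' not found")
  keep <- !is.na(y)
  dataset <- dataset[keep, , drop = FALSE]
  y <- as.numeric(y[keep])
  n <- length(y)
  cl <- dataset[[cluster]]
  if (is.null(cl)) stop("cluster column '", cluster, "' not found")
  if (length(unique(cl)) < 2L) stop("need at least 2 clusters")
  w <- if (is.null(weights)) rep(1, n) else {
    if (is.null(dataset[[weights]])) stop("weight column '", weights,
                                          "' not found; run compute_ipw()")
    dataset[[weights]]
  }

  enc <- encode_design(dataset, catalog)
  X <- enc$X
  terms <- enc$terms
  terms$class <- "treatment"
  if (!is.null(extra)) {
    X <- cbind(X, extra$X[keep, , drop = FALSE])
    et <- extra$terms
    et$class <- "interaction"
    terms <- rbind(terms, et)
  }

  # pre-treatment immediacy control, round-varying
  if (is.null(ypre)) {
    ypre <- switch(outcome, y_willing = "ypre_willing",
                   y_months = "ypre_months", NA_character_)
    if (!is.na(ypre) && is.null(dataset[[ypre]])) ypre <- NA_character_
  }
  C <- NULL
  if (!is.na(ypre)) {
    yp <- dataset[[ypre]]
    if (is.null(yp)) stop("ypre column '", ypre, "' not found")
    rounds <- sort(unique(dataset$round))
    cols <- list()
    if (fe != "both") cols[[paste0(ypre)]] <- yp
    for (r in rounds[-1]) {
      cols[[paste0(ypre, "_x_round", r)]] <- yp * (dataset$round == r)
    }
    if (length(cols)) C <- do.call(cbind, cols)
  }
  if (fe == "none") {
    C <- cbind(`(Intercept)` = rep(1, n), C)
  }
  n_ctrl <- if (is.null(C)) 0L else ncol(C)
  if (n_ctrl) {
    terms <- rbind(terms, data.frame(
      term = colnames(C), dimension = "control", level = NA_character_,
      baseline = NA_character_, class = "control",
      stringsAsFactors = FALSE))
  }
  M <- cbind(X, C)
  colnames(M) <- terms$term

  fe_groups <- switch(fe,
    both = list(respondent = dataset$respondent_id,
                cell = interaction(dataset$block_id, dataset$round,
                                   drop = TRUE)),
    cell = list(cell = interaction(dataset$block_id, dataset$round,
                                   drop = TRUE)),
    none = list())
  if (fe != "none") {
    D <- within_transform(cbind(y, M), fe_groups, weights = w)
    yt <- D[, 1L]
    Mt <- D[, -1L, drop = FALSE]
  } else {
    yt <- y
    Mt <- M
  }

  # rank check; columns are ordered treatment, interaction, control, and
  # the in-order sweep drops the later member of any collinear pair
  dropped <- collinear_columns(Mt, w)
  if (length(dropped)) {
    dr_class <- terms$class[match(dropped, terms$term)]
    if (any(dr_class == "treatment")) {
      stop("treatment column(s) collinear after fixed-effect absorption: ",
           paste(dropped[dr_class == "treatment"], collapse = ", "))
    }
    if (any(dr_class == "interaction") && on_drop_extra == "error") {
      stop("interaction column(s) collinear: ",
           paste(dropped[dr_class == "interaction"], collapse = ", "))
    }
    warning("dropping collinear column(s): ",
            paste(dropped, collapse = ", "))
    keep_cols <- setdiff(colnames(Mt), dropped)
    Mt <- Mt[, keep_cols, drop = FALSE]
    terms <- terms[terms$term %in% keep_cols, , drop = FALSE]
  }

  fit <- stats::lm.wfit(Mt, yt, w)
  beta <- fit$coefficients
  res <- fit$residuals
  df_used <- ncol(Mt) +
    fe_dof(fe_groups, cluster = if (df_fe == "nested") cl else NULL)
  V <- cluster_robust_vcov(Mt, res, w, cl, df_used = df_used)
  se <- sqrt(diag(V))
  G <- length(unique(cl))
  crit <- if (df_method == "normal") {
    stats::qnorm(1 - (1 - conf_level) / 2)
  } else {
    stats::qt(1 - (1 - conf_level) / 2, df = G - 1)
  }
  coefs <- data.frame(
    term = colnames(Mt),
    dimension = terms$dimension,
    level = terms$level,
    baseline = terms$baseline,
    class = terms$class,
    estimate = unname(beta),
    se = se,
    ci_low = unname(beta) - crit * se,
    ci_high = unname(beta) + crit * se,
    stringsAsFactors = FALSE
  )
  structure(list(
    coefficients = coefs,
    vcov = V,
    n = n,
    n_clusters = G,
    residuals = res,
    dropped = dropped,
    meta = list(outcome = outcome, weights = weights, fe = fe,
                ypre = ypre, conf_level = conf_level,
                df_method = df_method, df_used = df_used,
                baselines = vapply(catalog, function(d) d$baseline,
                                   character(1)))
  ), class = "conjoint_fit")
}

#' @export
print.conjoint_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Conjoint fit: outcome %s | n = %d rows, %d clusters | fe = %s | weights = %s\n",
              x$meta$outcome, x$n, x$n_clusters, x$meta$fe,
              if (is.null(x$meta$weights)) "none" else x$meta$weights))
  tab <- x$coefficients[x$coefficients$class != "control",
                        c("term", "estimate", "se", "ci_low", "ci_high")]
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.conjoint_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
vcov.conjoint_fit <- function(object, ...) object$vcov

#' @export
confint.conjoint_fit <- function(object, ...) {
  cbind(lower = object$coefficients$ci_low,
        upper = object$coefficients$ci_high)
}

#' Tidy coefficient table of a conjoint fit
#'
#' @param fit A `conjoint_fit`.
#' @param treatment_only Drop control columns (default TRUE).
#' @return data.frame with one row per estimated term plus `n` and
#'   `n_clusters` columns, plot-ready for dot-and-whisker displays.
#' @export
tidy_fit <- function(fit, treatment_only = TRUE) {
  tab <- fit$coefficients
  if (treatment_only) tab <- tab[tab$class != "control", , drop = FALSE]
  tab$n <- fit$n
  tab$n_clusters <- fit$n_clusters
  rownames(tab) <- NULL
  tab
}
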