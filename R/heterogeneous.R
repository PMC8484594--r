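#' Default mapping from attribute levels to trust columns
#'
#' Maps each producer to trust in its country of origin, each endorser to
#' trust in that actor, and each distributor to trust in that institution.
#' Used by [fit_heterogeneous()] to build actor-matched trust interactions.
#'
#' @return Named list of named character vectors (level -> trust column).
#' @export
default_trust_map <- function() {
  list(
    producer = c(pfizer = "trust_usa", astrazeneca = "trust_uk",
                 gamaleya = "trust_russia", sinovac = "trust_china"),
    endorser = c(president = "trust_president", mayor = "trust_mayor",
                 medical_association = "trust_medical",
                 religious_leader = "trust_religious",
                 left_newspaper = "trust_left_news",
                 right_newspaper = "trust_right_news"),
    distributor = c(healthcare_system = "trust_health_system",
                    military = "trust_military",
                    civil_society = "trust_civil_society")
  )
}

#' Estimate heterogeneous treatment effects
#'
#' Augments the AMCE regression with interactions between treatment dummies
#' and a moderating variable. Two moderator types are supported:
#'
#' * `moderator = "trust"`: actor-matched trust interactions. Each
#'   producer, endorser, and distributor dummy is interacted with the
#'   respondent's 1-4 trust score in that dummy's actor (trust in the
#'   producer's country, in the endorser, in the distributing
#'   institution). Producer-by-efficacy and uptake terms are not
#'   interacted. Interaction coefficients are the change in the effect of
#'   that level per one-unit increase in trust in the actor; raw
#'   (uncentered) trust values are used.
#' * a respondent-level column name (e.g. a subgroup indicator): every
#'   treatment dummy is interacted with it, and its main effect is
#'   included whenever respondent fixed effects do not absorb it.
#'
#' A moderator with no variation makes its interactions collinear with the
#' main effects; those columns are flagged and dropped with a warning.
#'
#' @inheritParams fit_amce
#' @param moderator `"trust"` or the name of a respondent-level column.
#' @param trust_map Level-to-column mapping, see [default_trust_map()].
#' @return A `conjoint_fit` whose coefficient table contains both main
#'   (`class == "treatment"`) and interaction (`class == "interaction"`)
#'   terms.
#' @export
fit_heterogeneous <- function(dataset, moderator, outcome = "y_willing",
                              catalog = build_catalog(), weights = "ipw",
                              fe = c("both", "cell", "none"), ypre = NULL,
                              cluster = "respondent_id",
                              trust_map = default_trust_map(),
                              conf_level = 0.95,
                              df_method = c("normal", "t")) {
  fe <- match.arg(fe)
  df_method <- match.arg(df_method)
  enc <- encode_design(dataset, catalog)
  terms <- enc$terms
  if (identical(moderator, "trust")) {
    cols <- list()
    rows <- list()
    for (k in seq_len(nrow(terms))) {
      tk <- terms[k, ]
      if (!tk$dimension %in% names(trust_map)) next
      tcol <- trust_map[[tk$dimension]][[tk$level]]
      if (is.null(tcol)) next
      tv <- dataset[[tcol]]
      if (is.null(tv)) stop("trust column '", tcol, "' (moderator for ",
                            tk$term, ") not found")
      if (anyNA(tv)) stop("trust column '", tcol, "' has missing values")
      nm <- paste0(tk$term, "_x_trust")
      cols[[nm]] <- enc$X[, tk$term] * as.numeric(tv)
      rows[[nm]] <- data.frame(
        term = nm, dimension = paste0(tk$dimension, "_x_trust"),
        level = tk$level, baseline = tk$baseline, stringsAsFactors = FALSE)
    }
    if (!length(cols)) stop("trust map matched no treatment terms")
    extra <- list(X = do.call(cbind, cols), terms = do.call(rbind, rows))
    # trust main effects are respondent-constant; include them when no
    # respondent fixed effect absorbs them
    if (fe != "both") {
      mains <- unique(unlist(trust_map))
      mains <- mains[mains %in% names(dataset)]
      Xm <- sapply(mains, function(cn) as.numeric(dataset[[cn]]))
      extra$X <- cbind(extra$X, Xm)
      extra$terms <- rbind(extra$terms, data.frame(
        term = mains, dimension = "moderator_main", level = NA_character_,
        baseline = NA_character_, stringsAsFactors = FALSE))
    }
  } else {
    mv <- dataset[[moderator]]
    if (is.null(mv)) stop("moderator column '", moderator, "' not found")
    if (anyNA(mv)) stop("moderator '", moderator, "' has missing values")
    mv <- as.numeric(mv)
    Xi <- enc$X * mv
    colnames(Xi) <- paste0(terms$term, "_x_", moderator)
    rows <- data.frame(term = colnames(Xi),
                       dimension = paste0(terms$dimension, "_x_", moderator),
                       level = terms$level, baseline = terms$baseline,
                       stringsAsFactors = FALSE)
    extra <- list(X = Xi, terms = rows)
    if (fe != "both") {
      extra$X <- cbind(extra$X, mv)
      colnames(extra$X)[ncol(extra$X)] <- moderator
      extra$terms <- rbind(extra$terms, data.frame(
        term = moderator, dimension = "moderator_main",
        level = NA_character_, baseline = NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  fit <- fit_amce(dataset, outcome = outcome, catalog = catalog,
                  weights = weights, fe = fe, ypre = ypre,
                  cluster = cluster, conf_level = conf_level,
                  df_method = df_method, extra = extra,
                  on_drop_extra = "warn")
  fit$meta$moderator <- if (identical(moderator, "trust")) "trust" else
    moderator
  fit
}
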