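#' Encode the treatment design matrix
#'
#' Expands the realized profiles into the treatment dummies of the AMCE
#' regression: one dummy per non-baseline producer (vs unspecified), one
#' producer-by-efficacy interaction dummy per specified producer (1 iff
#' that producer was drawn and its efficacy rate disclosed), endorser
#' dummies vs the medical association, distributor dummies vs the public
#' healthcare system, and uptake dummies vs unspecified. Under the default
#' catalog this yields 4 + 4 + 5 + 2 + 4 = 19 columns. Baseline levels are
#' omitted: a round-1 pure-control row is all zeros.
#'
#' @param dataset Long-format conjoint data with the dimension columns.
#' @param catalog An [attribute_catalog][build_catalog].
#' @return List with `X` (numeric matrix, n x terms) and `terms` (the
#'   [catalog_terms()] bookkeeping data.frame).
#' @export
encode_design <- function(dataset, catalog = build_catalog()) {
  terms <- catalog_terms(catalog)
  for (d in setdiff(names(catalog), "efficacy_shown")) {
    lev <- dataset[[d]]
    if (is.null(lev)) stop("dataset missing dimension column '", d, "'")
    unknown <- !(lev %in% catalog[[d]]$levels)
    if (any(unknown)) {
      stop("row ", which(unknown)[1], ": unknown level '",
           lev[unknown][1], "' for dimension '", d, "'")
    }
  }
  n <- nrow(dataset)
  X <- matrix(0, n, nrow(terms), dimnames = list(NULL, terms$term))
  shown <- dataset$efficacy_shown == "yes"
  for (k in seq_len(nrow(terms))) {
    tk <- terms[k, ]
    if (tk$dimension == "producer_x_efficacy") {
      X[, k] <- as.numeric(dataset$producer == tk$level & shown)
    } else {
      X[, k] <- as.numeric(dataset[[tk$dimension]] == tk$level)
    }
  }
  list(X = X, terms = terms)
}
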