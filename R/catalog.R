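#' Attribute catalogs for vaccine-campaign conjoint designs
#'
#' An attribute catalog describes the randomized dimensions of a mass
#' vaccination vignette: the set of levels per dimension, the baseline
#' (reference) level each coefficient is estimated against, which level (if
#' any) is an "unspecified" pure-control level available only in the first
#' conjoint round, optional per-level assignment probabilities, display
#' labels, and -- for the producer dimension -- the phase-3 trial efficacy
#' percentage revealed when efficacy disclosure is drawn.
#'
#' @details
#' The default catalog has five dimensions:
#' \describe{
#'   \item{producer}{Pfizer (USA), AstraZeneca-Oxford (UK), Gamaleya
#'     (Russia), Sinovac (China), or unspecified. Efficacy percentages
#'     95, 70, 91, 50.}
#'   \item{efficacy_shown}{whether the producer's trial efficacy rate is
#'     disclosed ("yes") or not ("unspecified"). When the producer is
#'     unspecified there is no rate to disclose, so efficacy_shown is
#'     forced to "unspecified".}
#'   \item{endorser}{President, mayor, national medical association
#'     (baseline), religious leader, left- or right-leaning newspaper.}
#'   \item{distributor}{public healthcare system (baseline), military,
#'     civil society.}
#'   \item{uptake}{community uptake already vaccinated: 1, 25, 50, 75
#'     percent, or unspecified.}
#' }
#' Any level named in `unspecified_level` may be assigned only in round 1,
#' so that a respondent never sees "no information" on a dimension after
#' having seen specific information on it in an earlier round.
#'
#' @param config A list describing the dimensions (see [build_catalog()]),
#'   or `NULL` for the default catalog.
#' @name attribute_catalog
NULL

.dimension_names <- c("producer", "efficacy_shown", "endorser",
                      "distributor", "uptake")

default_catalog_config <- function() {
  list(
    producer = list(
      levels = c("pfizer", "astrazeneca", "gamaleya", "sinovac",
                 "unspecified"),
      baseline = "unspecified",
      unspecified_level = "unspecified",
      efficacy_map = c(pfizer = 95, astrazeneca = 70, gamaleya = 91,
                       sinovac = 50),
      display = c(pfizer = "Pfizer, based in the USA",
                  astrazeneca = "AstraZeneca-University of Oxford, based in the UK",
                  gamaleya = "the Gamaleya Institute, based in Russia",
                  sinovac = "Sinovac, based in China",
                  unspecified = "")
    ),
    efficacy_shown = list(
      levels = c("yes", "unspecified"),
      baseline = "unspecified",
      unspecified_level = "unspecified"
    ),
    endorser = list(
      levels = c("president", "mayor", "medical_association",
                 "religious_leader", "left_newspaper", "right_newspaper"),
      baseline = "medical_association",
      display = c(president = "the President",
                  mayor = "the mayor of your municipality",
                  medical_association = "the national medical association",
                  religious_leader = "religious leader",
                  left_newspaper = "a left-leaning newspaper",
                  right_newspaper = "a right-leaning newspaper")
    ),
    distributor = list(
      levels = c("healthcare_system", "military", "civil_society"),
      baseline = "healthcare_system",
      display = c(healthcare_system = "the public healthcare system",
                  military = "the military",
                  civil_society = "civil society organizations")
    ),
    uptake = list(
      levels = c("1", "25", "50", "75", "unspecified"),
      baseline = "unspecified",
      unspecified_level = "unspecified"
    )
  )
}

#' Build and validate an attribute catalog
#'
#' @param config A named list with one entry per dimension. Each entry is a
#'   list with elements `levels` (character), `baseline` (one of the
#'   levels), optional `unspecified_level` (a level that may appear only in
#'   round 1), optional `probs` (named assignment probabilities over
#'   levels; uniform when omitted), optional `display` (named display
#'   labels), optional `country_display` (named list: country -> named
#'   label vector overriding `display`), and for the producer dimension an
#'   `efficacy_map` (named numeric, percent efficacy per specified
#'   producer). Omitted dimensions are filled from the default catalog.
#'   `NULL` gives the default catalog reproducing the study design.
#'
#' @return An object of class `attribute_catalog`: a named list of
#'   validated dimension descriptions.
#' @examples
#' cat5 <- build_catalog()
#' length(cat5$producer$levels)   # 5
#' @export
build_catalog <- function(config = NULL) {
  defaults <- default_catalog_config()
  if (is.null(config)) config <- defaults
  if (!is.list(config) || is.null(names(config))) {
    stop("catalog config must be a named list of dimensions")
  }
  missing_dims <- setdiff(.dimension_names, names(config))
  for (d in missing_dims) config[[d]] <- defaults[[d]]
  extra <- setdiff(names(config), .dimension_names)
  if (length(extra)) {
    stop("unknown dimension(s): ", paste(extra, collapse = ", "))
  }
  config <- config[.dimension_names]

  for (d in .dimension_names) {
    dim <- config[[d]]
    if (is.null(dim$levels) || length(dim$levels) < 1) {
      stop("dimension '", d, "': no levels supplied")
    }
    dim$levels <- as.character(dim$levels)
    if (anyDuplicated(dim$levels)) {
      stop("dimension '", d, "': duplicate level labels")
    }
    if (is.null(dim$baseline)) dim$baseline <- dim$levels[[1L]]
    if (!dim$baseline %in% dim$levels) {
      stop("dimension '", d, "': baseline '", dim$baseline,
           "' is not one of its levels")
    }
    if (!is.null(dim$unspecified_level) &&
        !dim$unspecified_level %in% dim$levels) {
      stop("dimension '", d, "': unspecified_level '",
           dim$unspecified_level, "' is not one of its levels")
    }
    if (is.null(dim$probs)) {
      dim$probs <- stats::setNames(rep(1 / length(dim$levels),
                                       length(dim$levels)), dim$levels)
    } else {
      dim$probs <- unlist(dim$probs)
      if (!setequal(names(dim$probs), dim$levels) ||
          any(dim$probs <= 0)) {
        stop("dimension '", d,
             "': probs must be positive and named by every level")
      }
      dim$probs <- dim$probs[dim$levels] / sum(dim$probs)
    }
    if (d == "producer") {
      specified <- setdiff(dim$levels, dim$unspecified_level)
      if (is.null(dim$efficacy_map)) {
        stop("dimension 'producer': efficacy_map required")
      }
      dim$efficacy_map <- unlist(dim$efficacy_map)
      if (!setequal(names(dim$efficacy_map), specified)) {
        stop("dimension 'producer': efficacy_map must cover every ",
             "specified producer and no unspecified one")
      }
    }
    config[[d]] <- dim
  }
  structure(config, class = "attribute_catalog")
}

#' Read an attribute catalog from a JSON or YAML file
#'
#' @param path Path to a JSON (`.json`) or YAML (`.yml`/`.yaml`) file with
#'   the [build_catalog()] schema.
#' @return An `attribute_catalog`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  config <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yml = ,
    yaml = yaml::read_yaml(path),
    stop("unsupported catalog format: .", ext)
  )
  build_catalog(config)
}

#' @export
print.attribute_catalog <- function(x, ...) {
  cat("Attribute catalog:", length(x), "dimensions\n")
  for (d in names(x)) {
    r1 <- if (is.null(x[[d]]$unspecified_level)) "" else
      paste0(" ['", x[[d]]$unspecified_level, "' round 1 only]")
    cat(sprintf("  %-15s %s (baseline %s)%s\n", d,
                paste(x[[d]]$levels, collapse = ", "),
                x[[d]]$baseline, r1))
  }
  invisible(x)
}

#' Levels of a dimension available in a given round
#'
#' Unspecified pure-control levels are available only in round 1.
#'
#' @param catalog An `attribute_catalog`.
#' @param dimension Dimension name.
#' @param round Round index (integer >= 1).
#' @return Character vector of assignable levels.
#' @export
levels_available <- function(catalog, dimension, round) {
  dim <- catalog[[dimension]]
  if (is.null(dim)) stop("unknown dimension: ", dimension)
  if (round > 1 && !is.null(dim$unspecified_level)) {
    setdiff(dim$levels, dim$unspecified_level)
  } else {
    dim$levels
  }
}

# Is this level the dimension's unspecified (round-1-only) level?
is_unspecified <- function(catalog, dimension, level) {
  u <- catalog[[dimension]]$unspecified_level
  !is.null(u) && level == u
}

#' Treatment dummy layout implied by a catalog
#'
#' Lists, in a fixed order, the non-baseline treatment terms of the AMCE
#' regression: one dummy per non-baseline level of each dimension except
#' `efficacy_shown`, whose disclosure enters as one producer-by-efficacy
#' interaction dummy per specified producer.
#'
#' @param catalog An `attribute_catalog`.
#' @return A data.frame with columns `term`, `dimension`, `level`,
#'   `baseline`.
#' @export
catalog_terms <- function(catalog) {
  rows <- list()
  prod <- catalog$producer
  prod_spec <- setdiff(prod$levels, prod$unspecified_level)
  nonbase <- setdiff(prod$levels, prod$baseline)
  for (l in nonbase) {
    rows[[length(rows) + 1L]] <- data.frame(
      term = paste0("producer_", l), dimension = "producer", level = l,
      baseline = prod$baseline, stringsAsFactors = FALSE)
  }
  if ("yes" %in% catalog$efficacy_shown$levels) {
    for (l in prod_spec) {
      rows[[length(rows) + 1L]] <- data.frame(
        term = paste0("producer_", l, "_x_efficacy"),
        dimension = "producer_x_efficacy", level = l,
        baseline = catalog$efficacy_shown$baseline,
        stringsAsFactors = FALSE)
    }
  }
  for (d in c("endorser", "distributor", "uptake")) {
    dim <- catalog[[d]]
    for (l in setdiff(dim$levels, dim$baseline)) {
      rows[[length(rows) + 1L]] <- data.frame(
        term = paste0(d, "_", l), dimension = d, level = l,
        baseline = dim$baseline, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
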