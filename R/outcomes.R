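#' Construct analysis outcomes from raw per-round responses
#'
#' Builds the estimation outcomes from raw survey responses: a binary
#' willingness indicator, a reversed months-to-wait outcome (so that
#' positive coefficients always imply greater willingness), the four
#' mechanism agreement items passed through unchanged, and the
#' pre-treatment immediacy controls attached per respondent.
#'
#' @details
#' `willing` may be 0/1, logical, `"yes"`/`"no"`, or a 5-point agreement
#' item; a 5-point item is dichotomized as agree/strongly agree (4-5) -> 1,
#' configurable via `binary_cut`. Months must be nonnegative wherever
#' willingness is observed. Pre-treatment controls: `ypre_willing` is the
#' respondent's prior 5-point willingness and `ypre_months` the negative of
#' the prior intended wait, each the lagged analogue of its outcome.
#'
#' @param raw data.frame with per-round columns `willing`, `months`, and
#'   optionally `mech_spread`, `mech_nocovid`, `mech_noside`, `mech_govt`,
#'   plus respondent-level `prior_willingness` (1-5) and `prior_wait`
#'   (months).
#' @param binary_cut Minimum 5-point response coded as willing (default 4).
#' @return `raw` with `y_willing`, `y_months`, `ypre_willing`,
#'   `ypre_months` columns added.
#' @export
build_outcomes <- function(raw, binary_cut = 4) {
  w <- raw$willing
  if (is.null(w)) stop("raw responses must contain a 'willing' column")
  if (is.logical(w)) {
    y <- as.integer(w)
  } else if (is.character(w) || is.factor(w)) {
    w <- tolower(as.character(w))
    if (!all(w %in% c("yes", "no", NA))) {
      stop("character 'willing' must be yes/no")
    }
    y <- ifelse(w == "yes", 1L, 0L)
  } else if (all(w %in% c(0, 1, NA))) {
    y <- as.integer(w)
  } else if (all(w %in% c(1:5, NA))) {
    y <- as.integer(w >= binary_cut)
  } else {
    stop("'willing' must be binary, yes/no, or a 1-5 item")
  }
  m <- raw$months
  if (is.null(m)) stop("raw responses must contain a 'months' column")
  bad <- which(!is.na(y) & (is.na(m) | m < 0))
  if (length(bad)) {
    stop("row ", bad[1], ": months missing or negative where willingness ",
         "is observed")
  }
  raw$y_willing <- y
  raw$y_months <- -m
  if (!is.null(raw$prior_willingness)) {
    raw$ypre_willing <- as.numeric(raw$prior_willingness)
  }
  if (!is.null(raw$prior_wait)) raw$ypre_months <- -as.numeric(raw$prior_wait)
  raw
}

#' Mechanism outcome columns
#'
#' Names of the four post-treatment mechanism agreement items: the vaccine
#' would end the spread of COVID-19 quickly; the respondent would be
#' unlikely to contract COVID-19; side effects would be unlikely; the
#' government's vaccination program is meant to help its citizens.
#'
#' @return Character vector of column names.
#' @export
mechanism_outcomes <- function() {
  c("mech_spread", "mech_nocovid", "mech_noside", "mech_govt")
}
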