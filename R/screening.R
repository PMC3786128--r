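#' Classify a participant into the four screening categories
#'
#' Risk classification uses only the AUDIT-C consumption subscale (0-12):
#' participants who report no alcohol in the past 12 months are
#' `nondrinker_12m`; an AUDIT-C below 5 screens negative; 5-9 screens
#' positive for hazardous or harmful drinking (the trial-eligible band,
#' chosen for high specificity with good sensitivity at the lower cut and a
#' high probability of dependence above 9); 10-12 indicates possible
#' alcohol dependence.
#'
#' @param drank_past_12m logical 12-month drinking gate.
#' @param audit_c AUDIT-C score 0-12; must be `NULL` when `drank_past_12m`
#'   is `FALSE` and present when `TRUE`.
#' @return list of class `esbi_screening` with `category` (one of
#'   `"nondrinker_12m"`, `"negative"`, `"hazardous_harmful"`,
#'   `"possible_dependence"`), `audit_c`, and `trial_eligible` (`TRUE` iff
#'   hazardous/harmful).
#' @export
#' @examples
#' classify(TRUE, 4)$category    # "negative"
#' classify(TRUE, 5)$trial_eligible
#' classify(FALSE, NULL)$category
classify <- function(drank_past_12m, audit_c = NULL) {
  if (!is_flag(drank_past_12m)) {
    esbi_stop("drank_past_12m must be TRUE or FALSE", "esbi_validation_error")
  }
  if (!drank_past_12m) {
    if (!is.null(audit_c)) {
      esbi_stop("audit_c must be absent for a 12-month nondrinker",
                "esbi_validation_error")
    }
    category <- "nondrinker_12m"
    audit_c <- NA_integer_
  } else {
    if (is.null(audit_c) || !is_count(audit_c) || audit_c > 12) {
      esbi_stop("audit_c must be an integer in 0-12 for a drinker",
                "esbi_range_error")
    }
    category <- if (audit_c < 5) "negative"
    else if (audit_c <= 9) "hazardous_harmful"
    else "possible_dependence"
  }
  structure(
    list(category = category, audit_c = audit_c,
         trial_eligible = identical(category, "hazardous_harmful")),
    class = "esbi_screening"
  )
}

#' Screening categories in flow order
#' @return character vector of the four category labels.
#' @export
screening_categories <- function() {
  c("nondrinker_12m", "negative", "hazardous_harmful", "possible_dependence")
}

#' Screen a batch of response records
#'
#' Scores each record and applies [classify()], yielding one row per
#' participant for CSV export.
#'
#' @param records list of [response_record()]s.
#' @param defs instrument definitions from [instrument_defs()].
#' @return data frame with columns `participant_id`, `audit_c`, `category`,
#'   `trial_eligible`.
#' @export
screen_records <- function(records, defs = instrument_defs()) {
  rows <- lapply(records, function(rec) {
    sc <- score_record(rec, defs)
    res <- classify(rec$drank_past_12m,
                    if (is.null(sc)) NULL else sc$audit_c)
    data.frame(participant_id = rec$participant_id,
               audit_c = res$audit_c,
               category = res$category,
               trial_eligible = res$trial_eligible,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
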