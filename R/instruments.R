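#' Load questionnaire instrument definitions
#'
#' Instruments (AUDIT, LDQ, trauma screen, 12-month gate) are shipped as an
#' editable YAML file so wording changes never touch code. Each item carries
#' its option labels and per-option integer scores; responses are 0-based
#' option indices into those lists.
#'
#' @param path path to an instrument-definition YAML file; default is the
#'   copy installed with the package.
#' @return named list of instrument definitions (class `esbi_instruments`);
#'   each element has `id`, `items` (with `text`, `options`, `scores`) and
#'   optionally `placeholder`.
#' @export
#' @examples
#' defs <- instrument_defs()
#' length(defs$AUDIT$items)  # 10
instrument_defs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "instruments.yaml", package = "esbi")
  }
  if (!file.exists(path)) {
    esbi_stop(sprintf("instrument definition file not found: %s", path),
              "esbi_config_error")
  }
  raw <- yaml::read_yaml(path)
  defs <- stats::setNames(raw$instruments,
                          vapply(raw$instruments, `[[`, "", "id"))
  validate_instrument_defs(defs)
  structure(defs, class = "esbi_instruments")
}

validate_instrument_defs <- function(defs) {
  for (def in defs) {
    for (i in seq_along(def$items)) {
      item <- def$items[[i]]
      if (length(item$options) != length(item$scores)) {
        esbi_stop(sprintf("%s item %d: options/scores length mismatch",
                          def$id, i), "esbi_config_error")
      }
      sc <- unlist(item$scores)
      if (any(sc < 0) || any(sc != trunc(sc))) {
        esbi_stop(sprintf("%s item %d: scores must be non-negative integers",
                          def$id, i), "esbi_config_error")
      }
    }
  }
  stopifnot(
    length(defs$AUDIT$items) == 10L,
    length(defs$LDQ$items) == 10L,
    length(defs$TRAUMA$items) == 5L
  )
  invisible(defs)
}

# Map 0-based option indices to scores for one instrument; errors name the
# offending item. No imputation: a missing item is an error, never prorated.
score_items <- function(def, indices, instrument) {
  n <- length(def$items)
  if (length(indices) != n || anyNA(indices)) {
    bad <- if (length(indices) != n) "wrong length" else
      paste("missing item(s)", paste(which(is.na(indices)), collapse = ", "))
    esbi_stop(sprintf("%s responses: expected %d answered items (%s)",
                      instrument, n, bad), "esbi_validation_error")
  }
  scores <- integer(n)
  for (i in seq_len(n)) {
    opts <- unlist(def$items[[i]]$scores)
    idx <- indices[i]
    if (!is_count(idx) || idx >= length(opts)) {
      esbi_stop(sprintf("%s item %d: option index %s out of range 0-%d",
                        instrument, i, format(idx), length(opts) - 1L),
                "esbi_validation_error")
    }
    scores[i] <- opts[idx + 1L]
  }
  scores
}

#' Score the 10-item AUDIT and its AUDIT-C consumption subscale
#'
#' The AUDIT total is the sum of per-option scores over all ten items
#' (0-40). AUDIT-C, used for risk classification, is the sum over the first
#' three consumption items only (0-12).
#'
#' @param audit_items integer vector of 10 zero-based option indices
#'   (items 1-8 take 0-4, items 9-10 take 0-2 scoring 0/2/4).
#' @param defs instrument definitions from [instrument_defs()].
#' @return list with integer `audit_total` and `audit_c`.
#' @export
#' @examples
#' score_audit(c(2, 3, 1, 0, 0, 1, 0, 0, 2, 0))
score_audit <- function(audit_items, defs = instrument_defs()) {
  s <- score_items(defs$AUDIT, audit_items, "AUDIT")
  list(audit_total = sum(s), audit_c = sum(s[1:3]))
}

#' Score the Leeds Dependence Questionnaire
#'
#' Ten items each scored 0-3; the total (0-30) indexes severity of alcohol
#' dependence.
#'
#' @param ldq_items integer vector of 10 zero-based option indices (0-3).
#' @param defs instrument definitions from [instrument_defs()].
#' @return integer total 0-30.
#' @export
score_ldq <- function(ldq_items, defs = instrument_defs()) {
  sum(score_items(defs$LDQ, ldq_items, "LDQ"))
}

#' Score the 5-item history-of-trauma screen
#'
#' The count of affirmative answers, 0-5. The shipped item wording and this
#' scoring rule are placeholders written for this engine (see
#' `instruments.yaml`).
#'
#' @param trauma_items integer vector of 5 zero-based indices (0 = no,
#'   1 = yes) or a logical vector of length 5.
#' @param defs instrument definitions from [instrument_defs()].
#' @return integer count of affirmative answers.
#' @export
score_trauma <- function(trauma_items, defs = instrument_defs()) {
  if (is.logical(trauma_items)) trauma_items <- as.integer(trauma_items)
  sum(score_items(defs$TRAUMA, trauma_items, "TRAUMA"))
}

#' Score all instruments in a response record
#'
#' @param record a [response_record()].
#' @param defs instrument definitions from [instrument_defs()].
#' @return list of class `esbi_scores` with `audit_total`, `audit_c`,
#'   `ldq_total`, `trauma_total`, or `NULL` when the participant was gated
#'   out by the 12-month question.
#' @export
score_record <- function(record, defs = instrument_defs()) {
  if (!isTRUE(record$drank_past_12m)) return(NULL)
  a <- score_audit(record$audit_items, defs)
  structure(
    list(audit_total = a$audit_total, audit_c = a$audit_c,
         ldq_total = score_ldq(record$ldq_items, defs),
         trauma_total = score_trauma(record$trauma_items, defs)),
    class = "esbi_scores"
  )
}

#' Construct a participant response record
#'
#' One participant's item-level answers across the survey pages. For a
#' participant who reports no alcohol in the past 12 months all instrument
#' answers must be absent (`NULL`).
#'
#' @param participant_id opaque identifier string.
#' @param gender `"male"` or `"female"`.
#' @param age_years integer age, 18 or older.
#' @param postcode postcode string.
#' @param drank_past_12m logical 12-month drinking gate.
#' @param audit_items,ldq_items,trauma_items zero-based option indices
#'   (lengths 10, 10, 5) or `NULL` when gated out.
#' @param episode list with `max_drinks` (standard drinks in the heaviest
#'   occasion of the last 4 weeks), `duration_hours`, `weight_kg`, or `NULL`.
#' @param email optional email address string.
#' @return list of class `esbi_response_record`.
#' @export
response_record <- function(participant_id, gender, age_years, postcode = "",
                            drank_past_12m = FALSE, audit_items = NULL,
                            episode = NULL, ldq_items = NULL,
                            trauma_items = NULL, email = NULL) {
  structure(
    list(participant_id = participant_id, gender = gender,
         age_years = age_years, postcode = postcode,
         drank_past_12m = drank_past_12m, audit_items = audit_items,
         episode = episode, ldq_items = ldq_items,
         trauma_items = trauma_items, email = email),
    class = "esbi_response_record"
  )
}

#' @export
print.esbi_response_record <- function(x, ...) {
  cat(sprintf("<response record %s: %s, %d y, drank past 12 m: %s>\n",
              x$participant_id, x$gender, x$age_years, x$drank_past_12m))
  invisible(x)
}

violation <- function(field, rule) {
  data.frame(field = field, rule = rule, stringsAsFactors = FALSE)
}

#' Validate a response record against its invariants
#'
#' Checks demographics (adult age, known gender), the 12-month gate rule
#' (no instrument answers for non-drinkers; all instrument answers present
#' for drinkers), option-index ranges, and episode-report consistency.
#' Violations are returned, not thrown.
#'
#' @param record a [response_record()].
#' @param defs instrument definitions from [instrument_defs()].
#' @return data frame with columns `field` and `rule`; zero rows when the
#'   record is valid.
#' @export
validate_record <- function(record, defs = instrument_defs()) {
  v <- violation(character(0), character(0))
  if (!is_string(record$participant_id) || !nzchar(record$participant_id)) {
    v <- rbind(v, violation("participant_id", "must be a non-empty string"))
  }
  if (!is_string(record$gender) || !record$gender %in% c("male", "female")) {
    v <- rbind(v, violation("gender", "must be 'male' or 'female'"))
  }
  if (!is_count(record$age_years) || record$age_years < 18) {
    v <- rbind(v, violation("age_years", "must be an integer >= 18 (adult eligibility)"))
  }
  if (!is_flag(record$drank_past_12m)) {
    v <- rbind(v, violation("drank_past_12m", "must be TRUE or FALSE"))
    return(v)
  }
  downstream <- c("audit_items", "episode", "ldq_items", "trauma_items")
  if (!record$drank_past_12m) {
    for (f in downstream) {
      if (!is.null(record[[f]])) {
        v <- rbind(v, violation(f, "must be absent when drank_past_12m is FALSE (gate rule)"))
      }
    }
    return(v)
  }
  for (f in downstream) {
    if (is.null(record[[f]])) {
      v <- rbind(v, violation(f, "must be present when drank_past_12m is TRUE"))
    }
  }
  check_idx <- function(field, def, items) {
    if (is.null(items)) return()
    if (length(items) != length(def$items)) {
      v <<- rbind(v, violation(field, sprintf("expected %d items", length(def$items))))
      return()
    }
    for (i in seq_along(items)) {
      nopt <- length(def$items[[i]]$options)
      if (is.na(items[i]) || items[i] < 0 || items[i] >= nopt ||
          items[i] != trunc(items[i])) {
        v <<- rbind(v, violation(sprintf("%s[%d]", field, i),
                                 sprintf("option index must be an integer in 0-%d", nopt - 1L)))
      }
    }
  }
  check_idx("audit_items", defs$AUDIT, record$audit_items)
  check_idx("ldq_items", defs$LDQ, record$ldq_items)
  check_idx("trauma_items", defs$TRAUMA, record$trauma_items)
  if (!is.null(record$episode)) {
    ep <- record$episode
    if (!is.numeric(ep$max_drinks) || is.na(ep$max_drinks) ||
        !is.finite(ep$max_drinks) || ep$max_drinks < 0) {
      v <- rbind(v, violation("episode$max_drinks", "must be a finite number >= 0"))
    } else if (ep$max_drinks > 0 &&
               (!is.numeric(ep$duration_hours) || is.na(ep$duration_hours) ||
                !is.finite(ep$duration_hours) || ep$duration_hours <= 0)) {
      v <- rbind(v, violation("episode$duration_hours",
                              "must be a finite number > 0 when drinks > 0"))
    }
    if (!is.numeric(ep$weight_kg) || is.na(ep$weight_kg) ||
        !is.finite(ep$weight_kg) || ep$weight_kg <= 0) {
      v <- rbind(v, violation("episode$weight_kg", "must be a finite number > 0"))
    }
  }
  if (!is.null(record$email) && !grepl("^[^@[:space:]]+@[^@[:space:]]+\\.[^@[:space:]]+$",
                                       record$email)) {
    v <- rbind(v, violation("email", "must be a syntactically valid address"))
  }
  v
}
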