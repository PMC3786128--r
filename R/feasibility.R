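#' @title Feasibility metrics for a recruitment episode
#' @description
#' Summaries of the participant-flow tree (approached -> consented ->
#' eligible -> completed -> followed-up): counts with percentages, the
#' screening-outcome mix, completion with a noncompletion-reason breakdown,
#' retention overall and by subgroup, and acceptability crosstabs. All
#' percentages are `100 * count / denominator` rounded half-up — one
#' decimal for flow percentages, whole numbers for acceptability and
#' retention tables. Ratios with a zero denominator are reported as `NA`
#' (undefined), never 0 or 100.
#'
#' Flow-event records are rows of a data frame with columns
#' `participant_id`, `approached`, `consented`, `eligible` (`NA` when never
#' assessed, i.e. refusers), `completed_esbi`, `noncompletion_reason`
#' (`"technical"`, `"called_for_appointment"` or `"none"`), `category`
#' (screening category for completers), `invited_followup`,
#' `completed_followup`, plus any number of acceptability answer columns
#' prefixed `accept_` and follow-up answer columns prefixed `fu_`.
#' @name feasibility
NULL

#' Validate flow-event records
#'
#' Checks the flow invariants: consent implies approach, completion implies
#' consent and eligibility, follow-up completion implies invitation, a
#' screening category present exactly for completers, and a noncompletion
#' reason exactly for eligible noncompleters.
#'
#' @param records flow-event data frame (see [feasibility]).
#' @return `records` invisibly; invariant violations raise a validation
#'   error listing the offending participants.
#' @export
validate_flow_records <- function(records) {
  need <- c("participant_id", "approached", "consented", "eligible",
            "completed_esbi", "noncompletion_reason", "category",
            "invited_followup", "completed_followup")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    esbi_stop(paste("flow records missing columns:", paste(miss, collapse = ", ")),
              "esbi_validation_error")
  }
  bad <- function(cond) records$participant_id[which(cond)]
  problems <- c(
    if (length(p <- bad(records$consented & !records$approached)))
      paste("consented but not approached:", paste(p, collapse = ", ")),
    if (length(p <- bad(records$completed_esbi %in% TRUE &
                        !(records$consented & records$eligible %in% TRUE))))
      paste("completed but not eligible/consented:", paste(p, collapse = ", ")),
    if (length(p <- bad(records$completed_followup %in% TRUE &
                        !(records$invited_followup %in% TRUE))))
      paste("followed-up but not invited:", paste(p, collapse = ", ")),
    if (length(p <- bad(!is.na(records$category) &
                        !(records$completed_esbi %in% TRUE))))
      paste("category without completion:", paste(p, collapse = ", ")),
    if (length(p <- bad(records$completed_esbi %in% FALSE &
                        records$noncompletion_reason %in% "none")))
      paste("eligible noncompleter without a reason:", paste(p, collapse = ", "))
  )
  if (length(problems)) {
    esbi_stop(paste("flow-record invariant violations:",
                    paste(problems, collapse = "; ")), "esbi_validation_error")
  }
  invisible(records)
}

eligible_mask <- function(records) {
  records$consented & records$eligible %in% TRUE
}

#' Recruitment summary: approach outcomes and screening mix
#'
#' Counts and percentages for the approach outcomes (consented, refused,
#' ineligible at approach), post-consent eligibility, and the five outcomes
#' among eligible consenting participants: noncompletion, 12-month
#' nondrinker, screen negative (AUDIT-C < 5), hazardous/harmful (5-9) and
#' possible dependence (10-12), plus the combined unhealthy-use proportion
#' (AUDIT-C >= 5). Flow percentages use one decimal.
#'
#' @param records flow-event data frame (see [feasibility]).
#' @return list of class `esbi_recruitment_summary` with `counts` and
#'   `percentages`.
#' @export
recruitment_summary <- function(records) {
  validate_flow_records(records)
  if (nrow(records) == 0) {
    return(structure(list(counts = list(approached = 0L),
                          percentages = list()),
                     class = "esbi_recruitment_summary"))
  }
  n_approached <- sum(records$approached)
  n_consented <- sum(records$consented)
  n_refused <- sum(records$approached & !records$consented &
                     !(records$eligible %in% FALSE))
  n_inelig_approach <- sum(!records$consented & records$eligible %in% FALSE)
  n_inelig_consent <- sum(records$consented & records$eligible %in% FALSE)
  elig <- eligible_mask(records)
  n_eligible <- sum(elig)
  n_noncomplete <- sum(elig & records$completed_esbi %in% FALSE)
  cat_counts <- vapply(screening_categories(), function(cc) {
    sum(elig & records$completed_esbi %in% TRUE & records$category %in% cc)
  }, integer(1))
  n_unhealthy <- cat_counts[["hazardous_harmful"]] +
    cat_counts[["possible_dependence"]]
  counts <- c(list(approached = n_approached, consented = n_consented,
                   refused = n_refused,
                   ineligible_at_approach = n_inelig_approach,
                   ineligible_post_consent = n_inelig_consent,
                   eligible = n_eligible, noncompleted = n_noncomplete),
              as.list(cat_counts), list(unhealthy_use = n_unhealthy))
  percentages <- list(
    consented = pct(n_consented, n_approached),
    refused = pct(n_refused, n_approached),
    ineligible_at_approach = pct(n_inelig_approach, n_approached),
    ineligible_post_consent = pct(n_inelig_consent, n_consented),
    noncompleted = pct(n_noncomplete, n_eligible),
    nondrinker_12m = pct(cat_counts[["nondrinker_12m"]], n_eligible),
    negative = pct(cat_counts[["negative"]], n_eligible),
    hazardous_harmful = pct(cat_counts[["hazardous_harmful"]], n_eligible),
    possible_dependence = pct(cat_counts[["possible_dependence"]], n_eligible),
    unhealthy_use = pct(n_unhealthy, n_eligible)
  )
  structure(list(counts = counts, percentages = percentages),
            class = "esbi_recruitment_summary")
}

#' Intervention completion rate with reason breakdown
#'
#' Proportion of eligible consenting participants who completed the
#' program (one decimal), and among noncompleters the split by reason
#' (whole-number percentages). Reasons partition the noncompleters.
#'
#' @param records flow-event data frame.
#' @return list with `n_eligible`, `n_completed`, `completion_pct`, and a
#'   `reasons` data frame (`reason`, `n`, `pct`).
#' @export
completion_rate <- function(records) {
  validate_flow_records(records)
  elig <- eligible_mask(records)
  n_eligible <- sum(elig)
  n_completed <- sum(elig & records$completed_esbi %in% TRUE)
  nc <- records[elig & records$completed_esbi %in% FALSE, , drop = FALSE]
  reasons <- if (nrow(nc) == 0) {
    data.frame(reason = character(0), n = integer(0), pct = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    tab <- table(nc$noncompletion_reason)
    data.frame(reason = names(tab), n = as.integer(tab),
               pct = pct(as.integer(tab), nrow(nc), digits = 0),
               stringsAsFactors = FALSE)
  }
  list(n_eligible = n_eligible, n_completed = n_completed,
       completion_pct = pct(n_completed, n_eligible), reasons = reasons)
}

#' Follow-up retention rate
#'
#' Proportion of invited participants who completed the follow-up
#' assessment, optionally within a screening-category subgroup.
#' Whole-number percentage; an empty subgroup yields `NA` (undefined).
#'
#' @param records flow-event data frame.
#' @param categories optional character vector of screening categories to
#'   restrict to (e.g. `"hazardous_harmful"`).
#' @return list with `n_invited`, `n_completed`, `retention_pct`.
#' @export
retention_rate <- function(records, categories = NULL) {
  validate_flow_records(records)
  sel <- records$invited_followup %in% TRUE
  if (!is.null(categories)) sel <- sel & records$category %in% categories
  n_invited <- sum(sel)
  n_completed <- sum(sel & records$completed_followup %in% TRUE)
  list(n_invited = n_invited, n_completed = n_completed,
       retention_pct = pct(n_completed, n_invited, digits = 0))
}

#' Acceptability crosstab
#'
#' Question-by-option-by-category counts with column percentages for the
#' acceptability answers of drinkers who completed the program (the group
#' the acceptability questionnaire was administered to). The percentage
#' denominator is the number of completing drinkers in the category, so
#' unanswered questions still count in the denominator, and column counts
#' of answered plus missing equal the category totals.
#'
#' @param records flow-event data frame with `accept_`-prefixed answer
#'   columns.
#' @param questions which questions to tabulate; default all `accept_`
#'   columns.
#' @return data frame with columns `question`, `option`, `category`, `n`,
#'   `denominator`, `pct` (whole numbers); an attribute
#'   `"category_totals"` carries the per-category denominators.
#' @export
acceptability_table <- function(records, questions = NULL) {
  validate_flow_records(records)
  if (is.null(questions)) {
    questions <- grep("^accept_", names(records), value = TRUE)
  }
  drinkers <- records$completed_esbi %in% TRUE &
    !(records$category %in% "nondrinker_12m")
  cats <- c(setdiff(screening_categories(), "nondrinker_12m"), "all_drinkers")
  totals <- c(vapply(setdiff(cats, "all_drinkers"),
                     function(cc) sum(drinkers & records$category %in% cc),
                     integer(1)),
              all_drinkers = sum(drinkers))
  rows <- list()
  for (q in questions) {
    ans <- records[[q]]
    opts <- unique(stats::na.omit(ans[drinkers]))
    opts <- if (is.factor(ans)) levels(ans) else sort(opts)
    for (cc in cats) {
      in_cat <- if (cc == "all_drinkers") drinkers else
        drinkers & records$category %in% cc
      den <- totals[[cc]]
      for (o in opts) {
        n <- sum(in_cat & ans %in% o)
        rows[[length(rows) + 1L]] <- data.frame(
          question = q, option = as.character(o), category = cc,
          n = n, denominator = den, pct = pct(n, den, digits = 0),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(question = character(0), option = character(0),
               category = character(0), n = integer(0),
               denominator = integer(0), pct = numeric(0))
  attr(out, "category_totals") <- totals
  out
}

#' Median with 25th and 75th percentiles
#'
#' The quartile convention is linear interpolation between order statistics
#' (`stats::quantile()` type 7, the R default); it is configurable because
#' different statistical packages disagree on quartiles of small samples.
#'
#' @param values non-empty numeric vector (`NA`s removed).
#' @param type quantile algorithm passed to [stats::quantile()].
#' @return named numeric vector `median`, `q25`, `q75`.
#' @export
#' @examples
#' median_iqr(c(1, 2, 3, 4, 5))
median_iqr <- function(values, type = 7) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    esbi_stop("median_iqr requires a non-empty numeric vector",
              "esbi_validation_error")
  }
  q <- stats::quantile(values, probs = c(0.5, 0.25, 0.75), type = type,
                       names = FALSE)
  c(median = q[1], q25 = q[2], q75 = q[3])
}

#' Full cohort summary
#'
#' Bundles the recruitment, completion, retention and acceptability
#' summaries, and — when item-level responses are supplied — per-category
#' medians (25th, 75th percentiles) of the AUDIT and LDQ scores.
#'
#' @param records flow-event data frame.
#' @param responses optional list of [response_record()]s for score medians.
#' @param defs instrument definitions from [instrument_defs()].
#' @return list of class `esbi_cohort_summary`.
#' @export
cohort_summary <- function(records, responses = NULL,
                           defs = instrument_defs()) {
  out <- list(
    recruitment = recruitment_summary(records),
    completion = completion_rate(records),
    retention = list(
      overall = retention_rate(records),
      hazardous_harmful = retention_rate(records, "hazardous_harmful")
    ),
    acceptability = acceptability_table(records)
  )
  if (!is.null(responses)) {
    scr <- screen_records(responses, defs)
    sc <- lapply(responses, score_record, defs = defs)
    tot <- vapply(sc, function(s) if (is.null(s)) NA_real_ else s$audit_total, 0)
    ldq <- vapply(sc, function(s) if (is.null(s)) NA_real_ else s$ldq_total, 0)
    meds <- lapply(split(seq_along(responses), scr$category), function(ii) {
      list(audit = if (all(is.na(tot[ii]))) NULL else median_iqr(tot[ii]),
           ldq = if (all(is.na(ldq[ii]))) NULL else median_iqr(ldq[ii]))
    })
    out$score_medians <- meds
  }
  structure(out, class = "esbi_cohort_summary")
}

#' @export
print.esbi_recruitment_summary <- function(x, ...) {
  cts <- x$counts
  pc <- x$percentages
  fmt <- function(n, p) sprintf("%d (%s%%)", n, ifelse(is.na(p), "-", format(p)))
  cat("Recruitment\n")
  cat(sprintf("  approached             %d\n", cts$approached))
  if (is.null(cts$consented)) return(invisible(x))
  cat(sprintf("  consented              %s\n", fmt(cts$consented, pc$consented)))
  cat(sprintf("  refused                %s\n", fmt(cts$refused, pc$refused)))
  cat(sprintf("  ineligible at approach %s\n",
              fmt(cts$ineligible_at_approach, pc$ineligible_at_approach)))
  cat(sprintf("  eligible               %d\n", cts$eligible))
  cat("Screening outcomes (of eligible)\n")
  for (k in c("noncompleted", "nondrinker_12m", "negative",
              "hazardous_harmful", "possible_dependence", "unhealthy_use")) {
    cat(sprintf("  %-22s %s\n", k, fmt(cts[[k]], pc[[k]])))
  }
  invisible(x)
}
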