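#' @title Synthetic cohorts for testing and demonstration
#' @description
#' A seeded generator of item-level synthetic respondents plus flow-event
#' records with a requested screening-category mixture, so every module can
#' be exercised without patient data, and a deterministic fixture
#' reproducing the participant-flow counts of the hospital-outpatient pilot
#' recruitment episode used throughout the documentation and tests.
#' @name synthetic_cohort
NULL

#' Specification for a synthetic cohort
#'
#' Defaults emulate the observed pilot recruitment episode: consent 108/172
#' with 2/172 ineligible at approach, 2/108 ineligible after consent,
#' completion 99/106 with noncompletion reasons split 3:4
#' technical:called-away, completer screening mix 15/43/33/8
#' (nondrinker / negative / hazardous-harmful / possible dependence),
#' category-conditional gender and age mixtures, 4-week drinking (follow-up
#' invitation) probabilities 32/43, 30/33, 7/8 by drinker category, and
#' follow-up completion 26/32, 22/30, 4/7.
#'
#' @param n number of approached participants.
#' @param seed integer seed for the cohort's single pseudo-random stream.
#' @param category_mixture named probabilities over the four screening
#'   categories for completers; must sum to 1.
#' @param p_consent,p_ineligible_approach,p_ineligible_consent,p_complete
#'   flow probabilities.
#' @param reason_technical probability a noncompletion was technical (the
#'   rest were called for their appointment).
#' @param p_invite,p_followup named per-drinker-category probabilities of
#'   follow-up invitation (drank in the past 4 weeks) and completion.
#' @return list of class `esbi_cohort_spec`.
#' @export
cohort_spec <- function(n = 172, seed = 1,
                        category_mixture = c(nondrinker_12m = 15,
                                             negative = 43,
                                             hazardous_harmful = 33,
                                             possible_dependence = 8) / 99,
                        p_consent = 108 / 172,
                        p_ineligible_approach = 2 / 172,
                        p_ineligible_consent = 2 / 108,
                        p_complete = 99 / 106,
                        reason_technical = 3 / 7,
                        p_invite = c(negative = 32 / 43,
                                     hazardous_harmful = 30 / 33,
                                     possible_dependence = 7 / 8),
                        p_followup = c(negative = 26 / 32,
                                       hazardous_harmful = 22 / 30,
                                       possible_dependence = 4 / 7)) {
  probs <- c(category_mixture, p_consent, p_ineligible_approach,
             p_ineligible_consent, p_complete, reason_technical,
             p_invite, p_followup)
  if (any(probs < 0 | probs > 1)) {
    esbi_stop("all probabilities must lie in [0, 1]", "esbi_spec_error")
  }
  if (abs(sum(category_mixture) - 1) > 1e-8) {
    esbi_stop("category_mixture must sum to 1", "esbi_spec_error")
  }
  if (!setequal(names(category_mixture), screening_categories())) {
    esbi_stop("category_mixture must name the four screening categories",
              "esbi_spec_error")
  }
  if (!is_count(n) || !is.numeric(seed)) {
    esbi_stop("n must be a count and seed an integer", "esbi_spec_error")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 category_mixture = category_mixture, p_consent = p_consent,
                 p_ineligible_approach = p_ineligible_approach,
                 p_ineligible_consent = p_ineligible_consent,
                 p_complete = p_complete, reason_technical = reason_technical,
                 p_invite = p_invite, p_followup = p_followup),
            class = "esbi_cohort_spec")
}

# All (item1, item2, item3) score triples whose AUDIT-C sum falls in the
# category's range, found by enumerating the full 5^3 grid.
audit_c_triples <- function(category) {
  grid <- expand.grid(i1 = 0:4, i2 = 0:4, i3 = 0:4)
  s <- grid$i1 + grid$i2 + grid$i3
  keep <- switch(category,
                 negative = s < 5,
                 hazardous_harmful = s >= 5 & s <= 9,
                 possible_dependence = s >= 10,
                 esbi_stop(sprintf("no AUDIT-C triples for category '%s'", category),
                           "esbi_spec_error"))
  as.matrix(grid[keep, , drop = FALSE])
}

# Category-conditional option distributions for AUDIT items 4-10, LDQ and
# trauma. These couple severity monotonically across instruments; they are
# synthetic modelling choices, not empirical distributions.
severity_profiles <- list(
  negative = list(
    audit_mid = c(0.70, 0.20, 0.10, 0.00, 0.00),
    audit_tail = c(0.85, 0.10, 0.05),
    ldq = c(0.90, 0.08, 0.02, 0.00),
    trauma_yes = 0.10,
    drinks_range = 0:4
  ),
  hazardous_harmful = list(
    audit_mid = c(0.40, 0.30, 0.20, 0.10, 0.00),
    audit_tail = c(0.60, 0.25, 0.15),
    ldq = c(0.60, 0.25, 0.10, 0.05),
    trauma_yes = 0.25,
    drinks_range = 5:15
  ),
  possible_dependence = list(
    audit_mid = c(0.15, 0.20, 0.30, 0.20, 0.15),
    audit_tail = c(0.30, 0.35, 0.35),
    ldq = c(0.35, 0.30, 0.20, 0.15),
    trauma_yes = 0.40,
    drinks_range = 7:24
  )
)

# Category-conditional demographic mixtures mirroring the pilot cohort.
demographic_profiles <- list(
  nondrinker_12m = list(p_male = 4 / 15, age = c(4, 6, 5) / 15),
  negative = list(p_male = 16 / 43, age = c(11, 11, 21) / 43),
  hazardous_harmful = list(p_male = 26 / 33, age = c(14, 13, 6) / 33),
  possible_dependence = list(p_male = 7 / 8, age = c(4, 2, 2) / 8)
)

# Acceptability-answer distributions by drinker category (usefulness of the
# drinking feedback), mirroring the pilot acceptability table.
usefulness_profiles <- list(
  negative = c(very = 11, quite = 7, somewhat = 13, not_at_all = 12) / 43,
  hazardous_harmful = c(very = 6, quite = 11, somewhat = 10, not_at_all = 5) / 32,
  possible_dependence = c(very = 4, quite = 2, somewhat = 2, not_at_all = 0) / 8
)

sample_age <- function(group) {
  switch(group,
         `18-34` = sample(18:34, 1),
         `35-54` = sample(35:54, 1),
         `55+` = sample(55:85, 1))
}

synth_drinker_record <- function(id, category, profile) {
  demo <- demographic_profiles[[category]]
  gender <- if (stats::runif(1) < demo$p_male) "male" else "female"
  group <- sample(c("18-34", "35-54", "55+"), 1, prob = demo$age)
  triples <- audit_c_triples(category)
  tri <- triples[sample(nrow(triples), 1), ]
  audit <- c(tri,
             sample(0:4, 5, replace = TRUE, prob = profile$audit_mid),
             sample(0:2, 2, replace = TRUE, prob = profile$audit_tail))
  drank_4wk <- NA  # decided by the flow layer; episode reflects it there
  max_drinks <- sample(profile$drinks_range, 1)
  episode <- list(
    max_drinks = max_drinks,
    duration_hours = if (max_drinks > 0) round(stats::runif(1, 1, 8), 1) else 1,
    weight_kg = round(max(45, stats::rnorm(1, if (gender == "male") 85 else 70, 12)), 1)
  )
  response_record(
    participant_id = id, gender = gender, age_years = sample_age(group),
    postcode = sprintf("2%03d", sample(0:999, 1)),
    drank_past_12m = TRUE, audit_items = unname(audit), episode = episode,
    ldq_items = sample(0:3, 10, replace = TRUE, prob = profile$ldq),
    trauma_items = stats::rbinom(5, 1, profile$trauma_yes)
  )
}

synth_nondrinker_record <- function(id) {
  demo <- demographic_profiles$nondrinker_12m
  gender <- if (stats::runif(1) < demo$p_male) "male" else "female"
  group <- sample(c("18-34", "35-54", "55+"), 1, prob = demo$age)
  response_record(
    participant_id = id, gender = gender, age_years = sample_age(group),
    postcode = sprintf("2%03d", sample(0:999, 1)), drank_past_12m = FALSE
  )
}

empty_flow_row <- function(id) {
  data.frame(participant_id = id, approached = TRUE, consented = FALSE,
             eligible = NA, completed_esbi = NA,
             noncompletion_reason = "none", category = NA_character_,
             invited_followup = FALSE, completed_followup = FALSE,
             accept_useful = NA_character_, stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws one flow-event record per approached participant and an item-level
#' response record for every completer, from a single seeded pseudo-random
#' stream. Each drinker's AUDIT items 1-3 are sampled uniformly from the
#' exact set of score triples whose sum lies in the intended category's
#' AUDIT-C range (found by enumerating all 125 triples), so scoring plus
#' classification always returns the intended category; remaining items are
#' drawn from category-conditioned severity profiles.
#'
#' @param spec a [cohort_spec()].
#' @param defs instrument definitions (used only to sanity-check scoring).
#' @return list of class `esbi_cohort` with `responses` (records for
#'   completers, named by participant id), `flow` (flow-event data frame,
#'   one row per approached participant) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), defs = instrument_defs()) {
  if (!inherits(spec, "esbi_cohort_spec")) {
    esbi_stop("spec must be a cohort_spec()", "esbi_spec_error")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  flow <- list()
  responses <- list()
  for (i in seq_len(spec$n)) {
    id <- sprintf("S%05d", i)
    row <- empty_flow_row(id)
    u <- stats::runif(1)
    if (u < spec$p_ineligible_approach) {
      row$eligible <- FALSE
    } else if (u < spec$p_ineligible_approach + (1 - spec$p_consent - spec$p_ineligible_approach)) {
      # refused; eligibility never assessed
    } else {
      row$consented <- TRUE
      if (stats::runif(1) < spec$p_ineligible_consent) {
        row$eligible <- FALSE
      } else {
        row$eligible <- TRUE
        if (stats::runif(1) >= spec$p_complete) {
          row$completed_esbi <- FALSE
          row$noncompletion_reason <-
            if (stats::runif(1) < spec$reason_technical) "technical"
            else "called_for_appointment"
        } else {
          row$completed_esbi <- TRUE
          category <- sample(names(spec$category_mixture), 1,
                             prob = spec$category_mixture)
          row$category <- category
          if (category == "nondrinker_12m") {
            responses[[id]] <- synth_nondrinker_record(id)
          } else {
            profile <- severity_profiles[[category]]
            responses[[id]] <- synth_drinker_record(id, category, profile)
            row$accept_useful <- sample(names(usefulness_profiles[[category]]), 1,
                                        prob = usefulness_profiles[[category]])
            if (stats::runif(1) < spec$p_invite[[category]]) {
              row$invited_followup <- TRUE
              row$completed_followup <-
                stats::runif(1) < spec$p_followup[[category]]
            } else {
              # no drinking in the past 4 weeks: episode reports zero drinks
              responses[[id]]$episode$max_drinks <- 0
            }
          }
        }
      }
    }
    flow[[i]] <- row
  }
  structure(list(responses = responses,
                 flow = do.call(rbind, c(flow, list(make.row.names = FALSE))),
                 spec = spec),
            class = "esbi_cohort")
}

#' @export
print.esbi_cohort <- function(x, ...) {
  cat(sprintf("<synthetic cohort: %d approached, %d completer responses, seed %d>\n",
              nrow(x$flow), length(x$responses), x$spec$seed))
  invisible(x)
}

#' Deterministic pilot participant-flow fixture
#'
#' A flow-event table whose node counts equal the hospital-outpatient pilot
#' recruitment episode referenced throughout the package: 172 approached;
#' 108 consented, 62 refused, 2 ineligible at approach; 2 of the consenters
#' ineligible; of 106 eligible, 7 noncompleters (3 technical, 4 called for
#' their appointment) and 99 completers splitting 15/43/33/8 across the
#' screening categories; 69 drinkers invited to follow-up (32/30/7 by
#' category) of whom 52 completed it (26/22/4); and usefulness-of-feedback
#' acceptability answers with column counts 11/7/13/12 (negative),
#' 6/11/10/5 plus one unanswered (hazardous/harmful) and 4/2/2/0 (possible
#' dependence).
#'
#' @return flow-event data frame with 172 rows (see [feasibility] for the
#'   column schema).
#' @export
pilot_flow_fixture <- function() {
  rows <- list()
  idx <- 0L
  add <- function(n, mutate) {
    for (k in seq_len(n)) {
      idx <<- idx + 1L
      row <- empty_flow_row(sprintf("F%03d", idx))
      rows[[idx]] <<- mutate(row)
    }
  }
  add(62, function(r) r)                                   # refused
  add(2, function(r) { r$eligible <- FALSE; r })           # ineligible at approach
  add(2, function(r) { r$consented <- TRUE; r$eligible <- FALSE; r })
  noncomplete <- function(reason) function(r) {
    r$consented <- TRUE; r$eligible <- TRUE
    r$completed_esbi <- FALSE; r$noncompletion_reason <- reason; r
  }
  add(3, noncomplete("technical"))
  add(4, noncomplete("called_for_appointment"))
  completer <- function(category, invited, followed, useful) function(r) {
    r$consented <- TRUE; r$eligible <- TRUE; r$completed_esbi <- TRUE
    r$category <- category
    r$invited_followup <- invited; r$completed_followup <- followed
    r$accept_useful <- useful; r
  }
  add(15, completer("nondrinker_12m", FALSE, FALSE, NA_character_))
  # usefulness answers cycle through each category's printed column counts
  useful_col <- function(counts) rep(names(counts), counts)
  neg_useful <- useful_col(c(very = 11, quite = 7, somewhat = 13, not_at_all = 12))
  haz_useful <- c(useful_col(c(very = 6, quite = 11, somewhat = 10, not_at_all = 5)),
                  NA_character_)
  dep_useful <- useful_col(c(very = 4, quite = 2, somewhat = 2))
  k <- 0L
  add(43, function(r) {
    k <<- k + 1L
    # invited: first 32; followed-up: first 26
    completer("negative", k <= 32, k <= 26, neg_useful[k])(r)
  })
  k <- 0L
  add(33, function(r) {
    k <<- k + 1L
    completer("hazardous_harmful", k <= 30, k <= 22, haz_useful[k])(r)
  })
  k <- 0L
  add(8, function(r) {
    k <<- k + 1L
    completer("possible_dependence", k <= 7, k <= 4, dep_useful[k])(r)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
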