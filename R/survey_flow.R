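#' @title Survey flow: page sequence, 12-month gate, interruption and resume
#' @description
#' The survey is a fixed page automaton:
#' `intro -> demographics -> gate12m -> (thanks | audit -> episode -> ldq ->
#' trauma -> feedback -> thanks)`.
#' A participant who reports no alcohol in the past 12 months jumps straight
#' to the thanks page and is complete. Sessions are keyed by an opaque
#' linkage identifier so a participant called away for their appointment can
#' resume exactly where they stopped, with all prior answers intact;
#' already-visited pages are never re-asked.
#' @name survey_flow
NULL

FLOW_PAGES <- c("intro", "demographics", "gate12m", "audit", "episode",
                "ldq", "trauma", "feedback", "thanks")

#' Start a new survey session
#'
#' @param linkage_id opaque unique identifier supplied by the caller (see
#'   [generate_linkage_id()]).
#' @return list of class `esbi_flow_session` with `linkage_id`,
#'   `current_page`, `answers`, `status`.
#' @export
flow_session <- function(linkage_id) {
  if (!is_string(linkage_id) || !nzchar(linkage_id)) {
    esbi_stop("linkage_id must be a non-empty string", "esbi_validation_error")
  }
  structure(
    list(linkage_id = linkage_id, current_page = "intro",
         answers = list(), status = "in_progress"),
    class = "esbi_flow_session"
  )
}

#' @export
print.esbi_flow_session <- function(x, ...) {
  cat(sprintf("<flow session %s: page '%s', %s>\n", x$linkage_id,
              x$current_page, x$status))
  invisible(x)
}

validate_page_answers <- function(page, answers, defs) {
  err <- function(msg) esbi_stop(msg, "esbi_validation_error")
  switch(page,
    intro = NULL,
    demographics = {
      if (!is_string(answers$gender) || !answers$gender %in% c("male", "female"))
        err("demographics: gender must be 'male' or 'female'")
      if (!is_count(answers$age_years) || answers$age_years < 18)
        err("demographics: age_years must be an integer >= 18")
    },
    gate12m = {
      if (!is_flag(answers$drank_past_12m))
        err("gate12m: drank_past_12m must be TRUE or FALSE")
    },
    audit = score_items(defs$AUDIT, answers$audit_items, "AUDIT"),
    episode = {
      ep <- answers$episode
      if (is.null(ep) || !is.numeric(ep$max_drinks) || is.na(ep$max_drinks) ||
          ep$max_drinks < 0)
        err("episode: max_drinks must be a number >= 0")
      if (ep$max_drinks > 0 &&
          (!is.numeric(ep$duration_hours) || is.na(ep$duration_hours) ||
           ep$duration_hours <= 0))
        err("episode: duration_hours must be > 0 when drinks > 0")
      if (!is.numeric(ep$weight_kg) || is.na(ep$weight_kg) || ep$weight_kg <= 0)
        err("episode: weight_kg must be > 0")
    },
    ldq = score_items(defs$LDQ, answers$ldq_items, "LDQ"),
    trauma = score_items(defs$TRAUMA, answers$trauma_items, "TRAUMA"),
    feedback = {
      if (!is.null(answers$email) &&
          !grepl("^[^@[:space:]]+@[^@[:space:]]+\\.[^@[:space:]]+$", answers$email))
        err("feedback: email address is not syntactically valid")
    },
    thanks = NULL
  )
  invisible(NULL)
}

#' Advance a session by one page
#'
#' Validates the answers for the current page, stores them, and moves to the
#' next page in the fixed order. Answering "no" at the 12-month gate jumps
#' directly to the thanks page and completes the session; advancing past the
#' feedback page also completes it. On any validation or sequencing error
#' the session is unchanged (the error is thrown before the returned value
#' exists).
#'
#' @param session an `esbi_flow_session`.
#' @param page_answers named list of answers for `session$current_page`
#'   (e.g. `list(drank_past_12m = TRUE)` on the gate page). The `page`
#'   element, if given, must match the current page.
#' @param defs instrument definitions from [instrument_defs()].
#' @return the advanced session.
#' @export
advance <- function(session, page_answers = list(), defs = instrument_defs()) {
  if (session$status == "completed") {
    esbi_stop("cannot advance a completed session", "esbi_sequencing_error")
  }
  page <- session$current_page
  if (!is.null(page_answers$page) && !identical(page_answers$page, page)) {
    esbi_stop(sprintf("answers are for page '%s' but session is on page '%s'",
                      page_answers$page, page), "esbi_sequencing_error")
  }
  page_answers$page <- NULL
  validate_page_answers(page, page_answers, defs)
  if (length(page_answers)) session$answers[[page]] <- page_answers
  session$status <- "in_progress"
  if (page == "gate12m" && !isTRUE(page_answers$drank_past_12m)) {
    session$current_page <- "thanks"
    session$status <- "completed"
  } else if (page == "feedback") {
    session$current_page <- "thanks"
    session$status <- "completed"
  } else if (page == "thanks") {
    session$current_page <- "thanks"
    session$status <- "completed"
  } else {
    session$current_page <- FLOW_PAGES[match(page, FLOW_PAGES) + 1L]
  }
  session
}

#' Mark a session as interrupted
#'
#' Used when a participant is called away before completing. The page
#' pointer and all answers are retained for [resume()].
#'
#' @param session an in-progress `esbi_flow_session`.
#' @return the session with status `"interrupted"`.
#' @export
interrupt <- function(session) {
  if (session$status == "completed") {
    esbi_stop("cannot interrupt a completed session", "esbi_sequencing_error")
  }
  session$status <- "interrupted"
  session
}

#' Session stores
#'
#' A pluggable persistence layer keyed by linkage identifier. Two backends
#' ship: an in-memory store (an environment) and a single-file JSON store
#' whose schema is one object per linkage identifier.
#'
#' @param backend `"memory"` or `"file"`.
#' @param path file path (required for the file backend).
#' @return a store object for [save_session()] / [resume()].
#' @export
session_store <- function(backend = c("memory", "file"), path = NULL) {
  backend <- match.arg(backend)
  if (backend == "file" && !is_string(path)) {
    esbi_stop("file backend requires a path", "esbi_usage_error")
  }
  structure(list(backend = backend, path = path, env = new.env(parent = emptyenv())),
            class = "esbi_session_store")
}

store_read_all <- function(store) {
  if (store$backend == "memory") {
    as.list(store$env)
  } else if (file.exists(store$path)) {
    jsonlite::read_json(store$path)
  } else {
    list()
  }
}

session_to_list <- function(session) unclass(session)

session_from_list <- function(x) {
  ans <- lapply(x$answers, function(page) {
    page <- lapply(page, function(v) if (is.list(v)) lapply(v, unlist) else unlist(v))
    page
  })
  structure(list(linkage_id = x$linkage_id, current_page = x$current_page,
                 answers = ans, status = x$status),
            class = "esbi_flow_session")
}

#' Persist a session in a store
#'
#' @param store a [session_store()].
#' @param session an `esbi_flow_session`.
#' @return the store, invisibly.
#' @export
save_session <- function(store, session) {
  if (store$backend == "memory") {
    assign(session$linkage_id, session, envir = store$env)
  } else {
    all <- store_read_all(store)
    all[[session$linkage_id]] <- session_to_list(session)
    jsonlite::write_json(all, store$path, auto_unbox = TRUE, null = "null",
                         digits = NA)
  }
  invisible(store)
}

#' Resume a persisted session
#'
#' Returns the session exactly as it was persisted: same page pointer, same
#' answers, so the participant continues rather than starting again. A
#' resumed interrupted session is returned in progress; a completed session
#' is returned completed and no pages are re-asked.
#'
#' @param store a [session_store()].
#' @param linkage_id the identifier the session was saved under.
#' @return the `esbi_flow_session`.
#' @export
resume <- function(store, linkage_id) {
  all <- store_read_all(store)
  s <- all[[linkage_id]]
  if (is.null(s)) {
    esbi_stop(sprintf("no session with linkage id '%s'", linkage_id),
              "esbi_not_found_error")
  }
  session <- if (inherits(s, "esbi_flow_session")) s else session_from_list(s)
  if (session$status == "interrupted") session$status <- "in_progress"
  session
}

#' Finalize a completed session
#'
#' Assembles the participant's [response_record()], runs screening, and —
#' for drinkers — builds the personalized feedback bundle. A gated-out
#' 12-month nondrinker yields a record and a `nondrinker_12m` screening
#' result with no feedback.
#'
#' @param session a completed `esbi_flow_session`.
#' @param defs instrument definitions from [instrument_defs()].
#' @param config a [feedback_config()].
#' @return list with `record`, `screening`, `scores` (or `NULL`) and
#'   `feedback` (or `NULL`).
#' @export
finalize <- function(session, defs = instrument_defs(),
                     config = feedback_config()) {
  if (session$status != "completed") {
    esbi_stop("cannot finalize a session that is not completed", "esbi_state_error")
  }
  a <- session$answers
  drank <- isTRUE(a$gate12m$drank_past_12m)
  record <- response_record(
    participant_id = session$linkage_id,
    gender = a$demographics$gender,
    age_years = a$demographics$age_years,
    postcode = if (is.null(a$demographics$postcode)) "" else a$demographics$postcode,
    drank_past_12m = drank,
    audit_items = a$audit$audit_items,
    episode = a$episode$episode,
    ldq_items = a$ldq$ldq_items,
    trauma_items = a$trauma$trauma_items,
    email = a$feedback$email
  )
  if (!drank) {
    return(list(record = record, screening = classify(FALSE, NULL),
                scores = NULL, feedback = NULL))
  }
  scores <- score_record(record, defs)
  list(record = record,
       screening = classify(TRUE, scores$audit_c),
       scores = scores,
       feedback = build_feedback(record, scores, config))
}
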