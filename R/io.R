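#' @title Reading and writing responses, screening results and summaries
#' @description
#' The on-disk formats are deliberately plain: UTF-8 comma-separated values
#' with a header row for tabular data (one participant per row, columns
#' `audit_1..audit_10`, `ldq_1..ldq_10`, `trauma_1..trauma_5`, episode
#' fields and demographics), and JSON (with a `schema_version` field) for
#' nested data. Reading and writing are lossless inverses on valid data;
#' malformed rows are reported with their row and column.
#' @name io
NULL

AUDIT_COLS <- paste0("audit_", 1:10)
LDQ_COLS <- paste0("ldq_", 1:10)
TRAUMA_COLS <- paste0("trauma_", 1:5)
RESPONSE_COLS <- c("participant_id", "gender", "age_years", "postcode",
                   "drank_past_12m", "email", AUDIT_COLS,
                   "episode_max_drinks", "episode_duration_hours",
                   "episode_weight_kg", LDQ_COLS, TRAUMA_COLS)

#' Convert response records to a flat data frame
#'
#' @param records list of [response_record()]s.
#' @return data frame with the documented response-CSV columns; absent
#'   (gated-out) instrument answers become `NA`.
#' @export
responses_to_df <- function(records) {
  rows <- lapply(records, function(r) {
    vec <- function(x, n) if (is.null(x)) rep(NA_integer_, n) else as.integer(x)
    ep <- r$episode
    df <- data.frame(
      participant_id = r$participant_id, gender = r$gender,
      age_years = as.integer(r$age_years), postcode = as.character(r$postcode),
      drank_past_12m = r$drank_past_12m,
      email = if (is.null(r$email)) NA_character_ else r$email,
      stringsAsFactors = FALSE)
    df[AUDIT_COLS] <- as.list(vec(r$audit_items, 10))
    df$episode_max_drinks <- if (is.null(ep)) NA_real_ else ep$max_drinks
    df$episode_duration_hours <- if (is.null(ep)) NA_real_ else ep$duration_hours
    df$episode_weight_kg <- if (is.null(ep)) NA_real_ else ep$weight_kg
    df[LDQ_COLS] <- as.list(vec(r$ldq_items, 10))
    df[TRAUMA_COLS] <- as.list(vec(r$trauma_items, 5))
    df[RESPONSE_COLS]
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

df_to_responses <- function(df, defs = instrument_defs(), origin = "input") {
  miss <- setdiff(RESPONSE_COLS, names(df))
  if (length(miss)) {
    esbi_stop(sprintf("%s: missing columns: %s", origin,
                      paste(miss, collapse = ", ")), "esbi_parse_error")
  }
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    items <- function(cols, nopt) {
      v <- as.numeric(row[cols])
      if (all(is.na(v))) return(NULL)
      for (j in seq_along(v)) {
        if (is.na(v[j]) || v[j] < 0 || v[j] >= nopt[j] || v[j] != trunc(v[j])) {
          esbi_stop(sprintf("%s row %d, column %s: invalid option index '%s'",
                            origin, i, cols[j], format(row[[cols[j]]])),
                    "esbi_parse_error")
        }
      }
      as.integer(v)
    }
    ep <- if (is.na(row$episode_max_drinks) && is.na(row$episode_weight_kg)) NULL
    else list(max_drinks = row$episode_max_drinks,
              duration_hours = row$episode_duration_hours,
              weight_kg = row$episode_weight_kg)
    records[[i]] <- response_record(
      participant_id = as.character(row$participant_id),
      gender = as.character(row$gender),
      age_years = row$age_years,
      postcode = if (is.na(row$postcode)) "" else as.character(row$postcode),
      drank_past_12m = as.logical(row$drank_past_12m),
      audit_items = items(AUDIT_COLS, vapply(defs$AUDIT$items,
                                             function(it) length(it$options), 0L)),
      episode = ep,
      ldq_items = items(LDQ_COLS, rep(4L, 10)),
      trauma_items = items(TRAUMA_COLS, rep(2L, 5)),
      email = if (is.na(row$email) || !nzchar(row$email)) NULL else row$email
    )
  }
  stats::setNames(records, vapply(records, `[[`, "", "participant_id"))
}

#' Read participant responses from CSV or JSON
#'
#' The format is chosen by file extension. An empty file yields an empty
#' list; malformed rows raise a parse error naming the row and column.
#'
#' @param path input file (`.csv` or `.json`).
#' @param defs instrument definitions used to validate option ranges.
#' @return named list of [response_record()]s.
#' @export
read_responses <- function(path, defs = instrument_defs()) {
  if (!file.exists(path)) {
    esbi_stop(sprintf("response file not found: %s", path), "esbi_parse_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    raw <- jsonlite::read_json(path)
    recs <- raw$responses
    if (is.null(recs)) recs <- raw
    out <- lapply(seq_along(recs), function(i) {
      r <- recs[[i]]
      response_record(
        participant_id = r$participant_id, gender = r$gender,
        age_years = r$age_years,
        postcode = if (is.null(r$postcode)) "" else r$postcode,
        drank_past_12m = isTRUE(r$drank_past_12m),
        audit_items = if (is.null(r$audit_items)) NULL else as.integer(unlist(r$audit_items)),
        episode = if (is.null(r$episode)) NULL else lapply(r$episode, as.numeric),
        ldq_items = if (is.null(r$ldq_items)) NULL else as.integer(unlist(r$ldq_items)),
        trauma_items = if (is.null(r$trauma_items)) NULL else as.integer(unlist(r$trauma_items)),
        email = r$email
      )
    })
    return(stats::setNames(out, vapply(out, `[[`, "", "participant_id")))
  }
  if (ext != "csv") {
    esbi_stop(sprintf("unsupported response format '.%s'", ext), "esbi_usage_error")
  }
  first <- readLines(path, n = 1, warn = FALSE)
  if (length(first) == 0 || !nzchar(trimws(first))) return(list())
  header <- strsplit(first, ",", fixed = TRUE)[[1]]
  chr_cols <- intersect(c("participant_id", "postcode"), gsub("\"", "", header))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = stats::setNames(rep("character",
                                                         length(chr_cols)),
                                                     chr_cols))
  if (nrow(df) == 0) return(list())
  df_to_responses(df, defs, origin = path)
}

#' Write participant responses to CSV or JSON
#'
#' @param records list of [response_record()]s.
#' @param path output file (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_responses <- function(records, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    payload <- list(schema_version = 1,
                    responses = lapply(records, unclass))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                         na = "null", digits = NA)
  } else if (ext == "csv") {
    utils::write.csv(responses_to_df(records), path, row.names = FALSE,
                     na = "")
  } else {
    esbi_stop(sprintf("unsupported response format '.%s'", ext), "esbi_usage_error")
  }
  invisible(path)
}

#' Write screening results to CSV
#'
#' @param results data frame from [screen_records()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_screening <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write flow-event records to CSV / read them back
#'
#' @param flow flow-event data frame (see [feasibility]).
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_flow <- function(flow, path) {
  utils::write.csv(flow, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_flow
#' @export
read_flow <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (length(first) == 0 || !nzchar(trimws(first))) {
    return(empty_flow_row("x")[0, ])
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  lgl <- c("approached", "consented", "eligible", "completed_esbi",
           "invited_followup", "completed_followup")
  for (cn in intersect(lgl, names(df))) df[[cn]] <- as.logical(df[[cn]])
  chr <- c("noncompletion_reason", "category",
           grep("^accept_|^fu_", names(df), value = TRUE))
  for (cn in intersect(chr, names(df))) {
    df[[cn]] <- as.character(df[[cn]])
    df[[cn]][!is.na(df[[cn]]) & df[[cn]] == ""] <- NA_character_
  }
  df$noncompletion_reason[is.na(df$noncompletion_reason)] <- "none"
  df
}

#' Write a cohort summary as JSON
#'
#' @param summary an [cohort_summary()] (or any summary list).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  strip <- function(x) {
    if (is.list(x)) {
      attributes(x) <- list(names = names(x))
      lapply(x, strip)
    } else x
  }
  jsonlite::write_json(strip(summary), path, auto_unbox = TRUE, null = "null",
                       na = "null", digits = NA, dataframe = "rows")
  invisible(path)
}
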