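defs <- instrument_defs()
cfg <- feedback_config()

demo_answers <- list(gender = "female", age_years = 44, postcode = "2300")

walk_drinker <- function(session,
                         audit = c(2, 2, 2, rep(0, 7)),
                         email = NULL) {
  session <- advance(session, list(), defs)                       # intro
  session <- advance(session, demo_answers, defs)                 # demographics
  session <- advance(session, list(drank_past_12m = TRUE), defs)  # gate
  session <- advance(session, list(audit_items = audit), defs)
  session <- advance(session, list(episode = list(max_drinks = 6,
                                                  duration_hours = 3,
                                                  weight_kg = 68)), defs)
  session <- advance(session, list(ldq_items = rep(1, 10)), defs)
  session <- advance(session, list(trauma_items = rep(0, 5)), defs)
  fb <- if (is.null(email)) list() else list(email = email)
  advance(session, fb, defs)                                      # feedback
}

test_that("the 12-month gate sends nondrinkers straight to thanks, completed", {
  s <- flow_session("gate-no")
  s <- advance(s, list(), defs)
  s <- advance(s, demo_answers, defs)
  s <- advance(s, list(drank_past_12m = FALSE), defs)
  expect_equal(s$current_page, "thanks")
  expect_equal(s$status, "completed")
  expect_null(s$answers$audit)
  fin <- finalize(s, defs, cfg)
  expect_equal(fin$screening$category, "nondrinker_12m")
  expect_null(fin$feedback)
  expect_false(fin$record$drank_past_12m)
})

test_that("drinkers proceed to the AUDIT and visit pages in the fixed order", {
  s <- flow_session("gate-yes")
  visited <- s$current_page
  s <- advance(s, list(), defs); visited <- c(visited, s$current_page)
  s <- advance(s, demo_answers, defs); visited <- c(visited, s$current_page)
  s <- advance(s, list(drank_past_12m = TRUE), defs)
  visited <- c(visited, s$current_page)
  expect_equal(visited, c("intro", "demographics", "gate12m", "audit"))
  s <- walk_drinker(flow_session("full-walk"))
  expect_equal(s$current_page, "thanks")
  expect_equal(s$status, "completed")
})

test_that("a completed drinker finalizes to record, screening and full feedback", {
  s <- walk_drinker(flow_session("done"), email = "me@example.org")
  fin <- finalize(s, defs, cfg)
  expect_equal(fin$screening$category, "hazardous_harmful")
  expect_equal(fin$record$email, "me@example.org")
  expect_s3_class(fin$feedback, "esbi_feedback_bundle")
  expect_named(fin$feedback[c("audit_band", "peak_bac", "monthly_spend",
                              "episodic_comparison", "weekly_comparison",
                              "ldq_band")])
  expect_equal(nrow(validate_record(fin$record, defs)), 0)
})

test_that("sequencing and validation errors leave the session unusable state out", {
  s <- walk_drinker(flow_session("term"))
  expect_error(advance(s, list(), defs), class = "esbi_sequencing_error")

  s2 <- flow_session("wrongpage")
  s2 <- advance(s2, list(), defs)
  expect_error(advance(s2, list(page = "audit", audit_items = rep(0, 10)), defs),
               class = "esbi_sequencing_error")
  expect_error(advance(s2, list(gender = "x", age_years = 30), defs),
               class = "esbi_validation_error")
  expect_equal(s2$current_page, "demographics")  # unchanged

  expect_error(finalize(s2, defs, cfg), class = "esbi_state_error")
})

test_that("interrupt + persist + resume is identity, at the exact page", {
  s <- flow_session("int1")
  s <- advance(s, list(), defs)
  s <- advance(s, demo_answers, defs)
  s <- advance(s, list(drank_past_12m = TRUE), defs)
  s <- advance(s, list(audit_items = c(1, 2, 3, rep(0, 7))), defs)
  store <- session_store("memory")
  save_session(store, interrupt(s))
  back <- resume(store, "int1")
  expect_equal(back$current_page, "episode")
  expect_equal(back$answers$audit$audit_items, c(1, 2, 3, rep(0, 7)))
  expect_equal(back$status, "in_progress")
})

test_that("the file store round-trips sessions through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  store <- session_store("file", path)
  s <- flow_session("file1")
  s <- advance(s, list(), defs)
  s <- advance(s, demo_answers, defs)
  save_session(store, interrupt(s))
  # a fresh store handle on the same file sees the session
  store2 <- session_store("file", path)
  back <- resume(store2, "file1")
  expect_equal(back$current_page, "gate12m")
  expect_equal(back$answers$demographics$gender, "female")
  expect_equal(back$answers$demographics$age_years, 44)
  expect_error(resume(store2, "nobody"), class = "esbi_not_found_error")
})

test_that("a resumed completed session stays completed with no pages re-asked", {
  store <- session_store("memory")
  s <- walk_drinker(flow_session("done2"))
  save_session(store, s)
  back <- resume(store, "done2")
  expect_equal(back$status, "completed")
  expect_equal(back$current_page, "thanks")
})

test_that("sessions with distinct linkage ids never cross-contaminate", {
  store <- session_store("memory")
  a <- flow_session("A"); b <- flow_session("B")
  a <- advance(a, list(), defs)
  a <- advance(a, list(gender = "male", age_years = 21), defs)
  b <- advance(b, list(), defs)
  b <- advance(b, list(gender = "female", age_years = 81), defs)
  save_session(store, interrupt(a)); save_session(store, interrupt(b))
  expect_equal(resume(store, "A")$answers$demographics$age_years, 21)
  expect_equal(resume(store, "B")$answers$demographics$age_years, 81)
})

test_that("no valid advance sequence visits a page twice or out of order", {
  order_of <- function(p) match(p, c("intro", "demographics", "gate12m", "audit",
                                     "episode", "ldq", "trauma", "feedback",
                                     "thanks"))
  # drinker branch
  s <- flow_session("walk1")
  seen <- order_of(s$current_page)
  for (step in list(list(), demo_answers, list(drank_past_12m = TRUE),
                    list(audit_items = rep(0, 10)),
                    list(episode = list(max_drinks = 0, duration_hours = 1,
                                        weight_kg = 60)),
                    list(ldq_items = rep(0, 10)),
                    list(trauma_items = rep(0, 5)), list())) {
    s <- advance(s, step, defs)
    seen <- c(seen, order_of(s$current_page))
  }
  expect_true(all(diff(seen) > 0))
  # gated-out branch skips every instrument page
  s <- flow_session("walk2")
  seen <- order_of(s$current_page)
  for (step in list(list(), demo_answers, list(drank_past_12m = FALSE))) {
    s <- advance(s, step, defs)
    seen <- c(seen, order_of(s$current_page))
  }
  expect_true(all(diff(seen) > 0))
  expect_equal(s$current_page, "thanks")
})

test_that("linkage id generation is URL-safe and email syntax is enforced", {
  ids <- generate_linkage_id(20)
  expect_true(all(grepl("^[A-Za-z0-9_-]{10}$", ids)))
  s2 <- flow_session("email-bad")
  s2 <- advance(s2, list(), defs)
  s2 <- advance(s2, demo_answers, defs)
  s2 <- advance(s2, list(drank_past_12m = TRUE), defs)
  s2 <- advance(s2, list(audit_items = rep(0, 10)), defs)
  s2 <- advance(s2, list(episode = list(max_drinks = 0, duration_hours = 1,
                                        weight_kg = 60)), defs)
  s2 <- advance(s2, list(ldq_items = rep(0, 10)), defs)
  s2 <- advance(s2, list(trauma_items = rep(0, 5)), defs)
  expect_error(advance(s2, list(email = "not an address"), defs),
               class = "esbi_validation_error")
})
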