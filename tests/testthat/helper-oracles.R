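# Independent scoring oracles: literal per-item score lookup tables written
# down separately from the implementation's instrument definitions.
oracle_audit_item_scores <- c(
  rep(list(c(0, 1, 2, 3, 4)), 8),  # items 1-8
  list(c(0, 2, 4), c(0, 2, 4))     # items 9-10
)

oracle_audit_total <- function(idx) {
  sum(vapply(1:10, function(i) oracle_audit_item_scores[[i]][idx[i] + 1], 0))
}

oracle_audit_c <- function(idx) {
  sum(vapply(1:3, function(i) oracle_audit_item_scores[[i]][idx[i] + 1], 0))
}

oracle_ldq_total <- function(idx) sum(idx)  # option index equals score, 0-3

# Brute-force AUDIT-C category oracle
oracle_category <- function(drank, audit_c) {
  if (!drank) "nondrinker_12m"
  else if (audit_c <= 4) "negative"
  else if (audit_c <= 9) "hazardous_harmful"
  else "possible_dependence"
}

random_audit_items <- function() {
  c(sample(0:4, 8, replace = TRUE), sample(0:2, 2, replace = TRUE))
}

# A complete, valid drinker response used across tests
drinker_record <- function(id = "p1", audit = c(2, 3, 1, 0, 0, 1, 0, 0, 2, 0),
                           gender = "male", age = 40,
                           episode = list(max_drinks = 10, duration_hours = 4,
                                          weight_kg = 80)) {
  response_record(
    participant_id = id, gender = gender, age_years = age, postcode = "2300",
    drank_past_12m = TRUE, audit_items = audit, episode = episode,
    ldq_items = c(0, 1, 2, 3, 0, 1, 2, 3, 1, 2),
    trauma_items = c(1, 0, 1, 0, 0)
  )
}
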