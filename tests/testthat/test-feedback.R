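cfg <- feedback_config()
defs <- instrument_defs()

test_that("peak BAC matches the closed-form Widmark expression", {
  # no alcohol -> exactly zero regardless of the other fields
  expect_identical(
    estimate_peak_bac(list(max_drinks = 0, duration_hours = 3, weight_kg = 70),
                      "female", cfg), 0)
  # independent hand evaluation: 10 drinks x 10 g / (80 kg x 0.68 x 10) - 0.015 x 4
  oracle <- 10 * 10 / (80 * 0.68 * 10) - 0.015 * 4
  expect_equal(
    estimate_peak_bac(list(max_drinks = 10, duration_hours = 4, weight_kg = 80),
                      "male", cfg), oracle)
  # elimination exceeding absorption clamps at exactly zero
  expect_identical(
    estimate_peak_bac(list(max_drinks = 1, duration_hours = 24, weight_kg = 80),
                      "male", cfg), 0)
})

test_that("peak BAC is monotone and never negative over random valid inputs", {
  set.seed(11)
  for (rep in 1:100) {
    d <- runif(1, 0.5, 25); h <- runif(1, 0.5, 12); w <- runif(1, 45, 130)
    g <- sample(c("male", "female"), 1)
    base <- estimate_peak_bac(list(max_drinks = d, duration_hours = h,
                                   weight_kg = w), g, cfg)
    expect_gte(base, 0)
    expect_gte(estimate_peak_bac(list(max_drinks = d + 1, duration_hours = h,
                                      weight_kg = w), g, cfg), base)
    expect_lte(estimate_peak_bac(list(max_drinks = d, duration_hours = h + 1,
                                      weight_kg = w), g, cfg), base)
    expect_lte(estimate_peak_bac(list(max_drinks = d, duration_hours = h,
                                      weight_kg = w + 5), g, cfg), base)
  }
})

test_that("invalid episode fields raise validation errors", {
  expect_error(estimate_peak_bac(list(max_drinks = 5, duration_hours = 0,
                                      weight_kg = 80), "male", cfg),
               class = "esbi_validation_error")
  expect_error(estimate_peak_bac(list(max_drinks = 5, duration_hours = 2,
                                      weight_kg = 0), "male", cfg),
               class = "esbi_validation_error")
})

test_that("monthly spend is zero for 'never', linear in price, errors off-map", {
  expect_equal(estimate_monthly_spend(0, 3, cfg), 0)
  s1 <- estimate_monthly_spend(3, 1, cfg, price = 4)
  s2 <- estimate_monthly_spend(3, 1, cfg, price = 8)
  expect_equal(s2, 2 * s1)
  # midpoint arithmetic: 11 days/month x 3.5 drinks x 5 = 192.5 at defaults
  expect_equal(estimate_monthly_spend(3, 1, cfg),
               unlist(cfg$spend$drinking_days_per_month)[4] *
                 unlist(cfg$spend$typical_drinks)[2] * cfg$spend$price_per_drink)
  expect_error(estimate_monthly_spend(5, 0, cfg), class = "esbi_config_error")
  expect_error(estimate_monthly_spend(0, 9, cfg), class = "esbi_config_error")
})

test_that("normative comparison suppression follows the strict below-guideline rule", {
  expect_equal(compare_to_guideline_and_norm(2, 4, 5)$status, "suppressed")
  expect_equal(compare_to_guideline_and_norm(4, 4, 5)$status, "shown")
  shown <- compare_to_guideline_and_norm(9, 4, 5)
  expect_equal(shown$status, "shown")
  expect_equal(c(shown$own, shown$norm, shown$guideline), c(9, 5, 4))
  # exhaustive grid
  for (own in seq(0, 10, by = 0.5)) {
    for (gl in seq(0.5, 8, by = 0.5)) {
      expect_equal(compare_to_guideline_and_norm(own, gl, 5)$status,
                   if (own < gl) "suppressed" else "shown")
    }
  }
})

test_that("AUDIT and LDQ bands partition their domains with correct boundaries", {
  labels40 <- vapply(0:40, function(s) audit_band(s, cfg)$label, "")
  expect_false(anyNA(labels40))
  expect_equal(audit_band(0, cfg)$label, "low_risk")
  expect_equal(audit_band(40, cfg)$label, "possible_dependence")
  expect_true(audit_band(7, cfg)$label != audit_band(8, cfg)$label)
  expect_true(audit_band(19, cfg)$label != audit_band(20, cfg)$label)

  labels30 <- vapply(0:30, function(s) ldq_band(s, cfg)$label, "")
  expect_false(anyNA(labels30))
  expect_equal(ldq_band(0, cfg)$label, "none")
  expect_equal(ldq_band(30, cfg)$label, "high")
  expect_error(audit_band(41, cfg), class = "esbi_range_error")
  expect_error(ldq_band(31, cfg), class = "esbi_range_error")
})

test_that("the feedback bundle carries all six components, recomputed independently", {
  rec <- drinker_record(audit = c(3, 2, 2, 1, 1, 1, 1, 1, 1, 0))
  scores <- score_record(rec, defs)
  b <- build_feedback(rec, scores, cfg)
  expect_named(b[c("audit_band", "peak_bac", "monthly_spend",
                   "episodic_comparison", "weekly_comparison", "ldq_band")])
  # independent recomputation of each component
  expect_equal(b$audit_band$score, oracle_audit_total(rec$audit_items))
  expect_equal(b$peak_bac$value,
               10 * 10 / (80 * 0.68 * 10) - 0.015 * 4)
  expect_equal(b$monthly_spend$amount,
               unlist(cfg$spend$drinking_days_per_month)[3 + 1] *
                 unlist(cfg$spend$typical_drinks)[2 + 1] * cfg$spend$price_per_drink)
  expect_equal(b$episodic_comparison$own, unlist(cfg$spend$typical_drinks)[3])
  expect_equal(b$weekly_comparison$guideline, 14)
  expect_equal(b$ldq_band$score, sum(rec$ldq_items))
  # own episodic 5.5 >= 4 and weekly 2.5 x 5.5 = 13.75 < 14: independent statuses
  expect_equal(b$episodic_comparison$status, "shown")
  expect_equal(b$weekly_comparison$status, "suppressed")
})

test_that("a below-guideline drinker has both comparisons suppressed", {
  rec <- drinker_record(audit = c(1, 0, 0, rep(0, 7)),
                        episode = list(max_drinks = 2, duration_hours = 2,
                                       weight_kg = 70))
  b <- build_feedback(rec, score_record(rec, defs), cfg)
  expect_equal(b$episodic_comparison$status, "suppressed")
  expect_equal(b$weekly_comparison$status, "suppressed")
  expect_gt(b$monthly_spend$amount, 0)
})

test_that("an all-zero AUDIT with a zero-drink episode yields floor feedback", {
  rec <- drinker_record(audit = rep(0, 10),
                        episode = list(max_drinks = 0, duration_hours = 1,
                                       weight_kg = 70))
  rec$ldq_items <- rep(0, 10)
  b <- build_feedback(rec, score_record(rec, defs), cfg)
  expect_equal(b$peak_bac$value, 0)
  expect_equal(b$monthly_spend$amount, 0)
  expect_equal(b$audit_band$label, "low_risk")
  expect_equal(b$ldq_band$label, "none")
})

test_that("rendering is deterministic, omits suppressed norms, quotes config messages", {
  rec <- drinker_record(audit = c(1, 0, 0, rep(0, 7)),
                        episode = list(max_drinks = 2, duration_hours = 2,
                                       weight_kg = 70))
  b <- build_feedback(rec, score_record(rec, defs), cfg)
  doc1 <- render_feedback(b, "text", cfg)
  doc2 <- render_feedback(b, "text", cfg)
  expect_identical(doc1, doc2)
  expect_false(grepl("Adults of your age and gender", doc1))
  expect_true(grepl(b$audit_band$message, doc1, fixed = TRUE))
  # all three static information pages present
  for (p in cfg$info_pages) expect_true(grepl(p$title, doc1, fixed = TRUE))

  heavy <- drinker_record(audit = c(4, 3, 3, rep(1, 5), 1, 1))
  bh <- build_feedback(heavy, score_record(heavy, defs), cfg)
  expect_true(grepl("Adults of your age and gender",
                    render_feedback(bh, "text", cfg)))
  html <- render_feedback(bh, "html", cfg)
  expect_true(grepl("<h2>", html))
  expect_error(render_feedback(b, "pdf", cfg), class = "esbi_usage_error")
})

test_that("a missing norm cell is a config error", {
  broken <- cfg
  broken$norms <- cfg$norms[1:5]
  rec <- drinker_record(gender = "female", age = 70)
  expect_error(build_feedback(rec, score_record(rec, defs), broken),
               class = "esbi_config_error")
})
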