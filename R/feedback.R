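#' Load the personalized-feedback configuration
#'
#' Guideline limits, Widmark parameters, band cut points and messages,
#' spend midpoints, the age-by-gender norm table and the static information
#' pages all live in one YAML file. The defaults shipped with the package
#' carry placeholder prose and synthetic norm values (see the file header).
#'
#' @param path path to a feedback-configuration YAML file; default is the
#'   installed copy.
#' @return list of class `esbi_feedback_config`.
#' @export
feedback_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "feedback_config.yaml", package = "esbi")
  }
  if (!file.exists(path)) {
    esbi_stop(sprintf("feedback config file not found: %s", path),
              "esbi_config_error")
  }
  cfg <- yaml::read_yaml(path)
  g <- cfg$guidelines
  if (g$single_occasion_limit <= 0 || g$daily_limit <= 0 ||
      g$standard_drink_grams <= 0) {
    esbi_stop("guideline limits must be positive", "esbi_config_error")
  }
  for (r in cfg$bac$distribution_ratio) {
    if (r <= 0 || r > 1) esbi_stop("distribution ratio must be in (0, 1]",
                                   "esbi_config_error")
  }
  if (cfg$bac$elimination_rate <= 0) {
    esbi_stop("elimination rate must be positive", "esbi_config_error")
  }
  want <- expand.grid(gender = c("male", "female"),
                      age_group = c("18-34", "35-54", "55+"),
                      stringsAsFactors = FALSE)
  have <- vapply(cfg$norms, function(n) paste(n$gender, n$age_group), "")
  missing <- setdiff(paste(want$gender, want$age_group), have)
  if (length(missing)) {
    esbi_stop(paste("norm table missing cells:", paste(missing, collapse = "; ")),
              "esbi_config_error")
  }
  structure(cfg, class = "esbi_feedback_config")
}

#' Age group used by the norm table
#' @param age_years integer age (>= 18).
#' @return one of `"18-34"`, `"35-54"`, `"55+"`.
#' @export
age_group <- function(age_years) {
  ifelse(age_years < 35, "18-34", ifelse(age_years < 55, "35-54", "55+"))
}

norm_cell <- function(config, gender, group) {
  for (n in config$norms) {
    if (n$gender == gender && n$age_group == group) return(n)
  }
  esbi_stop(sprintf("no norm-table cell for (%s, %s)", gender, group),
            "esbi_config_error")
}

#' Estimate peak blood alcohol concentration (Widmark)
#'
#' Peak BAC in g/100 mL for the heaviest drinking occasion of the last four
#' weeks, from the Widmark body-water model with linear time-based
#' elimination:
#' \deqn{BAC = \frac{drinks \times g_{drink}}{weight_{kg} \times r \times 10}
#'       - \beta \times hours}
#' where `r` is the gender-specific distribution ratio and `beta` the
#' elimination rate (g/100 mL per hour). Negative values are clamped to 0.
#'
#' @param episode list with `max_drinks` (Australian standard drinks),
#'   `duration_hours`, `weight_kg`.
#' @param gender `"male"` or `"female"`.
#' @param config a [feedback_config()].
#' @return peak BAC in g/100 mL, `>= 0`.
#' @export
#' @examples
#' estimate_peak_bac(list(max_drinks = 10, duration_hours = 4, weight_kg = 80),
#'                   "male")
estimate_peak_bac <- function(episode, gender, config = feedback_config()) {
  d <- episode$max_drinks
  if (!is.numeric(d) || is.na(d) || !is.finite(d) || d < 0) {
    esbi_stop("max_drinks must be a finite number >= 0", "esbi_validation_error")
  }
  if (d == 0) return(0)
  if (!is.numeric(episode$weight_kg) || episode$weight_kg <= 0) {
    esbi_stop("weight_kg must be > 0", "esbi_validation_error")
  }
  if (!is.numeric(episode$duration_hours) || episode$duration_hours <= 0) {
    esbi_stop("duration_hours must be > 0 when drinks > 0",
              "esbi_validation_error")
  }
  r <- config$bac$distribution_ratio[[gender]]
  if (is.null(r)) esbi_stop(sprintf("no distribution ratio for gender '%s'", gender),
                            "esbi_config_error")
  grams <- d * config$guidelines$standard_drink_grams
  bac <- grams / (episode$weight_kg * r * 10) -
    config$bac$elimination_rate * episode$duration_hours
  max(bac, 0)
}

band_lookup <- function(bands, value) {
  for (b in bands) {
    if (value >= b$min && value <= b$max) {
      return(list(label = b$label, message = b$message))
    }
  }
  esbi_stop(sprintf("no band covers value %s", format(value)), "esbi_config_error")
}

#' AUDIT-score feedback band
#'
#' Maps an AUDIT total (0-40) to the configured risk zone (defaults follow
#' the WHO zones 0-7 / 8-15 / 16-19 / 20-40) and its message.
#'
#' @param audit_total integer 0-40.
#' @param config a [feedback_config()].
#' @return list with `score`, `label`, `message`.
#' @export
audit_band <- function(audit_total, config = feedback_config()) {
  if (!is_count(audit_total) || audit_total > 40) {
    esbi_stop("audit_total must be an integer in 0-40", "esbi_range_error")
  }
  c(list(score = audit_total), band_lookup(config$audit_bands, audit_total))
}

#' LDQ-score feedback band
#'
#' Maps an LDQ total (0-30) to a dependence-severity label and message.
#' Default cut points 0 / 1-10 / 11-20 / 21-30 are an engine choice and
#' configurable.
#'
#' @param ldq_total integer 0-30.
#' @param config a [feedback_config()].
#' @return list with `score`, `label`, `message`.
#' @export
ldq_band <- function(ldq_total, config = feedback_config()) {
  if (!is_count(ldq_total) || ldq_total > 30) {
    esbi_stop("ldq_total must be an integer in 0-30", "esbi_range_error")
  }
  c(list(score = ldq_total), band_lookup(config$ldq_bands, ldq_total))
}

bac_tier <- function(peak_bac, config) {
  tiers <- config$bac_tiers
  hit <- tiers[[1]]
  for (t in tiers) if (peak_bac >= t$min) hit <- t
  list(label = hit$label, message = hit$message)
}

#' Estimate monthly spending on alcohol
#'
#' Spending is the product of the numeric midpoints configured for the
#' AUDIT item 1 (drinking days per month) and item 2 (typical drinks per
#' occasion) response bands and the configured price per standard drink.
#' A frequency of "never" always yields 0.
#'
#' @param freq_index zero-based AUDIT item 1 option index.
#' @param drinks_index zero-based AUDIT item 2 option index.
#' @param config a [feedback_config()].
#' @param price price per standard drink; default from config.
#' @return estimated spend per month in the configured currency.
#' @export
estimate_monthly_spend <- function(freq_index, drinks_index,
                                   config = feedback_config(),
                                   price = config$spend$price_per_drink) {
  days <- unlist(config$spend$drinking_days_per_month)
  drinks <- unlist(config$spend$typical_drinks)
  if (!is_count(freq_index) || freq_index >= length(days)) {
    esbi_stop("frequency band has no configured midpoint", "esbi_config_error")
  }
  if (!is_count(drinks_index) || drinks_index >= length(drinks)) {
    esbi_stop("typical-drinks band has no configured midpoint", "esbi_config_error")
  }
  if (price <= 0) esbi_stop("price must be positive", "esbi_config_error")
  days[freq_index + 1L] * drinks[drinks_index + 1L] * price
}

#' Estimated weekly consumption from AUDIT items 1-2
#'
#' Weekly standard drinks as occasions-per-week midpoint times
#' typical-drinks midpoint, for the weekly comparison bar.
#'
#' @inheritParams estimate_monthly_spend
#' @return standard drinks per week.
#' @export
estimate_weekly_drinks <- function(freq_index, drinks_index,
                                   config = feedback_config()) {
  occ <- unlist(config$spend$occasions_per_week)
  drinks <- unlist(config$spend$typical_drinks)
  if (!is_count(freq_index) || freq_index >= length(occ) ||
      !is_count(drinks_index) || drinks_index >= length(drinks)) {
    esbi_stop("band has no configured midpoint", "esbi_config_error")
  }
  occ[freq_index + 1L] * drinks[drinks_index + 1L]
}

#' Compare own consumption with guideline and population norm
#'
#' Normative feedback is withheld (suppressed) when the participant's own
#' consumption is strictly lower than the medical recommendation, to avoid
#' the risk of "drinking up" to the norm; at or above the guideline all
#' three bar values are shown. The comparator is strict: own equal to the
#' guideline is shown.
#'
#' @param own participant's consumption (standard drinks).
#' @param guideline guideline limit (standard drinks).
#' @param norm same-age/gender population value (standard drinks).
#' @return list with `own`, `guideline`, `norm`, and `status`
#'   (`"shown"` or `"suppressed"`).
#' @export
#' @examples
#' compare_to_guideline_and_norm(2, 4, 5)$status  # "suppressed"
#' compare_to_guideline_and_norm(4, 4, 5)$status  # "shown"
compare_to_guideline_and_norm <- function(own, guideline, norm) {
  stopifnot(own >= 0, guideline >= 0, norm >= 0)
  list(own = own, guideline = guideline, norm = norm,
       status = if (own < guideline) "suppressed" else "shown")
}

#' Build the full personalized-feedback bundle
#'
#' Assembles the six feedback components every completing drinker receives:
#' (1) the AUDIT score with a risk-zone message, (2) estimated peak BAC for
#' the heaviest recent occasion with a sequelae tier, (3) estimated monthly
#' spending on alcohol, (4) a single-occasion comparison of own consumption
#' with the guideline and the same-age/gender norm, (5) the same comparison
#' for weekly consumption, and (6) the LDQ score with a dependence message.
#' Suppression of normative bars is applied independently to the episodic
#' and weekly comparisons.
#'
#' @param record a gated-in [response_record()] (`drank_past_12m` TRUE).
#' @param scores instrument scores from [score_record()].
#' @param config a [feedback_config()].
#' @return list of class `esbi_feedback_bundle`.
#' @export
build_feedback <- function(record, scores, config = feedback_config()) {
  if (!isTRUE(record$drank_past_12m)) {
    esbi_stop("feedback is only built for participants who drank in the past 12 months",
              "esbi_state_error")
  }
  grp <- age_group(record$age_years)
  nc <- norm_cell(config, record$gender, grp)
  peak <- estimate_peak_bac(record$episode, record$gender, config)
  freq_idx <- record$audit_items[1]
  drinks_idx <- record$audit_items[2]
  own_episodic <- unlist(config$spend$typical_drinks)[drinks_idx + 1L]
  own_weekly <- estimate_weekly_drinks(freq_idx, drinks_idx, config)
  structure(
    list(
      participant_id = record$participant_id,
      audit_band = audit_band(scores$audit_total, config),
      peak_bac = c(list(value = peak), bac_tier(peak, config)),
      monthly_spend = list(
        amount = estimate_monthly_spend(freq_idx, drinks_idx, config),
        currency = config$spend$currency
      ),
      episodic_comparison = compare_to_guideline_and_norm(
        own_episodic, config$guidelines$single_occasion_limit,
        nc$typical_occasion_drinks),
      weekly_comparison = compare_to_guideline_and_norm(
        own_weekly, 7 * config$guidelines$daily_limit, nc$weekly_drinks),
      ldq_band = ldq_band(scores$ldq_total, config)
    ),
    class = "esbi_feedback_bundle"
  )
}

render_comparison <- function(cmp, what, unit) {
  if (cmp$status == "suppressed") {
    sprintf("Your %s is below the recommended limit of %g %s. Well done - keeping within the guideline keeps your risk low.",
            what, cmp$guideline, unit)
  } else {
    paste0(
      sprintf("Your %s: %g %s\n", what, cmp$own, unit),
      sprintf("Recommended limit: %g %s\n", cmp$guideline, unit),
      sprintf("Adults of your age and gender: %g %s", cmp$norm, unit)
    )
  }
}

#' Render a feedback bundle to text or HTML
#'
#' Produces a deterministic document: every shown component appears,
#' suppressed normative bars are omitted entirely, and the three static
#' information pages from the configuration are appended. Identical bundles
#' render to identical bytes, so a participant can email themselves an
#' exact copy.
#'
#' @param bundle an [build_feedback()] bundle.
#' @param format `"text"` or `"html"`.
#' @param config a [feedback_config()] (for the static pages).
#' @return a single string containing the document.
#' @export
render_feedback <- function(bundle, format = c("text", "html"),
                            config = feedback_config()) {
  if (!is_string(format[1]) || !format[1] %in% c("text", "html")) {
    esbi_stop(sprintf("unknown format '%s' (use 'text' or 'html')",
                      paste(format[1], collapse = "")), "esbi_usage_error")
  }
  format <- format[1]
  sections <- list(
    list(title = "Your AUDIT score",
         body = sprintf("Score: %d (%s)\n%s", bundle$audit_band$score,
                        bundle$audit_band$label, bundle$audit_band$message)),
    list(title = "Estimated peak blood alcohol concentration",
         body = sprintf("Peak BAC for your heaviest recent occasion: %.3f g/100 mL (%s)\n%s",
                        bundle$peak_bac$value, bundle$peak_bac$label,
                        bundle$peak_bac$message)),
    list(title = "Estimated monthly spending on alcohol",
         body = sprintf("About %s %.2f per month.", bundle$monthly_spend$currency,
                        bundle$monthly_spend$amount)),
    list(title = "Your drinking on one occasion",
         body = render_comparison(bundle$episodic_comparison,
                                  "typical single-occasion consumption",
                                  "standard drinks")),
    list(title = "Your drinking over a week",
         body = render_comparison(bundle$weekly_comparison,
                                  "weekly consumption", "standard drinks/week")),
    list(title = "Your LDQ score",
         body = sprintf("Score: %d (%s)\n%s", bundle$ldq_band$score,
                        bundle$ldq_band$label, bundle$ldq_band$message))
  )
  for (p in config$info_pages) {
    sections <- c(sections, list(list(title = p$title, body = p$body)))
  }
  if (format == "text") {
    paste(vapply(sections, function(s) {
      paste0(s$title, "\n", strrep("-", nchar(s$title)), "\n", s$body, "\n")
    }, ""), collapse = "\n")
  } else {
    esc <- function(x) {
      x <- gsub("&", "&amp;", x, fixed = TRUE)
      x <- gsub("<", "&lt;", x, fixed = TRUE)
      gsub(">", "&gt;", x, fixed = TRUE)
    }
    body <- paste(vapply(sections, function(s) {
      sprintf("<section>\n<h2>%s</h2>\n<p>%s</p>\n</section>", esc(s$title),
              gsub("\n", "<br/>", esc(s$body), fixed = TRUE))
    }, ""), collapse = "\n")
    paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>",
           "<title>Your personalized feedback</title></head>\n<body>\n",
           body, "\n</body></html>\n")
  }
}
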