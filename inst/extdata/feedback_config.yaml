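# Personalized-feedback configuration for the e-SBI engine.
#
# Everything a site might legitimately tune lives here: guideline limits,
# Widmark parameters, band cut points and messages, the drink price used in
# the monthly-spend estimate, the normative table, and the static
# information pages appended to every feedback document.
#
# PLACEHOLDERS: the norm table values, band messages, BAC sequelae text and
# the information pages are synthetic text written for this engine. They are
# NOT the wording or the national-survey norms used in any deployed program
# and must be replaced before clinical use.
schema_version: 1

guidelines:
  # 2009 Australian adult guidelines: no more than 2 standard drinks on any
  # day, no more than 4 on a single occasion. One standard drink = 10 g
  # ethanol (Australia).
  single_occasion_limit: 4
  daily_limit: 2
  standard_drink_grams: 10

bac:
  # Widmark body-water distribution ratios and a linear elimination rate in
  # g/100 mL per hour (standard forensic conventions).
  distribution_ratio:
    male: 0.68
    female: 0.55
  elimination_rate: 0.015

spend:
  # Numeric midpoints for the AUDIT item 1 (frequency) and item 2 (typical
  # drinks) response bands, used only for the monthly-spend estimate and the
  # weekly-consumption bar.
  price_per_drink: 5.0
  currency: AUD
  drinking_days_per_month: [0, 1, 3, 11, 22]      # per item 1 option
  occasions_per_week: [0, 0.25, 0.75, 2.5, 5]     # per item 1 option
  typical_drinks: [1.5, 3.5, 5.5, 8, 11]          # per item 2 option

audit_bands:
  # WHO AUDIT risk zones. Messages are placeholders.
  - {min: 0,  max: 7,  label: low_risk,
     message: "Your answers suggest you are at low risk of harm from alcohol."}
  - {min: 8,  max: 15, label: hazardous,
     message: "Your answers suggest a level of drinking that increases your risk of harm."}
  - {min: 16, max: 19, label: harmful,
     message: "Your answers suggest a level of drinking that is likely already harming your health."}
  - {min: 20, max: 40, label: possible_dependence,
     message: "Your answers suggest possible alcohol dependence; consider discussing your drinking with a health professional."}

ldq_bands:
  # LDQ severity bands used for the dependence-feedback message. The
  # published questionnaire does not fix population cut points; these are an
  # engine default and are configurable.
  - {min: 0,  max: 0,  label: none,
     message: "Your answers show no signs of dependence on alcohol."}
  - {min: 1,  max: 10, label: low,
     message: "Your answers show low levels of dependence on alcohol."}
  - {min: 11, max: 20, label: moderate,
     message: "Your answers show moderate dependence on alcohol; cutting down may be hard without support."}
  - {min: 21, max: 30, label: high,
     message: "Your answers show a high level of dependence on alcohol; support is strongly recommended."}

bac_tiers:
  # Behavioural/physiological sequelae tiers by peak BAC (g/100 mL).
  # Placeholder prose.
  - {min: 0.0,  label: minimal,
     message: "Little or no measurable impairment."}
  - {min: 0.05, label: impaired,
     message: "Judgement and fine motor control are measurably impaired; crash risk is roughly doubled."}
  - {min: 0.10, label: marked,
     message: "Reaction time, balance and speech are clearly affected; crash risk rises steeply."}
  - {min: 0.20, label: severe,
     message: "Severe intoxication: blackouts, vomiting and injury are common at this level."}
  - {min: 0.30, label: dangerous,
     message: "Potentially life-threatening: risk of loss of consciousness and respiratory depression."}

norms:
  # Typical single-occasion and weekly consumption (standard drinks) of
  # adults of the same gender and age group. SYNTHETIC PLACEHOLDER values —
  # replace with national survey estimates before use.
  - {gender: male,   age_group: "18-34", typical_occasion_drinks: 5.0, weekly_drinks: 14.0}
  - {gender: male,   age_group: "35-54", typical_occasion_drinks: 4.0, weekly_drinks: 11.0}
  - {gender: male,   age_group: "55+",   typical_occasion_drinks: 3.0, weekly_drinks: 8.0}
  - {gender: female, age_group: "18-34", typical_occasion_drinks: 3.5, weekly_drinks: 8.0}
  - {gender: female, age_group: "35-54", typical_occasion_drinks: 2.5, weekly_drinks: 6.0}
  - {gender: female, age_group: "55+",   typical_occasion_drinks: 2.0, weekly_drinks: 4.0}

info_pages:
  # The three static pages appended after the personalized feedback.
  # Placeholder prose.
  - title: "About alcohol"
    body: "Drinking above guideline levels increases the risk of injury, liver disease, some cancers and mental health problems."
  - title: "Tips for reducing risk"
    body: "Set a limit before you start, alternate alcoholic drinks with water, eat before and while drinking, and keep several alcohol-free days each week."
  - title: "Sources of support"
    body: "If you are concerned about your drinking, speak to your general practitioner or contact your local alcohol and drug information service."
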