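# Shared fixtures: all built in code, no data files.

small_population <- function(n = 200, seed = 42) {
  generate_base_population(synthetic_config(n_individuals = n), seed = seed)
}

# population with random dementia flags (for condition-count oracles)
random_states <- function(n = 200, seed = 42, p_dementia = 0.1) {
  pop <- small_population(n, seed)
  set.seed(seed + 1)
  pop$dementia <- runif(n) < p_dementia
  pop
}

# schedule with no mortality before the terminal age
no_mortality_schedule <- function(years = 2014:2036, terminal_age = 150L) {
  grid <- expand.grid(year = years, sex = c("male", "female"),
                      age = 35:terminal_age, stringsAsFactors = FALSE)
  grid$q <- ifelse(grid$age == terminal_age, 1, 0)
  mortality_schedule(grid)
}

# bundle in which every monthly move-probability is zero (states frozen):
# huge own-state coefficients pin the interval distribution at the diagonal
frozen_bundle <- function(registry = default_registry()) {
  big <- 1000
  b <- function(name, ...) manual_transition_model(registry[[name]], c(...))
  models <- list(
    marital = manual_transition_model(registry$marital, rbind(
      married = c("(Intercept)" = -big, age_c = 0, sexfemale = 0,
                  marital_married = 2 * big, marital_widowed = 0),
      widowed = c("(Intercept)" = -big, age_c = 0, sexfemale = 0,
                  marital_married = 0, marital_widowed = 2 * big))),
    smoking = manual_transition_model(registry$smoking, rbind(
      former = c("(Intercept)" = -big, age_c = 0, sexfemale = 0,
                 smoking_former = 2 * big, smoking_current = 0),
      current = c("(Intercept)" = -big, age_c = 0, sexfemale = 0,
                  smoking_former = 0, smoking_current = 2 * big))),
    inactive = b("inactive", "(Intercept)" = -big, age_c = 0, sexfemale = 0,
                 education_c = 0, bmi_score = 0, inactive = 2 * big),
    bmi_cat = manual_transition_model(registry$bmi_cat,
      list(zeta = c(-big / 2, big / 2, 3 * big / 2),
           beta = c(age_c = 0, inactive = 0, bmi_score = big))),
    arthritis = b("arthritis", "(Intercept)" = -big, age_c = 0,
                  sexfemale = 0, education_c = 0, ses_c = 0,
                  smoking_former = 0, smoking_current = 0, inactive = 0,
                  bmi_score = 0),
    cancer = b("cancer", "(Intercept)" = -big, age_c = 0, sexfemale = 0,
               education_c = 0, ses_c = 0, smoking_former = 0,
               smoking_current = 0, inactive = 0, bmi_score = 0),
    chd = b("chd", "(Intercept)" = -big, age_c = 0, sexfemale = 0,
            education_c = 0, ses_c = 0, smoking_former = 0,
            smoking_current = 0, inactive = 0, bmi_score = 0,
            hypertension = 0, diabetes = 0),
    depression = b("depression", "(Intercept)" = -big, age_c = 0,
                   sexfemale = 0, education_c = 0, ses_c = 0, inactive = 0,
                   arthritis = 0, depression = 2 * big),
    diabetes = b("diabetes", "(Intercept)" = -big, age_c = 0, sexfemale = 0,
                 education_c = 0, ses_c = 0, smoking_former = 0,
                 smoking_current = 0, inactive = 0, bmi_score = 0),
    hypertension = b("hypertension", "(Intercept)" = -big, age_c = 0,
                     sexfemale = 0, education_c = 0, ses_c = 0,
                     smoking_former = 0, smoking_current = 0, inactive = 0,
                     bmi_score = 0),
    respiratory = b("respiratory", "(Intercept)" = -big, age_c = 0,
                    sexfemale = 0, education_c = 0, ses_c = 0,
                    smoking_former = 0, smoking_current = 0, inactive = 0,
                    bmi_score = 0),
    stroke = b("stroke", "(Intercept)" = -big, age_c = 0, sexfemale = 0,
               education_c = 0, ses_c = 0, smoking_former = 0,
               smoking_current = 0, inactive = 0, bmi_score = 0,
               hypertension = 0, diabetes = 0),
    hearing = b("hearing", "(Intercept)" = -big, age_c = 0, sexfemale = 0,
                hearing = 2 * big),
    vision = b("vision", "(Intercept)" = -big, age_c = 0, sexfemale = 0,
               diabetes = 0, vision = 2 * big),
    mmse_band = manual_transition_model(registry$mmse_band,
      list(zeta = c(-big / 2, big / 2),
           beta = c(age_c = 0, education_c = 0, mmse_band_score = big))))
  structure(models, class = "transition_bundle", interval_months = 24L)
}

# bundle with a single absorbing disease at a covariate-free 2-year onset
single_disease_bundle <- function(p2, name = "arthritis") {
  spec <- default_registry()[[name]]
  cf <- c("(Intercept)" = qlogis(p2), age_c = 0, sexfemale = 0,
          education_c = 0, ses_c = 0, smoking_former = 0,
          smoking_current = 0, inactive = 0, bmi_score = 0)
  structure(list(manual_transition_model(spec, cf)) |>
              stats::setNames(name),
            class = "transition_bundle", interval_months = 24L)
}

empty_bundle <- function() {
  structure(list(), class = "transition_bundle", interval_months = 24L)
}

# uniform single-cell allocation population: everyone 70y, band 26-30, community
one_cell_population <- function(n, seed = 1) {
  pop <- small_population(n, seed)
  pop$age_months <- 70L * 12L
  pop$mmse <- 28L
  pop$residence <- "community"
  pop
}
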