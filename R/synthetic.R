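#' Synthetic-population configuration
#'
#' Defines the marginal structure of the generated base population: the
#' age-band/sex composition of the 35+ population, logistic-in-age
#' prevalence curves per condition, and odds multipliers linking risk
#' factors (inactivity, obesity, current smoking) to disease presence.
#' Defaults emulate the broad structure of the England 2014 population aged
#' 35 and over (about 30.4 million people, of whom roughly a third are 65+),
#' with condition prevalences of published English order of magnitude at
#' older ages. The generator is a stand-in for restricted survey microdata
#' and is not calibrated to reproduce any published table.
#'
#' Prevalence curves are parameterised on the log-odds scale:
#' `logit(p) = intercept + slope * (age - 70)/10 + female * sex_offset`,
#' plus the per-condition risk-factor offsets for individuals who are
#' inactive, obese or current smokers.
#'
#' @param n_individuals sample size (default 30,000; the full-scale
#'   reference is a 1 percent population sample of about 303,589).
#' @param age_range inclusive age range in years at baseline.
#' @param age_sex_structure data frame with columns `age_lo`, `age_hi`,
#'   `sex`, `weight` (weights sum to 1).
#' @param prevalence_curves named list per condition of
#'   `c(intercept, slope, sex_offset)` log-odds parameters.
#' @param risk_effects named list per condition of
#'   `c(inactive, obese, smoker)` log-odds offsets.
#' @param scale_factor population persons represented per sample person.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_individuals = 30000L,
                             age_range = c(35L, 100L),
                             age_sex_structure = NULL,
                             prevalence_curves = NULL,
                             risk_effects = NULL,
                             scale_factor = 100) {
  if (is.null(age_sex_structure)) {
    bands <- data.frame(
      age_lo = c(35, 45, 55, 65, 75, 85, 95),
      age_hi = c(44, 54, 64, 74, 84, 94, 100),
      total = c(0.240, 0.250, 0.200, 0.160, 0.100, 0.044, 0.006),
      female = c(0.50, 0.51, 0.51, 0.52, 0.56, 0.63, 0.72))
    age_sex_structure <- rbind(
      data.frame(age_lo = bands$age_lo, age_hi = bands$age_hi, sex = "male",
                 weight = bands$total * (1 - bands$female)),
      data.frame(age_lo = bands$age_lo, age_hi = bands$age_hi, sex = "female",
                 weight = bands$total * bands$female))
  }
  if (abs(sum(age_sex_structure$weight) - 1) > 1e-8)
    .config_error("age/sex structure weights must sum to 1")
  if (is.null(prevalence_curves))
    prevalence_curves <- list(
      arthritis    = c(-0.68, 0.50,  0.30),
      cancer       = c(-2.47, 0.55,  0.00),
      chd          = c(-1.90, 0.50, -0.50),
      depression   = c(-4.20, -0.10, 0.50),
      diabetes     = c(-2.33, 0.35, -0.15),
      hypertension = c(-0.54, 0.50,  0.00),
      respiratory  = c(-1.89, 0.25,  0.00),
      stroke       = c(-3.18, 0.65, -0.20),
      hearing      = c(-2.51, 0.85, -0.30),
      vision       = c(-3.40, 0.75,  0.10))
  if (is.null(risk_effects))
    risk_effects <- list(
      arthritis    = c(inactive = 0.25, obese = 0.45, smoker = 0.00),
      cancer       = c(inactive = 0.10, obese = 0.10, smoker = 0.35),
      chd          = c(inactive = 0.35, obese = 0.40, smoker = 0.45),
      depression   = c(inactive = 0.40, obese = 0.20, smoker = 0.30),
      diabetes     = c(inactive = 0.35, obese = 0.90, smoker = 0.10),
      hypertension = c(inactive = 0.25, obese = 0.60, smoker = 0.10),
      respiratory  = c(inactive = 0.25, obese = 0.20, smoker = 0.85),
      stroke       = c(inactive = 0.35, obese = 0.30, smoker = 0.45),
      hearing      = c(inactive = 0.00, obese = 0.00, smoker = 0.10),
      vision       = c(inactive = 0.00, obese = 0.00, smoker = 0.10))
  structure(list(n_individuals = as.integer(n_individuals),
                 age_range = age_range,
                 age_sex_structure = age_sex_structure,
                 prevalence_curves = prevalence_curves,
                 risk_effects = risk_effects,
                 scale_factor = scale_factor),
            class = "synthetic_config")
}

# evaluate a prevalence curve at given ages for one condition
curve_prob <- function(curve, age, female, inactive, obese, smoker, effects) {
  eta <- curve[1] + curve[2] * (age - 70) / 10 + curve[3] * female +
    effects["inactive"] * inactive + effects["obese"] * obese +
    effects["smoker"] * smoker
  p <- stats::plogis(eta)
  if (any(is.nan(p) | p < 0 | p > 1))
    .config_error("degenerate prevalence curve (probability outside [0,1])")
  p
}

#' Generate a synthetic base population
#'
#' Draws `n_individuals` individuals with the configured age/sex structure,
#' age-graded education, marital status, smoking, inactivity, BMI category,
#' residence and MMSE, and condition flags from the logistic prevalence
#' curves with risk-factor correlation. Dementia is left `FALSE` throughout:
#' dementia status is assigned by [allocate_dementia()], outside the
#' simulation.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; the same seed reproduces the population exactly.
#' @return a validated population data frame (see [population]).
#' @export
generate_base_population <- function(config = synthetic_config(), seed = 1L) {
  set.seed(seed)
  n <- config$n_individuals
  st <- config$age_sex_structure
  cell <- sample.int(nrow(st), n, replace = TRUE, prob = st$weight)
  sex <- st$sex[cell]
  age <- st$age_lo[cell] + floor(runif(n) * (st$age_hi[cell] - st$age_lo[cell] + 1))
  age <- pmin(pmax(age, config$age_range[1]), config$age_range[2])
  age_months <- as.integer(age * 12L + floor(runif(n) * 12))
  z <- (age - 70) / 10
  female <- as.numeric(sex == "female")

  # education: younger cohorts more educated; ses independent of age
  p_high <- stats::plogis(-0.2 - 0.5 * z)
  p_low <- stats::plogis(-1.2 + 0.6 * z) * (1 - p_high)
  u <- runif(n)
  education <- 2L + (u < p_high) - (u > 1 - p_low)
  ses <- sample.int(3L, n, replace = TRUE, prob = c(0.3, 0.4, 0.3))

  # marital status: widowhood rises steeply with age, more so for women
  p_wid <- stats::plogis(-2.7 + 1.5 * z + 0.7 * female)
  u <- runif(n)
  marital <- ifelse(u < p_wid, "widowed",
                    ifelse(u < p_wid + (1 - p_wid) * 0.68, "married", "single"))

  # smoking: current declines with age, former rises
  p_cur <- stats::plogis(-2.0 - 0.3 * z)
  p_frm <- stats::plogis(-0.6 + 0.5 * z) * (1 - p_cur)
  u <- runif(n)
  smoking <- ifelse(u < p_cur, "current", ifelse(u < p_cur + p_frm, "former", "never"))

  inactive <- runif(n) < stats::plogis(-1.1 + 0.5 * z)
  bmi_cat <- sample.int(4L, n, replace = TRUE, prob = c(0.02, 0.34, 0.40, 0.24))

  # MMSE band then integer score within band
  p_imp <- stats::plogis(-4.4 + 0.9 * z)
  p_mild <- stats::plogis(-1.7 + 0.4 * z) * (1 - p_imp)
  u <- runif(n)
  band <- ifelse(u < p_imp, 1L, ifelse(u < p_imp + p_mild, 2L, 3L))
  lo <- c(8L, 21L, 26L)[band]
  hi <- c(20L, 25L, 30L)[band]
  mmse <- as.integer(lo + floor(runif(n) * (hi - lo + 1)))

  residence <- ifelse(runif(n) < stats::plogis(-6.8 + 2.8 * pmax(z, 0)),
                      "care_home", "community")

  pop <- data.frame(id = seq_len(n), sex = sex, education = education,
                    ses = ses, residence = residence,
                    age_months = age_months, alive = TRUE,
                    marital = marital, smoking = smoking,
                    inactive = inactive, bmi_cat = bmi_cat,
                    stringsAsFactors = FALSE)
  obese <- as.numeric(bmi_cat == 4L)
  smoker <- as.numeric(smoking == "current")
  for (cond in names(config$prevalence_curves)) {
    p <- curve_prob(config$prevalence_curves[[cond]], age, female,
                    as.numeric(inactive), obese, smoker,
                    config$risk_effects[[cond]])
    pop[[cond]] <- runif(n) < p
  }
  pop$dementia <- FALSE
  pop$mmse <- mmse
  pop <- pop[, POPULATION_COLUMNS]
  validate_population(pop)
  pop
}

#' Zero out all condition prevalence curves
#'
#' Convenience for tests: with all curves at `-Inf` log-odds no condition is
#' present at baseline.
#'
#' @param config a [synthetic_config()].
#' @return modified config.
#' @export
zero_prevalence <- function(config) {
  config$prevalence_curves <- lapply(config$prevalence_curves,
                                     function(cv) c(-Inf, 0, 0))
  config
}

#' Default ground-truth transition bundle
#'
#' Hand-specified 2-year transition models for every stochastic
#' characteristic, used to generate panels with known coefficients and to
#' drive simulations when no fitted bundle is supplied. Magnitudes are
#' chosen to be epidemiologically plausible (rising disease onset with age,
#' strong state persistence for behaviours, depression remission, downward
#' cognitive drift at older ages); they are package defaults, not estimates.
#'
#' @param registry a `characteristic_registry`.
#' @param interval_months interval the coefficients refer to (default 24).
#' @return a `transition_bundle`.
#' @export
default_truth_bundle <- function(registry = default_registry(),
                                 interval_months = 24L) {
  b <- function(name, ...) {
    cf <- c(...)
    manual_transition_model(registry[[name]], cf, interval_months)
  }
  onset <- function(name, intercept, age, female = 0, edu = -0.10,
                    ses = -0.10, frm = 0.05, cur = 0.15, inact = 0.25,
                    bmi = 0.20, extra = NULL) {
    cf <- c("(Intercept)" = intercept, age_c = age, sexfemale = female,
            education_c = edu, ses_c = ses, smoking_former = frm,
            smoking_current = cur, inactive = inact, bmi_score = bmi)
    manual_transition_model(registry[[name]], c(cf, extra), interval_months)
  }
  marital <- rbind(
    married = c("(Intercept)" = -4.0, age_c = 0.0, sexfemale = 0.0,
                marital_married = 8.0, marital_widowed = 0.0),
    widowed = c("(Intercept)" = -5.0, age_c = 1.0, sexfemale = 0.5,
                marital_married = 6.0, marital_widowed = 9.0))
  smoking <- rbind(
    former = c("(Intercept)" = -6.0, age_c = 0.1, sexfemale = 0.0,
               smoking_former = 9.0, smoking_current = 8.3),
    current = c("(Intercept)" = -7.0, age_c = -0.2, sexfemale = 0.0,
                smoking_former = 6.8, smoking_current = 11.0))
  models <- list(
    marital = manual_transition_model(registry$marital, marital, interval_months),
    smoking = manual_transition_model(registry$smoking, smoking, interval_months),
    inactive = b("inactive", "(Intercept)" = -2.3, age_c = 0.35,
                 sexfemale = 0.1, education_c = -0.15, bmi_score = 0.25,
                 inactive = 2.8),
    bmi_cat = manual_transition_model(registry$bmi_cat,
      list(zeta = c("under|normal" = -5.5, "normal|overweight" = 2.2,
                    "overweight|obese" = 7.0),
           beta = c(age_c = 0.12, inactive = 0.30, bmi_score = 4.5)),
      interval_months),
    arthritis = onset("arthritis", -3.20, 0.25, female = 0.30, bmi = 0.30),
    cancer = onset("cancer", -3.90, 0.45, female = -0.10, cur = 0.30),
    chd = onset("chd", -4.20, 0.40, female = -0.45, cur = 0.40,
                extra = c(hypertension = 0.50, diabetes = 0.40)),
    depression = b("depression", "(Intercept)" = -4.30, age_c = -0.10,
                   sexfemale = 0.40, education_c = -0.10, ses_c = -0.10,
                   inactive = 0.35, arthritis = 0.30, depression = 3.50),
    diabetes = onset("diabetes", -3.90, 0.30, female = -0.15, bmi = 0.55),
    hypertension = onset("hypertension", -3.20, 0.25, female = 0.00,
                         bmi = 0.35),
    respiratory = onset("respiratory", -4.20, 0.20, female = 0.05,
                        cur = 0.80),
    stroke = onset("stroke", -4.60, 0.50, female = -0.15, cur = 0.40,
                   extra = c(hypertension = 0.55, diabetes = 0.40)),
    hearing = b("hearing", "(Intercept)" = -4.10, age_c = 0.70,
                sexfemale = -0.25, hearing = 4.5),
    vision = b("vision", "(Intercept)" = -4.70, age_c = 0.60,
               sexfemale = 0.05, diabetes = 0.35, vision = 4.0),
    mmse_band = manual_transition_model(registry$mmse_band,
      list(zeta = c("0-20|21-25" = -2.2, "21-25|26-30" = 0.75),
           beta = c(age_c = -0.50, education_c = 0.40,
                    mmse_band_score = 3.8)),
      interval_months))
  structure(models, class = "transition_bundle",
            interval_months = as.integer(interval_months))
}

#' Generate a two-wave panel from a ground-truth bundle
#'
#' Produces the follow-up wave by evolving each characteristic under the
#' truth bundle over `interval_months` months. In `"monthly"` mode each
#' characteristic is advanced month by month with its monthly probabilities,
#' with cross-characteristic covariates held at their wave-1 values (own
#' lagged state and deterministic age advance monthly); in `"interval"` mode
#' the wave-2 state is a single draw from the truth's interval distribution.
#' Optional mortality applies the monthly survival schedule over the
#' interval; decedents appear in wave 2 with `alive = FALSE`.
#'
#' @param base base population data frame.
#' @param truth a `transition_bundle` covering every modelled characteristic.
#' @param interval_months months between the two waves (default 24).
#' @param seed integer seed.
#' @param schedule optional [mortality_schedule()]; `NULL` disables death.
#' @param mode `"monthly"` (default) or `"interval"`; recorded in the
#'   `mode` attribute of the result.
#' @param start_year calendar year of wave 1 (used only for mortality).
#' @return panel data frame (rows of wave 1 then wave 2, `wave` column),
#'   with attributes `mode` and `interval_months`.
#' @export
generate_panel <- function(base, truth, interval_months = 24L, seed = 1L,
                           schedule = NULL, mode = c("monthly", "interval"),
                           start_year = 2014L) {
  mode <- match.arg(mode)
  specs_needed <- names(modelled_characteristics(default_registry()))
  missing_models <- setdiff(specs_needed, names(truth))
  if (length(missing_models))
    .config_error(paste0("truth bundle missing model(s): ",
                         paste(missing_models, collapse = ", ")))
  set.seed(seed)
  n <- nrow(base)
  w2 <- base
  if (mode == "interval") {
    for (m in truth) {
      P <- predict_interval_probs(m, base)
      cur <- current_state_index(m, base)
      if (m$absorbing) {
        pres <- cur == 2L
        P[pres, 1L] <- 0
        P[pres, 2L] <- 1
      }
      k <- draw_categorical(P, runif(n))
      w2 <- assign_state(w2, m, seq_len(n), k)
    }
  } else {
    cov_frozen <- base  # cross-characteristic covariates held at wave 1
    for (m in truth) {
      state <- base  # own state evolves
      for (t in seq_len(interval_months)) {
        cov_frozen[[m$name]] <- state[[m$name]]
        if (m$name == "mmse_band") cov_frozen$mmse <- state$mmse
        cov_frozen$age_months <- base$age_months + (t - 1L)
        M <- monthly_transition_probabilities(m, cov_frozen)
        k <- draw_categorical(M, runif(n))
        state <- assign_state(state, m, seq_len(n), k)
      }
      w2 <- assign_state(w2, m, seq_len(n),
                         current_state_index(m, state))
      if (m$name == "mmse_band") w2$mmse <- state$mmse
    }
  }
  w2$age_months <- base$age_months + as.integer(interval_months)
  if (!is.null(schedule)) {
    lk <- monthly_survival_lookup(schedule)
    alive <- rep(TRUE, n)
    for (t in seq_len(interval_months)) {
      am <- base$age_months + (t - 1L)
      yr <- start_year + (t - 1L) %/% 12L
      s <- lk$arr[cbind(pmin(am %/% 12L, lk$terminal_age) - lk$age0 + 1L,
                        ifelse(base$sex == "male", 1L, 2L),
                        yr - lk$year0 + 1L)]
      alive <- alive & (runif(n) < s)
    }
    w2$alive <- alive
  }
  base$wave <- 1L
  w2$wave <- 2L
  panel <- rbind(base, w2)
  attr(panel, "mode") <- mode
  attr(panel, "interval_months") <- as.integer(interval_months)
  panel
}

# write back a drawn state index k into the population
assign_state <- function(pop, model, idx, k) {
  nm <- model$name
  switch(model$family,
    binary_logit = pop[[nm]][idx] <- k == 2L,
    ordinal_logit = {
      if (nm == "mmse_band") {
        old <- mmse_band_index(pop$mmse[idx])
        changed <- which(k != old)
        if (length(changed)) {
          lo <- c(8L, 21L, 26L)[k[changed]]
          hi <- c(20L, 25L, 30L)[k[changed]]
          pop$mmse[idx[changed]] <-
            as.integer(lo + floor(runif(length(changed)) * (hi - lo + 1L)))
        }
      } else pop[[nm]][idx] <- as.integer(k)
    },
    generalised_logit = pop[[nm]][idx] <- model$states[k])
  pop
}

# vectorised categorical draw: row-wise inverse CDF over probability matrix
draw_categorical <- function(M, u) {
  K <- ncol(M)
  k <- rep.int(1L, nrow(M))
  cum <- M[, 1L]
  if (K > 1) for (j in 2:K) {
    k <- k + (u > cum)
    if (j < K) cum <- cum + M[, j]
  }
  k
}
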