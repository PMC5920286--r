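# Covariate encoding shared by model fitting and the simulation engine.
# Encodings are fixed so that a coefficient vector stored in a bundle can be
# applied with plain column arithmetic in the monthly loop:
#   age        -> age_c            (age in years - 65) / 10
#   sex        -> sexfemale        0/1
#   education  -> education_c      code - 2  (centred 3-level ordinal)
#   ses        -> ses_c            code - 2
#   smoking    -> smoking_former, smoking_current   dummies (ref never)
#   marital    -> marital_married, marital_widowed  dummies (ref single)
#   bmi_cat    -> bmi_score        code - 2  (linear score)
#   mmse_band  -> mmse_band_score  band - 2  (linear score, band from mmse)
#   flags      -> 0/1 under their own name

encode_predictor <- function(pop, name, idx) {
  g <- function(col) if (is.null(idx)) pop[[col]] else pop[[col]][idx]
  switch(name,
    age = list(age_c = (g("age_months") / 12 - 65) / 10),
    sex = list(sexfemale = as.numeric(g("sex") == "female")),
    education = list(education_c = g("education") - 2),
    ses = list(ses_c = g("ses") - 2),
    smoking = {
      s <- g("smoking")
      list(smoking_former = as.numeric(s == "former"),
           smoking_current = as.numeric(s == "current"))
    },
    marital = {
      m <- g("marital")
      list(marital_married = as.numeric(m == "married"),
           marital_widowed = as.numeric(m == "widowed"))
    },
    bmi_cat = list(bmi_score = g("bmi_cat") - 2),
    mmse_band = list(mmse_band_score = mmse_band_index(g("mmse")) - 2),
    {
      if (is.null(pop[[name]]))
        .schema_error(paste0("covariate missing from population: ", name))
      stats::setNames(list(as.numeric(g(name))), name)
    })
}

# named list of covariate columns (no intercept), in predictor order
design_columns <- function(pop, predictors, idx = NULL) {
  cols <- list()
  for (p in predictors) cols <- c(cols, encode_predictor(pop, p, idx))
  cols
}

# design matrix without intercept
build_design <- function(pop, predictors, idx = NULL) {
  cols <- design_columns(pop, predictors, idx)
  n <- if (is.null(idx)) length(pop$id) else length(idx)
  if (!length(cols)) return(matrix(numeric(0), nrow = n, ncol = 0))
  do.call(cbind, cols)
}

# linear predictor from intercept + named coefficients over covariate columns
linear_predictor <- function(cols, beta) {
  eta <- rep.int(beta[["(Intercept)"]], length(cols[[1]]))
  for (nm in names(beta)) {
    if (nm == "(Intercept)") next
    b <- beta[[nm]]
    if (b != 0) eta <- eta + b * cols[[nm]]
  }
  eta
}
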