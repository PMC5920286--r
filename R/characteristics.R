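#' @name conditions
#' @title Condition names and built-in condition sets
#'
#' @description Nine chronic diseases and three impairments are tracked per
#' individual. Two built-in sets define the morbidity count: diseases only,
#' and diseases plus impairments (vision, hearing and cognitive impairment
#' no dementia, CIND).
NULL

DISEASES <- c("arthritis", "cancer", "chd", "dementia", "depression",
              "diabetes", "hypertension", "respiratory", "stroke")
IMPAIRMENTS <- c("cind", "hearing", "vision")

#' Construct a condition set
#'
#' @param name identifier for the set.
#' @param members character vector of condition names; `"cind"` is evaluated
#'   from the MMSE score and dementia flag, all others are state columns.
#' @return an object of class `condition_set`.
#' @export
condition_set <- function(name, members) {
  known <- c(DISEASES, IMPAIRMENTS)
  bad <- setdiff(members, known)
  if (length(bad))
    .config_error(paste0("unknown condition name(s) in set '", name, "': ",
                         paste(bad, collapse = ", ")))
  structure(list(name = name, members = members), class = "condition_set")
}

#' @rdname condition_set
#' @export
diseases_only <- function() condition_set("diseases_only", DISEASES)

#' @rdname condition_set
#' @export
diseases_and_impairments <- function()
  condition_set("diseases_and_impairments", c(DISEASES, IMPAIRMENTS))

#' Cognitive impairment no dementia (CIND)
#'
#' CIND is defined as an MMSE score of 0--20 in the absence of dementia.
#'
#' @param mmse integer MMSE scores, 0--30.
#' @param dementia logical dementia flags.
#' @return logical vector: `TRUE` where MMSE <= 20 and dementia is absent.
#' @export
classify_cind <- function(mmse, dementia) {
  if (any(is.na(mmse)) || any(mmse < 0 | mmse > 30))
    .domain_error("mmse must lie in [0, 30]")
  mmse <= 20 & !dementia
}

# MMSE band index: 1 = 0-20 (impaired), 2 = 21-25, 3 = 26-30
MMSE_BANDS <- c("0-20", "21-25", "26-30")
mmse_band_index <- function(mmse) {
  if (any(is.na(mmse)) || any(mmse < 0 | mmse > 30))
    .domain_error("mmse must lie in [0, 30]")
  1L + (mmse > 20) + (mmse > 25)
}

# condition indicator matrix (n x members) for a population data frame
condition_matrix <- function(pop, set) {
  stopifnot(inherits(set, "condition_set"))
  out <- matrix(FALSE, nrow = length(pop$id), ncol = length(set$members),
                dimnames = list(NULL, set$members))
  for (m in set$members) {
    out[, m] <- if (m == "cind") classify_cind(pop$mmse, pop$dementia)
                else if (is.null(pop[[m]]))
                  .config_error(paste0("condition column missing: ", m))
                else pop[[m]]
  }
  out
}

#' Count conditions and classify the multi-morbidity category
#'
#' @param pop population data frame (see [generate_base_population()]).
#' @param set a [condition_set()]; CIND membership is evaluated via
#'   [classify_cind()].
#' @return data frame with `raw_count` and `category`
#'   (one of `"0","1","2","3","4+"`; counts of four or more are pooled).
#' @export
count_conditions <- function(pop, set = diseases_only()) {
  raw <- rowSums(condition_matrix(pop, set))
  data.frame(raw_count = as.integer(raw),
             category = morbidity_category(raw),
             stringsAsFactors = FALSE)
}

MORBIDITY_LEVELS <- c("0", "1", "2", "3", "4+")

morbidity_category <- function(raw_count) {
  factor(ifelse(raw_count >= 4, "4+", as.character(raw_count)),
         levels = MORBIDITY_LEVELS)
}

#' Mental ill-health indicator
#'
#' Mental ill-health is defined as dementia, depression or CIND.
#'
#' @inheritParams count_conditions
#' @return logical vector.
#' @export
has_mental_ill_health <- function(pop) {
  pop$dementia | pop$depression | classify_cind(pop$mmse, pop$dementia)
}

#' Define one characteristic of the individual state
#'
#' A characteristic is `fixed` (never changes: sex, education, socio-economic
#' status, residence), `deterministic` (age), or `stochastic` (updated by a
#' monthly draw from a fitted transition model). Dementia is stochastic but
#' carries no transition model: it is allocated outside the simulation (see
#' [allocate_dementia()]) and never appears as a predictor.
#'
#' @param name column name in the population table (for ordinal/categorical
#'   characteristics the column holds the state; the MMSE band is derived
#'   from the `mmse` column).
#' @param kind one of `"fixed"`, `"deterministic"`, `"stochastic"`.
#' @param states ordered state labels; binary conditions use
#'   `c("absent", "present")`.
#' @param model_family one of `"binary_logit"`, `"ordinal_logit"`,
#'   `"generalised_logit"`, `"none"`.
#' @param predictors characteristic names entering the transition model in
#'   addition to the model's own lagged state (see Details); must not
#'   include dementia.
#' @param absorbing once `"present"`, stays present (binary only).
#' @return an object of class `characteristic_spec`.
#' @export
characteristic_spec <- function(name, kind, states,
                                model_family = "none",
                                predictors = character(),
                                absorbing = FALSE) {
  kind <- match.arg(kind, c("fixed", "deterministic", "stochastic"))
  model_family <- match.arg(model_family,
    c("none", "binary_logit", "ordinal_logit", "generalised_logit"))
  if (kind != "stochastic" && model_family != "none")
    .config_error(paste0(name, ": fixed/deterministic characteristics take no model"))
  if (absorbing && length(states) != 2L)
    .config_error(paste0(name, ": absorbing is only meaningful for binary characteristics"))
  if ("dementia" %in% predictors)
    .config_error(paste0(name, ": dementia must not be used as a predictor"))
  structure(list(name = name, kind = kind, states = states,
                 model_family = model_family, predictors = predictors,
                 absorbing = absorbing),
            class = "characteristic_spec")
}

#' Default characteristic registry
#'
#' The registry fixes the update order of the monthly loop: behaviours and
#' marital status first, then diseases, then impairments. Each update within
#' a month sees the already-updated values of earlier characteristics.
#' Diseases are ever-diagnosed (absorbing) except depression, which may
#' remit; impairments and behaviours are recoverable.
#'
#' @param education_levels,ses_levels labels for the 3-level ordinal codings
#'   (the coding of the source data is survey-specific, so labels are
#'   configurable).
#' @return an object of class `characteristic_registry` (named list of
#'   [characteristic_spec()]s in update order).
#' @export
default_registry <- function(education_levels = c("low", "mid", "high"),
                             ses_levels = c("low", "mid", "high")) {
  base_predictors <- c("age", "sex", "education", "ses",
                       "smoking", "inactive", "bmi_cat")
  bin <- c("absent", "present")
  specs <- list(
    characteristic_spec("sex", "fixed", c("male", "female")),
    characteristic_spec("education", "fixed", education_levels),
    characteristic_spec("ses", "fixed", ses_levels),
    characteristic_spec("residence", "fixed", c("community", "care_home")),
    characteristic_spec("age", "deterministic", "months"),
    # behaviours / sociodemographic
    characteristic_spec("marital", "stochastic",
                        c("single", "married", "widowed"),
                        "generalised_logit", c("age", "sex", "marital")),
    characteristic_spec("smoking", "stochastic",
                        c("never", "former", "current"),
                        "generalised_logit", c("age", "sex", "smoking")),
    characteristic_spec("inactive", "stochastic", bin, "binary_logit",
                        c("age", "sex", "education", "bmi_cat", "inactive")),
    characteristic_spec("bmi_cat", "stochastic",
                        c("under", "normal", "overweight", "obese"),
                        "ordinal_logit", c("age", "inactive", "bmi_cat")),
    # diseases (dementia allocated outwith the simulation)
    characteristic_spec("arthritis", "stochastic", bin, "binary_logit",
                        base_predictors, absorbing = TRUE),
    characteristic_spec("cancer", "stochastic", bin, "binary_logit",
                        base_predictors, absorbing = TRUE),
    characteristic_spec("chd", "stochastic", bin, "binary_logit",
                        c(base_predictors, "hypertension", "diabetes"),
                        absorbing = TRUE),
    characteristic_spec("dementia", "stochastic", bin, "none"),
    characteristic_spec("depression", "stochastic", bin, "binary_logit",
                        c("age", "sex", "education", "ses", "inactive",
                          "arthritis", "depression")),
    characteristic_spec("diabetes", "stochastic", bin, "binary_logit",
                        base_predictors, absorbing = TRUE),
    characteristic_spec("hypertension", "stochastic", bin, "binary_logit",
                        base_predictors, absorbing = TRUE),
    characteristic_spec("respiratory", "stochastic", bin, "binary_logit",
                        base_predictors, absorbing = TRUE),
    characteristic_spec("stroke", "stochastic", bin, "binary_logit",
                        c(base_predictors, "hypertension", "diabetes"),
                        absorbing = TRUE),
    # impairments
    characteristic_spec("hearing", "stochastic", bin, "binary_logit",
                        c("age", "sex", "hearing")),
    characteristic_spec("vision", "stochastic", bin, "binary_logit",
                        c("age", "sex", "diabetes", "vision")),
    characteristic_spec("mmse_band", "stochastic", MMSE_BANDS,
                        "ordinal_logit", c("age", "education", "mmse_band"))
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  structure(specs, class = "characteristic_registry")
}

# stochastic characteristics that carry a transition model, in update order
modelled_characteristics <- function(registry) {
  keep <- vapply(registry, function(s)
    s$kind == "stochastic" && s$model_family != "none", logical(1))
  registry[keep]
}

#' Read or write a characteristic registry as JSON
#'
#' @param registry a `characteristic_registry`.
#' @param path file path.
#' @return `read_registry` returns a `characteristic_registry`.
#' @export
write_registry <- function(registry, path) {
  jsonlite::write_json(lapply(unclass(registry), unclass), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(raw, function(s)
    characteristic_spec(s$name, s$kind, s$states, s$model_family,
                        as.character(unlist(s$predictors)),
                        isTRUE(s$absorbing)))
  names(specs) <- vapply(specs, `[[`, "", "name")
  structure(specs, class = "characteristic_registry")
}

#' @export
print.characteristic_registry <- function(x, ...) {
  cat("<characteristic_registry> ", length(x), " characteristics\n", sep = "")
  for (s in x)
    cat(sprintf("  %-12s %-13s %-17s %s\n", s$name, s$kind, s$model_family,
                if (s$absorbing) "[absorbing]" else ""))
  invisible(x)
}
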