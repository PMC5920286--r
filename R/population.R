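#' @name population
#' @title The individual-state table
#'
#' @description A population is a plain data frame with one row per
#' individual and the columns below. Binary conditions are logical, ordinal
#' characteristics are integer codes (education/ses 1--3, bmi_cat 1--4 for
#' under/normal/overweight/obese), categorical characteristics are labels.
#'
#' \itemize{
#'   \item `id` integer, unique
#'   \item `sex` "male"/"female"; `education`, `ses` integer 1--3;
#'     `residence` "community"/"care_home" (all fixed)
#'   \item `age_months` integer, >= 420 (35 years); `alive` logical
#'   \item `marital` "single"/"married"/"widowed";
#'     `smoking` "never"/"former"/"current"; `inactive` logical;
#'     `bmi_cat` integer 1--4
#'   \item disease flags `arthritis cancer chd dementia depression diabetes
#'     hypertension respiratory stroke` (logical)
#'   \item impairment flags `hearing vision` (logical); `mmse` integer 0--30
#' }
NULL

POPULATION_COLUMNS <- c(
  "id", "sex", "education", "ses", "residence", "age_months", "alive",
  "marital", "smoking", "inactive", "bmi_cat",
  DISEASES, "hearing", "vision", "mmse")

LOGICAL_COLUMNS <- c("alive", "inactive", DISEASES, "hearing", "vision")

#' Validate a population table
#'
#' Checks column presence, types, ranges and id uniqueness; missing values
#' are forbidden.
#'
#' @param pop data frame as described in [population].
#' @return `pop`, invisibly, after validation.
#' @export
validate_population <- function(pop) {
  missing_cols <- setdiff(POPULATION_COLUMNS, names(pop))
  if (length(missing_cols))
    .input_error(paste0("population missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  if (anyNA(pop[POPULATION_COLUMNS]))
    .input_error("population contains missing values")
  if (anyDuplicated(pop$id))
    .input_error("population ids are not unique")
  if (any(pop$age_months < 35L * 12L))
    .input_error("age_months below 420 (35 years)")
  if (any(pop$mmse < 0 | pop$mmse > 30))
    .input_error("mmse outside [0, 30]")
  chk <- function(col, values)
    if (!all(pop[[col]] %in% values))
      .input_error(paste0("invalid values in column ", col))
  chk("sex", c("male", "female"))
  chk("residence", c("community", "care_home"))
  chk("marital", c("single", "married", "widowed"))
  chk("smoking", c("never", "former", "current"))
  chk("education", 1:3); chk("ses", 1:3); chk("bmi_cat", 1:4)
  for (col in LOGICAL_COLUMNS)
    if (!is.logical(pop[[col]])) .input_error(paste0(col, " must be logical"))
  invisible(pop)
}

#' Read / write a population CSV
#'
#' The CSV has one column per field with a mandatory header row; lines
#' starting with `#` (manifest comments) are skipped. Missing values are
#' forbidden after load.
#'
#' @param path file path.
#' @param pop population data frame.
#' @param comment optional comment line(s) written before the header,
#'   prefixed with `#`.
#' @return `read_population` returns the validated data frame.
#' @export
read_population <- function(path) {
  pop <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  for (col in intersect(LOGICAL_COLUMNS, names(pop)))
    pop[[col]] <- as.logical(pop[[col]])
  validate_population(pop)
  pop
}

#' @rdname read_population
#' @export
write_population <- function(pop, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(pop, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
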