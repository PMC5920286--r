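#' Validate a mortality schedule
#'
#' A schedule holds annual death probabilities `q` by calendar year, sex and
#' single year of age. Ages must be contiguous from 35 to a terminal age
#' with `q = 1` at the terminal age, for every (year, sex) pair present.
#'
#' @param schedule data frame with columns `year`, `sex`, `age`, `q`.
#' @return the schedule, invisibly, with class `mortality_schedule`.
#' @export
mortality_schedule <- function(schedule) {
  need <- c("year", "sex", "age", "q")
  if (!all(need %in% names(schedule)))
    .input_error("schedule must have columns year, sex, age, q")
  if (anyNA(schedule[need])) .input_error("schedule contains missing values")
  if (any(schedule$q < 0 | schedule$q > 1))
    .domain_error("annual death probabilities outside [0, 1]")
  for (yr in unique(schedule$year)) for (sx in unique(schedule$sex)) {
    s <- schedule[schedule$year == yr & schedule$sex == sx, ]
    if (!nrow(s)) next
    ages <- sort(s$age)
    if (ages[1] != 35L || !identical(ages, seq(35L, max(ages))))
      .input_error(sprintf("schedule ages not contiguous from 35 (%s %d)", sx, yr))
    if (s$q[s$age == max(ages)] != 1)
      .input_error(sprintf("terminal age must have q = 1 (%s %d)", sx, yr))
  }
  class(schedule) <- c("mortality_schedule", "data.frame")
  invisible(schedule)
}

#' Gompertz-type synthetic mortality schedule
#'
#' A packaged stand-in for a national projected-mortality schedule:
#' `q(age, sex, year) = min(1, a_sex * exp(b * (age - 35)) * (1 - improvement)^(year - 2014))`
#' closed with `q = 1` at the terminal age. Default level and slope give a
#' period life expectancy at 65 of roughly 18--21 years in 2015, with a
#' steady annual mortality improvement driving life-expectancy gains over
#' the projection. This synthetic schedule is not an official projection.
#'
#' @param years calendar years covered.
#' @param a_male,a_female baseline hazard level at age 35.
#' @param b log-hazard slope per year of age.
#' @param improvement annual proportional reduction in q.
#' @param terminal_age age at which q is set to 1.
#' @return a `mortality_schedule`.
#' @export
gompertz_schedule <- function(years = 2014:2036,
                              a_male = 1.05e-3, a_female = 7.8e-4,
                              b = 0.088, improvement = 0.012,
                              terminal_age = 105L) {
  grid <- expand.grid(year = years, sex = c("male", "female"),
                      age = 35:terminal_age, stringsAsFactors = FALSE)
  a <- ifelse(grid$sex == "male", a_male, a_female)
  q <- pmin(1, a * exp(b * (grid$age - 35)) *
                 (1 - improvement)^(grid$year - min(years)))
  q[grid$age == terminal_age] <- 1
  mortality_schedule(data.frame(grid, q = q))
}

#' Monthly survival from an annual death probability
#'
#' Under a constant hazard within the year, the probability of surviving one
#' month is `(1 - q)^(1/12)`, so twelve months compound to the annual
#' survival `1 - q` exactly.
#'
#' @param q_annual annual death probability in \[0, 1\].
#' @return monthly survival probability.
#' @export
annual_to_monthly_survival <- function(q_annual) {
  if (any(is.na(q_annual)) || any(q_annual < 0 | q_annual > 1))
    .domain_error("annual death probability outside [0, 1]")
  (1 - q_annual)^(1 / 12)
}

#' Build a period lifetable
#'
#' Standard single-year period lifetable with deaths assumed mid-interval
#' (`a_x = 0.5`): `l_{x+1} = l_x (1 - q_x)`, `L_x = l_x - d_x / 2`,
#' `e_x = sum_{y >= x} L_y / l_x`.
#'
#' @param schedule a [mortality_schedule()].
#' @param year,sex the (year, sex) slice to use.
#' @param start_age first age of the table (default 65).
#' @param radix survivors at `start_age`.
#' @return data frame of class `lifetable` with columns `age, q, l, d, L, e`.
#' @export
build_lifetable <- function(schedule, year, sex, start_age = 65L,
                            radix = 1e5) {
  s <- schedule[schedule$year == year & schedule$sex == sex, ]
  if (!nrow(s)) .input_error(sprintf("schedule has no rows for %s %d", sex, year))
  s <- s[order(s$age), ]
  s <- s[s$age >= start_age, ]
  if (!identical(as.integer(s$age), seq(as.integer(start_age), max(s$age))))
    .input_error("gap in schedule ages")
  q <- s$q
  n <- length(q)
  l <- radix * cumprod(c(1, 1 - q[-n]))
  d <- l * q
  L <- l - d / 2
  e <- rev(cumsum(rev(L))) / l
  structure(data.frame(age = s$age, q = q, l = l, d = d, L = L, e = e),
            class = c("lifetable", "data.frame"))
}

#' Read / write a mortality schedule CSV (columns year,sex,age,q)
#'
#' @param path file path.
#' @param schedule a `mortality_schedule`.
#' @return `read_mortality_schedule` returns a validated schedule.
#' @export
read_mortality_schedule <- function(path) {
  mortality_schedule(utils::read.csv(path, stringsAsFactors = FALSE,
                                     comment.char = "#"))
}

#' @rdname read_mortality_schedule
#' @export
write_mortality_schedule <- function(schedule, path) {
  utils::write.csv(schedule, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# fast lookup array of monthly survival probabilities:
# dims [age 35..terminal, sex (male=1, female=2), year]
monthly_survival_lookup <- function(schedule) {
  ages <- sort(unique(schedule$age))
  years <- sort(unique(schedule$year))
  arr <- array(NA_real_, dim = c(length(ages), 2L, length(years)),
               dimnames = list(ages, c("male", "female"), years))
  sexi <- ifelse(schedule$sex == "male", 1L, 2L)
  arr[cbind(match(schedule$age, ages), sexi,
            match(schedule$year, years))] <-
    (1 - schedule$q)^(1 / 12)
  list(arr = arr, age0 = ages[1], year0 = years[1],
       terminal_age = max(ages), years = range(years))
}
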