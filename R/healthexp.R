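#' Age-specific morbidity-category prevalence surface
#'
#' Proportion of the alive population in each morbidity category
#' (`0,1,2,3,4+`) at each single year of age, for one sex, computed from a
#' snapshot. Proportions are estimated within `band_width`-year age bands
#' (default 5) to stabilise single-year cells at reduced sample sizes, and
#' assigned to every age in the band; ages above the last populated band
#' carry the last band's distribution forward. `band_width = 1` gives raw
#' single-year proportions.
#'
#' @param snapshot population data frame (dementia allocated).
#' @param set a [condition_set()].
#' @param sex `"male"` or `"female"`.
#' @param ages integer ages the surface must cover (default 65:105).
#' @param band_width age-band width in years for smoothing.
#' @return matrix `length(ages) x 5` of category proportions (rows sum
#'   to 1), with class `prevalence_surface`.
#' @export
prevalence_surface <- function(snapshot, set = diseases_only(),
                               sex = "male", ages = 65:105,
                               band_width = 5L) {
  snap <- snapshot[snapshot$sex == sex, , drop = FALSE]
  if (!nrow(snap)) .input_error(paste0("no individuals of sex ", sex))
  cat <- count_conditions(snap, set)$category
  agey <- snap$age_months %/% 12L
  band_of <- function(a) ages[1] + band_width * ((a - ages[1]) %/% band_width)
  pi <- matrix(NA_real_, length(ages), length(MORBIDITY_LEVELS),
               dimnames = list(ages, MORBIDITY_LEVELS))
  last <- NULL
  for (b in unique(band_of(ages))) {
    sel <- agey >= b & agey < b + band_width & agey >= ages[1]
    if (sum(sel)) {
      last <- as.numeric(table(cat[sel]) / sum(sel))
    }
    if (is.null(last))
      next
    rows <- which(band_of(ages) == b)
    pi[rows, ] <- matrix(last, length(rows), length(last), byrow = TRUE)
  }
  # leading empty bands (no individuals yet that old/young): carry backward
  if (anyNA(pi[, 1])) {
    filled <- which(!is.na(pi[, 1]))
    if (!length(filled)) .input_error("no individuals in requested age range")
    for (i in which(is.na(pi[, 1])))
      pi[i, ] <- pi[filled[which.min(abs(filled - i))], ]
  }
  structure(pi, class = c("prevalence_surface", "matrix"))
}

#' Sullivan health expectancy by morbidity category
#'
#' Splits remaining life expectancy at `from_age` into expected years lived
#' in each morbidity category, by weighting lifetable person-years with the
#' age-specific category prevalence:
#' `years_c = (1/l_from) * sum_x pi_c(x) * L_x`.
#' Category years sum to total life expectancy by construction.
#'
#' @param lifetable a [build_lifetable()] result.
#' @param surface a [prevalence_surface()] covering the lifetable ages.
#' @param from_age age from which expectancies are computed (default 65).
#' @return object of class `health_expectancy`: list with `total_le`,
#'   `years` (named by category), and `shares` (percent of LE, 1 dp).
#' @export
sullivan <- function(lifetable, surface, from_age = 65L) {
  lt <- lifetable[lifetable$age >= from_age, , drop = FALSE]
  if (!nrow(lt)) .input_error("lifetable does not cover from_age")
  srows <- match(lt$age, as.integer(rownames(surface)))
  if (anyNA(srows))
    .input_error("prevalence surface does not cover the lifetable ages")
  pi <- surface[srows, , drop = FALSE]
  l0 <- lt$l[1]
  years <- colSums(pi * lt$L) / l0
  total <- sum(lt$L) / l0
  structure(list(total_le = total, years = years,
                 shares = share_of_le(years, total), from_age = from_age),
            class = "health_expectancy")
}

#' Share of life expectancy spent in a state
#'
#' `years / total_le * 100`, rounded half away from zero to 1 decimal place.
#'
#' @param years_in_state years (0 <= years <= total).
#' @param total_le total life expectancy (> 0).
#' @return percent, 1 decimal place.
#' @export
share_of_le <- function(years_in_state, total_le) {
  if (any(total_le <= 0)) .input_error("total life expectancy must be > 0")
  if (any(years_in_state < 0 | years_in_state > total_le + 1e-9))
    .input_error("years in state outside [0, total_le]")
  round_half_out(years_in_state / total_le * 100, 1)
}

# years in an aggregate category ("2+" = 2,3,4+) from a sullivan result
category_years <- function(hx, category) {
  members <- if (category == "2+") c("2", "3", "4+") else category
  if (!all(members %in% names(hx$years)))
    .input_error(paste0("unknown morbidity category ", category))
  sum(hx$years[members])
}

#' Decompose change in category-specific expected years
#'
#' Splits the change between settings a and b (e.g. years lived with 2+
#' diseases from 65 in 2015 vs 2035) into a mortality component and a
#' prevalence component by symmetric two-way stepwise replacement:
#' each component averages the two replacement orders, so the split is
#' order-invariant and the components sum exactly to the total change.
#'
#' @param lt_a,lt_b lifetables for the two settings.
#' @param surf_a,surf_b prevalence surfaces for the two settings.
#' @param category morbidity category (`"0","1","2","3","4+"` or `"2+"`).
#' @param from_age age from which years are computed.
#' @return object of class `decomposition_result`: list with `delta`,
#'   `mortality`, `prevalence` (years) and `shares` (% of delta).
#' @export
decompose_change <- function(lt_a, surf_a, lt_b, surf_b, category = "2+",
                             from_age = 65L) {
  if (!identical(lt_a$age, lt_b$age))
    .input_error("lifetable age grids differ between settings")
  S <- function(lt, surf)
    category_years(sullivan(lt, surf, from_age), category)
  Saa <- S(lt_a, surf_a); Sab <- S(lt_a, surf_b)
  Sba <- S(lt_b, surf_a); Sbb <- S(lt_b, surf_b)
  mortality  <- 0.5 * ((Sba - Saa) + (Sbb - Sab))
  prevalence <- 0.5 * ((Sab - Saa) + (Sbb - Sba))
  delta <- Sbb - Saa
  shares <- if (abs(delta) > 1e-12)
    c(mortality = 100 * mortality / delta,
      prevalence = 100 * prevalence / delta)
  else c(mortality = NA_real_, prevalence = NA_real_)
  structure(list(category = category, delta = delta, mortality = mortality,
                 prevalence = prevalence, shares = shares),
            class = "decomposition_result")
}

#' @export
print.health_expectancy <- function(x, ...) {
  cat("<health_expectancy> from age ", x$from_age, ": total LE ",
      sprintf("%.2f", x$total_le), " years\n", sep = "")
  for (k in names(x$years))
    cat(sprintf("  %-3s %6.2f years (%s%%)\n", k, x$years[k],
                format(x$shares[k])))
  invisible(x)
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat("<decomposition_result> category ", x$category, ": delta ",
      sprintf("%.3f", x$delta), " years = mortality ",
      sprintf("%.3f", x$mortality), " + prevalence ",
      sprintf("%.3f", x$prevalence), "\n", sep = "")
  invisible(x)
}
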