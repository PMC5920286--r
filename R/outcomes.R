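REPORT_AGE_GROUPS <- c("65-74", "75-84", "85+", "65+")

report_age_group <- function(age_years) {
  cut(age_years, breaks = c(64, 74, 84, Inf),
      labels = c("65-74", "75-84", "85+"), right = TRUE)
}

snapshot_list <- function(x) {
  if (inherits(x, "simulation_output")) x$snapshots
  else if (is.data.frame(x)) stats::setNames(list(x), "snapshot")
  else x
}

#' Prevalence of (and numbers with) individual conditions
#'
#' For each snapshot year, reporting age group (65-74, 75-84, 85+ and all
#' 65+) and condition: the percentage of the alive population with the
#' condition (1 decimal place) and the represented head count
#' (sample count x `scale_factor`, rounded to the nearest 100). CIND is
#' evaluated from MMSE and the dementia flag, so snapshots should be
#' post-allocation.
#'
#' @param x a `simulation_output`, named list of snapshots, or a single
#'   population data frame.
#' @param conditions condition names (default: all 12).
#' @param scale_factor persons represented per sample person.
#' @return data frame with columns `year, age_group, condition, n_sample,
#'   alive, prevalence, count`.
#' @export
prevalence_table <- function(x, conditions = c(DISEASES, IMPAIRMENTS),
                             scale_factor = 100) {
  snaps <- snapshot_list(x)
  rows <- list()
  for (yr in names(snaps)) {
    snap <- snaps[[yr]]
    cm <- condition_matrix(snap, condition_set("report", conditions))
    grp <- report_age_group(snap$age_months %/% 12L)
    for (ag in REPORT_AGE_GROUPS) {
      in_grp <- if (ag == "65+") !is.na(grp) else !is.na(grp) & grp == ag
      alive_n <- sum(in_grp)
      for (cond in conditions) {
        if (alive_n == 0L) {
          warning("empty stratum: ", yr, " ", ag, call. = FALSE)
          rows[[length(rows) + 1L]] <- data.frame(
            year = yr, age_group = ag, condition = cond, n_sample = 0L,
            alive = 0L, prevalence = NA_real_, count = 0)
          next
        }
        n_with <- sum(cm[in_grp, cond])
        rows[[length(rows) + 1L]] <- data.frame(
          year = yr, age_group = ag, condition = cond,
          n_sample = n_with, alive = alive_n,
          prevalence = round_half_out(100 * n_with / alive_n, 1),
          count = round_nearest(n_with * scale_factor, 100))
      }
    }
  }
  do.call(rbind, rows)
}

#' Multi-morbidity category distribution by age group and year
#'
#' Categories `0, 1, 2, 3, 4+` from [count_conditions()], plus the derived
#' `2+` (multi-morbid) row equal to the sum of the 2, 3 and 4+ rows.
#'
#' @inheritParams prevalence_table
#' @param set a [condition_set()] defining the morbidity count.
#' @return data frame with columns `year, age_group, category, n_sample,
#'   alive, prevalence, count`.
#' @export
multimorbidity_table <- function(x, set = diseases_only(),
                                 scale_factor = 100) {
  snaps <- snapshot_list(x)
  rows <- list()
  for (yr in names(snaps)) {
    snap <- snaps[[yr]]
    cat <- count_conditions(snap, set)$category
    grp <- report_age_group(snap$age_months %/% 12L)
    for (ag in REPORT_AGE_GROUPS) {
      in_grp <- if (ag == "65+") !is.na(grp) else !is.na(grp) & grp == ag
      alive_n <- sum(in_grp)
      tab <- table(cat[in_grp])
      counts <- c(as.numeric(tab[MORBIDITY_LEVELS]),
                  sum(tab[c("2", "3", "4+")]))
      counts[is.na(counts)] <- 0
      lev <- c(MORBIDITY_LEVELS, "2+")
      if (alive_n == 0L) warning("empty stratum: ", yr, " ", ag, call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        year = yr, age_group = ag, category = lev, n_sample = counts,
        alive = alive_n,
        prevalence = if (alive_n) round_half_out(100 * counts / alive_n, 1)
                     else NA_real_,
        count = round_nearest(counts * scale_factor, 100))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentage change in counts between two years
#'
#' `(n_end - n_start) / n_start * 100`, rounded half away from zero to one
#' decimal place, matching the presentation of projection tables.
#'
#' @param n_start,n_end counts (vectors recycle); `n_start` must be > 0.
#' @return percent change, 1 decimal place.
#' @export
percent_change <- function(n_start, n_end) {
  if (any(is.na(n_start)) || any(n_start <= 0))
    .domain_error("percent change undefined for n_start <= 0")
  round_half_out((n_end - n_start) / n_start * 100, 1)
}

#' Mental ill-health overlap by morbidity-count category
#'
#' Among individuals whose morbidity count (under `set`) falls in each
#' category 1, 2, 3, 4+, the percentage with mental ill-health (dementia,
#' depression or CIND). By default mental-ill-health members count toward
#' the morbidity total; `include_mih_in_count = FALSE` instead counts
#' categories over the non-mental conditions only, so category k reads
#' "mental ill-health co-existing with k other conditions".
#'
#' @param snapshot population data frame (dementia allocated).
#' @param set a [condition_set()].
#' @param include_mih_in_count see Description.
#' @return data frame `category, n, n_mih, pct_mih`.
#' @export
mental_illhealth_overlap <- function(snapshot, set = diseases_and_impairments(),
                                     include_mih_in_count = TRUE) {
  mih <- has_mental_ill_health(snapshot)
  members <- set$members
  if (!include_mih_in_count)
    members <- setdiff(members, c("dementia", "depression", "cind"))
  raw <- rowSums(condition_matrix(snapshot, condition_set("overlap", members)))
  cat <- morbidity_category(raw)
  out <- data.frame(category = c("1", "2", "3", "4+"), n = NA_integer_,
                    n_mih = NA_integer_, pct_mih = NA_real_)
  for (i in seq_len(nrow(out))) {
    sel <- cat == out$category[i]
    out$n[i] <- sum(sel)
    out$n_mih[i] <- sum(mih[sel])
    if (out$n[i] == 0L) {
      warning("empty morbidity category ", out$category[i], call. = FALSE)
    } else {
      out$pct_mih[i] <- round_half_out(100 * out$n_mih[i] / out$n[i], 1)
    }
  }
  out
}
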