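test_that("prevalence rows follow the direct arithmetic", {
  pop <- small_population(40, seed = 1)
  pop$age_months <- 70L * 12L
  pop <- pop[1:10, ]
  pop$stroke <- c(rep(TRUE, 3), rep(FALSE, 7))
  pop$cancer <- FALSE
  tab <- suppressWarnings(
    prevalence_table(stats::setNames(list(pop), "2015"),
                     conditions = c("stroke", "cancer"), scale_factor = 100))
  row <- tab[tab$age_group == "65-74" & tab$condition == "stroke", ]
  expect_equal(row$prevalence, 30.0)
  expect_equal(row$count, 300)
  expect_equal(tab$prevalence[tab$age_group == "65+" &
                                tab$condition == "cancer"], 0.0)
})

test_that("prevalence and multi-morbidity tables agree with a groupby recount", {
  pop <- random_states(3000, seed = 22)
  snaps <- stats::setNames(list(pop), "2015")
  tab <- prevalence_table(snaps, scale_factor = 100)
  age <- pop$age_months %/% 12L
  grp_sel <- list(`65-74` = age >= 65 & age <= 74,
                  `75-84` = age >= 75 & age <= 84,
                  `85+` = age >= 85, `65+` = age >= 65)
  for (ag in names(grp_sel)) for (cond in c("arthritis", "dementia", "cind")) {
    present <- if (cond == "cind") pop$mmse <= 20 & !pop$dementia
               else pop[[cond]]
    n <- sum(grp_sel[[ag]])
    want <- round_half_out(100 * sum(present & grp_sel[[ag]]) / n, 1)
    expect_equal(tab$prevalence[tab$age_group == ag & tab$condition == cond],
                 want)
  }
  mm <- multimorbidity_table(snaps, diseases_only())
  counts <- rowSums(sapply(c("arthritis", "cancer", "chd", "dementia",
                             "depression", "diabetes", "hypertension",
                             "respiratory", "stroke"), function(d) pop[[d]]))
  for (ag in names(grp_sel)) {
    sel <- grp_sel[[ag]]
    for (k in c("0", "1", "2", "3")) {
      want <- sum(counts[sel] == as.integer(k))
      expect_equal(mm$n_sample[mm$age_group == ag & mm$category == k], want)
    }
    expect_equal(mm$n_sample[mm$age_group == ag & mm$category == "4+"],
                 sum(counts[sel] >= 4))
    expect_equal(mm$n_sample[mm$age_group == ag & mm$category == "2+"],
                 sum(counts[sel] >= 2))
  }
  # scaled counts over exclusive categories add up to the stratum total
  for (ag in names(grp_sel)) {
    sub <- mm[mm$age_group == ag & mm$category %in% c("0", "1", "2", "3", "4+"), ]
    expect_equal(sum(sub$n_sample), sub$alive[1])
  }
})

test_that("multi-morbidity categories behave at the edges", {
  pop <- small_population(30, seed = 7)
  for (d in c("arthritis", "cancer", "chd", "dementia", "depression",
              "diabetes", "hypertension", "respiratory", "stroke"))
    pop[[d]] <- FALSE
  pop$arthritis <- TRUE
  pop$age_months <- 70L * 12L
  mm <- suppressWarnings(
    multimorbidity_table(stats::setNames(list(pop), "2020"), diseases_only()))
  sub <- mm[mm$age_group == "65+", ]
  expect_equal(sub$prevalence[sub$category == "1"], 100.0)
  expect_equal(sub$prevalence[sub$category == "2+"], 0.0)
  # complement identity: 2+ = 100 - (0 + 1) up to reporting rounding
  mm2 <- multimorbidity_table(stats::setNames(list(random_states(500, 3)), "y"),
                              diseases_only())
  for (ag in unique(mm2$age_group)) {
    s <- mm2[mm2$age_group == ag, ]
    expect_lt(abs(s$prevalence[s$category == "2+"] -
                    (100 - s$prevalence[s$category == "0"] -
                       s$prevalence[s$category == "1"])), 0.15)
  }
})

test_that("percent change matches the printed-table convention", {
  expect_equal(percent_change(100, 100), 0.0)
  expect_equal(percent_change(200, 300), 50.0)
  expect_equal(percent_change(300, 200), round_half_out(-100 / 3, 1))
  # antisymmetry identity: pc(a,b) = -pc(b,a) * b/a up to rounding
  set.seed(5)
  a <- sample(1000:100000, 20)
  b <- sample(1000:100000, 20)
  expect_true(all(abs(percent_change(a, b) +
                        percent_change(b, a) * b / a) < 0.06 * (1 + b / a)))
  expect_error(percent_change(0, 10), class = "morbsim_domain_error")
})

test_that("mental ill-health overlap matches explicit cross-tabulation", {
  pop <- random_states(2000, seed = 15)
  ov <- mental_illhealth_overlap(pop, diseases_and_impairments())
  mih <- pop$dementia | pop$depression | (pop$mmse <= 20 & !pop$dementia)
  counts <- count_conditions(pop, diseases_and_impairments())$raw_count
  for (k in c(1, 2, 3)) {
    sel <- counts == k
    expect_equal(ov$pct_mih[ov$category == as.character(k)],
                 round_half_out(100 * sum(mih[sel]) / sum(sel), 1))
  }
  sel <- counts >= 4
  expect_equal(ov$pct_mih[ov$category == "4+"],
               round_half_out(100 * sum(mih[sel]) / sum(sel), 1))
  # trivial poles
  clean <- pop
  clean$dementia <- FALSE; clean$depression <- FALSE; clean$mmse <- 28L
  ov0 <- mental_illhealth_overlap(clean, diseases_and_impairments())
  expect_true(all(ov0$pct_mih[!is.na(ov0$pct_mih)] == 0))
  dep <- pop
  dep$depression <- TRUE
  ovd <- mental_illhealth_overlap(dep, diseases_and_impairments())
  expect_equal(ovd$pct_mih[ovd$category == "4+"], 100.0)
})

test_that("empty strata warn and never divide by zero", {
  pop <- small_population(30, seed = 2)
  pop$age_months <- 70L * 12L   # nobody 85+
  w <- capture_warnings(
    tab <- prevalence_table(stats::setNames(list(pop), "2015"),
                            conditions = "stroke"))
  expect_match(w, "empty stratum", all = TRUE)
  expect_gt(length(w), 0)
  expect_true(is.na(tab$prevalence[tab$age_group == "85+"]))
})
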