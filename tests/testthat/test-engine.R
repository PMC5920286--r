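test_that("null dynamics: zero move-probabilities and no mortality only age people", {
  base <- small_population(300, seed = 12)
  out <- run_simulation(base, frozen_bundle(), no_mortality_schedule(),
                        run_config(horizon = 2016, seed = 1))
  first <- out$snapshots[["2014"]]
  last <- out$snapshots[["2016"]]
  expect_identical(nrow(last), nrow(base))
  expect_identical(last$age_months, base$age_months + 24L)
  for (cl in setdiff(names(base), "age_months"))
    expect_identical(last[[cl]], base[[cl]], label = cl)
  expect_identical(first$age_months, base$age_months)
  expect_identical(nrow(out$deaths), 0L)
})

test_that("mortality-only survivorship matches the analytic lifetable", {
  n <- 50000L
  base <- small_population(n, seed = 30)
  base$age_months <- 65L * 12L   # cohort aged exactly 65 at start
  sch <- gompertz_schedule(improvement = 0)  # period = cohort schedule
  out <- run_simulation(base, empty_bundle(), sch,
                        run_config(horizon = 2030, seed = 77))
  male <- base$sex == "male"
  for (sx in c("male", "female")) {
    lt <- build_lifetable(sch, 2014, sx, start_age = 65)
    sel_ids <- base$id[base$sex == sx]
    for (yr in c("2019", "2024", "2029")) {
      k <- as.integer(yr) - 2014L
      alive_frac <- mean(sel_ids %in% out$snapshots[[yr]]$id)
      expected <- lt$l[lt$age == 65 + k] / lt$l[1]
      se <- sqrt(expected * (1 - expected) / length(sel_ids))
      expect_lt(abs(alive_frac - expected), 3 * se)
    }
  }
})

test_that("a single absorbing disease follows the geometric prevalence curve", {
  n <- 20000L
  base <- small_population(n, seed = 31)
  base$arthritis <- FALSE
  p2 <- 0.3
  m <- interval_to_monthly(p2, 24L)
  out <- run_simulation(base, single_disease_bundle(p2),
                        no_mortality_schedule(),
                        run_config(horizon = 2017, seed = 5))
  for (yr in c("2015", "2016", "2017")) {
    t <- (as.integer(yr) - 2014L) * 12L
    expected <- 1 - (1 - m)^t
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(mean(out$snapshots[[yr]]$arthritis) - expected), 3 * se)
  }
})

test_that("simulation runs are deterministic and replicates reproducible in isolation", {
  base <- small_population(500, seed = 2)
  bundle <- default_truth_bundle()
  sch <- gompertz_schedule()
  cfg <- run_config(horizon = 2017, seed = 3, n_replicates = 2L)
  a <- run_simulation(base, bundle, sch, cfg)
  b <- run_simulation(base, bundle, sch, cfg)
  expect_identical(a$snapshots, b$snapshots)
  reps <- run_replicates(base, bundle, sch, cfg)
  solo <- run_simulation(base, bundle, sch, cfg, replicate = 2L)
  expect_identical(reps[[2]]$snapshots, solo$snapshots)
  expect_false(identical(reps[[1]]$snapshots[["2017"]],
                         reps[[2]]$snapshots[["2017"]]))
})

test_that("the population is closed and absorbing flags never revert", {
  base <- small_population(800, seed = 19)
  out <- run_simulation(base, default_truth_bundle(), gompertz_schedule(),
                        run_config(horizon = 2024, seed = 9))
  alive_counts <- vapply(out$snapshots, nrow, integer(1))
  expect_true(all(diff(alive_counts) <= 0))
  expect_true(all(unlist(lapply(out$snapshots, function(s) s$id %in% base$id))))
  # every id ends up alive or in the death log, never both, never created
  expect_identical(anyDuplicated(out$deaths$id), 0L)
  expect_true(all(out$deaths$id %in% base$id))
  last <- out$snapshots[[length(out$snapshots)]]
  died_by_snapshot <- out$deaths$id[out$deaths$year < 2024L |
    (out$deaths$year == 2024L & out$deaths$month <= 7L)]
  expect_setequal(last$id, setdiff(base$id, died_by_snapshot))
  yrs <- names(out$snapshots)
  for (i in seq_along(yrs)[-1]) {
    prev <- out$snapshots[[yrs[i - 1]]]
    cur <- out$snapshots[[yrs[i]]]
    common <- intersect(prev$id, cur$id)
    for (d in c("arthritis", "cancer", "chd", "diabetes", "hypertension",
                "respiratory", "stroke"))
      expect_false(any(prev[[d]][match(common, prev$id)] &
                         !cur[[d]][match(common, cur$id)]))
    expect_true(all(cur$age_months[match(common, cur$id)] >
                      prev$age_months[match(common, prev$id)]))
  }
})

test_that("a horizon equal to the start year yields one near-identity snapshot", {
  base <- small_population(300, seed = 40)
  out <- run_simulation(base, frozen_bundle(), no_mortality_schedule(),
                        run_config(horizon = 2014, seed = 1))
  expect_identical(names(out$snapshots), "2014")
  expect_identical(out$snapshots[["2014"]]$age_months, base$age_months)
})

test_that("stepping past the schedule's coverage raises schedule errors", {
  base <- small_population(50, seed = 3)
  sch <- gompertz_schedule(years = 2014:2015)
  expect_error(run_simulation(base, empty_bundle(), sch,
                              run_config(horizon = 2020, seed = 1)),
               class = "morbsim_input_error")
  base$age_months <- 120L * 12L
  expect_no_error(validate_population(base))
  expect_error(run_simulation(base, empty_bundle(), gompertz_schedule(),
                              run_config(horizon = 2015, seed = 1)),
               class = "morbsim_input_error")
  expect_error(run_simulation(base[0, ], empty_bundle(), gompertz_schedule(),
                              run_config(seed = 1)),
               class = "morbsim_input_error")
})
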