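test_that("base-population generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_individuals = 1000L)
  a <- generate_base_population(cfg, seed = 7)
  b <- generate_base_population(cfg, seed = 7)
  pa <- withr::local_tempfile(fileext = ".csv")
  pb <- withr::local_tempfile(fileext = ".csv")
  write_population(a, pa)
  write_population(b, pb)
  expect_identical(readLines(pa), readLines(pb))
  expect_false(identical(a, generate_base_population(cfg, seed = 8)))
  expect_identical(anyDuplicated(a$id), 0L)
})

test_that("zeroed prevalence curves produce a condition-free population", {
  cfg <- zero_prevalence(synthetic_config(n_individuals = 500L))
  pop <- generate_base_population(cfg, seed = 3)
  for (cond in setdiff(names(cfg$prevalence_curves), "dementia"))
    expect_identical(sum(pop[[cond]]), 0L)
  expect_identical(sum(pop$dementia), 0L)  # allocated outwith the generator
})

test_that("realised prevalence tracks the configured curves within binomial error", {
  cfg <- synthetic_config(n_individuals = 30000L)
  pop <- generate_base_population(cfg, seed = 17)
  age <- pop$age_months %/% 12L
  female <- as.numeric(pop$sex == "female")
  inact <- as.numeric(pop$inactive)
  obese <- as.numeric(pop$bmi_cat == 4L)
  smoker <- as.numeric(pop$smoking == "current")
  bands <- cbind(lo = c(35, 45, 55, 65, 75), hi = c(44, 54, 64, 74, 84))
  for (cond in c("arthritis", "hypertension", "diabetes", "stroke")) {
    cv <- cfg$prevalence_curves[[cond]]
    ef <- cfg$risk_effects[[cond]]
    # binomial-error oracle: expected prevalence from the configured
    # individual-level probabilities (Poisson-binomial mean and SE)
    p_i <- plogis(cv[1] + cv[2] * (age - 70) / 10 + cv[3] * female +
                    ef["inactive"] * inact + ef["obese"] * obese +
                    ef["smoker"] * smoker)
    for (r in seq_len(nrow(bands))) {
      sel <- age >= bands[r, "lo"] & age <= bands[r, "hi"]
      n <- sum(sel)
      expected <- mean(p_i[sel])
      se <- sqrt(sum(p_i[sel] * (1 - p_i[sel]))) / n
      expect_lt(abs(mean(pop[[cond]][sel]) - expected), 3 * se + 1e-12)
    }
  }
  # age-band / sex frequencies within 3 binomial SE of configured weights
  st <- cfg$age_sex_structure
  for (r in seq_len(nrow(st))) {
    sel <- age >= st$age_lo[r] & age <= st$age_hi[r] & pop$sex == st$sex[r]
    w <- st$weight[r]
    se <- sqrt(w * (1 - w) / nrow(pop))
    expect_lt(abs(mean(sel) - w), 3 * se)
  }
})

test_that("a zero-move truth leaves wave 2 identical apart from ageing", {
  base <- small_population(300, seed = 5)
  panel <- generate_panel(base, frozen_bundle(), seed = 2)
  w1 <- panel[panel$wave == 1, setdiff(names(panel), "wave")]
  w2 <- panel[panel$wave == 2, setdiff(names(panel), "wave")]
  rownames(w1) <- rownames(w2) <- NULL
  expect_identical(w2$age_months, w1$age_months + 24L)
  same <- setdiff(names(w1), "age_months")
  expect_identical(w2[same], w1[same])
})

test_that("panel onset over 24 months matches the geometric closed form", {
  base <- small_population(20000, seed = 6)
  base$arthritis <- FALSE
  p2 <- 0.2
  truth <- frozen_bundle()
  truth$arthritis <- single_disease_bundle(p2)$arthritis
  panel <- generate_panel(base, truth, seed = 9)
  w2 <- panel[panel$wave == 2, ]
  m <- interval_to_monthly(p2, 24L)
  expected <- 1 - (1 - m)^24   # = p2 by the round-trip identity
  se <- sqrt(expected * (1 - expected) / nrow(base))
  expect_lt(abs(mean(w2$arthritis) - expected), 3 * se)
  # absorbing conditions never revert between waves
  w1 <- panel[panel$wave == 1, ]
  expect_false(any(w1$arthritis & !w2$arthritis))
})

test_that("panel generation is reproducible and validates its inputs", {
  base <- small_population(200, seed = 1)
  truth <- default_truth_bundle()
  p1 <- generate_panel(base, truth, seed = 4)
  p2 <- generate_panel(base, truth, seed = 4)
  expect_identical(p1, p2)
  expect_identical(attr(p1, "mode"), "monthly")
  incomplete <- truth[names(truth) != "stroke"]
  class(incomplete) <- "transition_bundle"
  expect_error(generate_panel(base, incomplete, seed = 4),
               class = "morbsim_config_error")
})

test_that("panel mortality follows the supplied schedule", {
  base <- small_population(3000, seed = 44)
  base$age_months <- 80L * 12L   # high-mortality ages
  sch <- gompertz_schedule()
  panel <- generate_panel(base, frozen_bundle(), seed = 5, schedule = sch)
  expect_identical(anyDuplicated(panel$id[panel$wave == 1]), 0L)
  w2 <- panel[panel$wave == 2, ]
  q80 <- sch$q[sch$year == 2014 & sch$sex == "male" & sch$age == 80]
  expect_gt(sum(!w2$alive), 0)
  # two-year survival should be of order (1-q80)^2 (ages/sex/year mix shifts it)
  expect_gt(mean(w2$alive), 0.75)
  expect_lt(mean(w2$alive), (1 - q80 / 3)^2)
})
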