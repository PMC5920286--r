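toy_lifetable <- function(q = c(0.2, 0.5, 1), start_age = 65L) {
  sch <- data.frame(expand.grid(year = 2015, sex = "male",
                                age = 35:(start_age + length(q) - 1)),
                    q = 0)
  sch$q[sch$age >= start_age] <- q
  sch$q[nrow(sch)] <- 1
  build_lifetable(mortality_schedule(sch), 2015, "male", start_age = start_age)
}

toy_surface <- function(pi_rows, ages = 65:67) {
  m <- matrix(pi_rows, nrow = length(ages), ncol = 5, byrow = TRUE,
              dimnames = list(ages, c("0", "1", "2", "3", "4+")))
  structure(m, class = c("prevalence_surface", "matrix"))
}

test_that("Sullivan reduces to total life expectancy for degenerate surfaces", {
  lt <- toy_lifetable()
  all_free <- toy_surface(c(1, 0, 0, 0, 0))
  hx <- sullivan(lt, all_free)
  expect_equal(unname(hx$years["0"]), hx$total_le, tolerance = 1e-12)
  expect_equal(hx$total_le, lt$e[1], tolerance = 1e-12)
  all_mm <- toy_surface(c(0, 0, 1, 0, 0))
  hx2 <- sullivan(lt, all_mm)
  expect_equal(unname(hx2$years["2"]), lt$e[1], tolerance = 1e-12)
})

test_that("a three-age toy example matches hand-summed person-years", {
  lt <- toy_lifetable(q = c(0.2, 0.5, 1))
  # l = 1e5, 8e4, 4e4; L = 9e4, 6e4, 2e4
  pi <- rbind(c(0.5, 0.3, 0.2, 0.0, 0.0),
              c(0.2, 0.3, 0.3, 0.2, 0.0),
              c(0.1, 0.2, 0.3, 0.2, 0.2))
  surf <- toy_surface(t(pi))
  surf[] <- pi
  hx <- sullivan(lt, surf)
  hand <- colSums(pi * c(9e4, 6e4, 2e4)) / 1e5
  expect_equal(unname(hx$years), unname(hand), tolerance = 1e-12)
  expect_equal(sum(hx$years), lt$e[1], tolerance = 1e-12)
})

test_that("category-years always conserve total life expectancy", {
  set.seed(31)
  for (rep in 1:10) {
    q <- c(runif(30, 0, 0.4), 1)
    lt <- toy_lifetable(q = q)
    raw <- matrix(runif(31 * 5), 31, 5)
    pi <- raw / rowSums(raw)
    dimnames(pi) <- list(65:95, c("0", "1", "2", "3", "4+"))
    hx <- sullivan(lt, structure(pi, class = c("prevalence_surface", "matrix")))
    expect_equal(sum(hx$years), hx$total_le, tolerance = 1e-9)
    expect_true(all(hx$years >= 0))
  }
})

test_that("life-expectancy shares follow the printed convention", {
  expect_equal(share_of_le(9.9, 18.6), 53.2)
  expect_equal(share_of_le(12.2, 21.2), 57.5)
  expect_equal(share_of_le(0, 18.6), 0.0)
  expect_error(share_of_le(20, 18.6), class = "morbsim_input_error")
  expect_error(share_of_le(1, 0), class = "morbsim_input_error")
})

test_that("decomposition components are additive and cancel correctly", {
  lt_a <- toy_lifetable(q = c(0.2, 0.5, 1))
  lt_b <- toy_lifetable(q = c(0.1, 0.3, 1))
  surf_a <- toy_surface(c(0.4, 0.3, 0.2, 0.1, 0.0))
  surf_b <- toy_surface(c(0.2, 0.2, 0.3, 0.2, 0.1))
  # identical settings: no change, both components zero
  d0 <- decompose_change(lt_a, surf_a, lt_a, surf_a)
  expect_equal(d0$delta, 0)
  expect_equal(d0$mortality, 0)
  expect_equal(d0$prevalence, 0)
  # equal surfaces: prevalence component exactly zero
  dm <- decompose_change(lt_a, surf_a, lt_b, surf_a)
  expect_equal(dm$prevalence, 0)
  expect_equal(dm$mortality, dm$delta, tolerance = 1e-12)
  # equal lifetables: mortality component exactly zero
  dp <- decompose_change(lt_a, surf_a, lt_a, surf_b)
  expect_equal(dp$mortality, 0)
  # random settings: exact additivity and order symmetry
  set.seed(77)
  for (rep in 1:10) {
    qa <- c(runif(10, 0, 0.4), 1); qb <- c(runif(10, 0, 0.4), 1)
    la <- toy_lifetable(q = qa); lb <- toy_lifetable(q = qb)
    ra <- matrix(runif(55), 11, 5); ra <- ra / rowSums(ra)
    rb <- matrix(runif(55), 11, 5); rb <- rb / rowSums(rb)
    dimnames(ra) <- dimnames(rb) <- list(65:75, c("0", "1", "2", "3", "4+"))
    sa <- structure(ra, class = c("prevalence_surface", "matrix"))
    sb <- structure(rb, class = c("prevalence_surface", "matrix"))
    for (catg in c("2+", "4+", "0")) {
      d <- decompose_change(la, sa, lb, sb, catg)
      expect_equal(d$mortality + d$prevalence, d$delta, tolerance = 1e-12)
      rev <- decompose_change(lb, sb, la, sa, catg)
      expect_equal(rev$delta, -d$delta, tolerance = 1e-12)
      expect_equal(rev$mortality, -d$mortality, tolerance = 1e-12)
    }
  }
})

test_that("prevalence surfaces from snapshots are proper and band-smoothed", {
  pop <- random_states(5000, seed = 55)
  surf <- prevalence_surface(pop, diseases_only(), sex = "female")
  expect_equal(unname(rowSums(surf)), rep(1, nrow(surf)), tolerance = 1e-12)
  # within a 5-year band all single-year rows share the banded estimate
  expect_equal(surf["65", ], surf["69", ])
  raw <- prevalence_surface(pop, diseases_only(), sex = "female",
                            band_width = 1L)
  expect_equal(unname(rowSums(raw)), rep(1, nrow(raw)), tolerance = 1e-12)
  # mismatched ages are rejected
  lt <- build_lifetable(gompertz_schedule(years = 2015), 2015, "male")
  short <- surf[1:10, , drop = FALSE]
  class(short) <- c("prevalence_surface", "matrix")
  expect_error(sullivan(lt, short), class = "morbsim_input_error")
})
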