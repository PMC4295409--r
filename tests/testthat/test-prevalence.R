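rs_one <- function(d, g, y) rep(1, max(length(d), length(y)))

# rate matrix over the full diagnosis span needed for `years`
rate_matrix <- function(rate, years, cfg = default_config()) {
  ages <- cfg$age_min:cfg$age_max
  dx <- (min(years) - (cfg$age_max - cfg$age_min)):max(years)
  matrix(rate, length(ages), length(dx),
         dimnames = list(age = ages, year = dx))
}

test_that("expected survival follows the life-table diagonal", {
  lt <- flat_lifetable(0.1)
  expect_identical(expected_survival_factor(lt, 50, 1990, 0), 1)
  expect_equal(expected_survival_factor(lt, 50, 1990, 2), 0.81)
  expect_equal(expected_survival_factor(lt, 50, 1990, 0:3),
               c(1, 0.9, 0.81, 0.729))

  # agreement with a simulated cohort drawn from the same qx
  set.seed(91)
  n <- 5e4
  kb <- 1 + stats::rgeom(n, 0.1)
  emp <- mean(kb > 2)
  expect_lt(abs(emp - 0.81), 3 * sqrt(0.81 * 0.19 / n))
})

test_that("population projection advances cohorts with frozen survival", {
  pop <- as_population(expand.grid(age = 0:1, year = 1990:1991, count = 100))
  lt <- flat_lifetable(0.5, ages = 0:1, years = 1990:1991)
  proj <- project_population(pop, lt, 1992)
  expect_equal(unname(proj["0", "1992"]), 100)     # stable inflow
  expect_equal(unname(proj["1", "1992"]), 50)      # halved diagonal

  lt0 <- flat_lifetable(0, ages = 0:1, years = 1990:1991)
  proj0 <- project_population(pop, lt0, 1992:1995)
  expect_true(all(unclass(proj0)[, c("1993", "1995")] == 100))

  reg <- small_registry()
  proj10 <- project_population(reg$population, reg$lifetable, 2008:2017)
  expect_true(all(is.finite(unclass(proj10))))
  expect_true(all(unclass(proj10) > 0))
})

test_that("the immortal limit reduces to cumulative incidence exactly", {
  cfg <- default_config()
  years <- 1990:1995
  r <- 2e-3
  rates <- rate_matrix(r, years, cfg)
  pop <- flat_population(10000)
  lt0 <- flat_lifetable(0)
  surf <- compute_prevalence(rates, rs_one, lt0, pop, cfg, years)

  ages <- cfg$age_min:cfg$age_max
  expected_by_age <- (ages - cfg$age_min + 1) * r * 10000
  for (t in as.character(years))
    expect_equal(unname(apply(surf$count[, t, ], 1, sum)),
                 unname(expected_by_age), tolerance = 1e-12)

  # zero incidence annihilates the surface
  surf0 <- compute_prevalence(rate_matrix(0, years, cfg), rs_one, lt0, pop,
                              cfg, years)
  expect_true(all(surf0$count == 0))
})

test_that("prevalence totals are exact marginal sums and respond monotonically", {
  an <- default_analysis()
  surf <- an$surface
  tot <- prevalence_totals(surf)
  expect_equal(unname(tot), unname(apply(surf$count, 2, sum)))
  expect_equal(colSums(prevalence_by_age_group(surf)), tot,
               ignore_attr = TRUE)

  cfg <- default_config()
  years <- 1990:1992
  rates <- rate_matrix(1e-3, years, cfg)
  pop <- flat_population(10000)
  lt <- flat_lifetable(0.02)
  s1 <- compute_prevalence(rates, rs_one, lt, pop, cfg, years)
  s2 <- compute_prevalence(rates * 1.1, rs_one, lt, pop, cfg, years)
  nz <- s1$count > 0
  expect_true(all(s2$count[nz] > s1$count[nz]))
  expect_equal(sum(s2$count), 1.1 * sum(s1$count), tolerance = 1e-12)
})

test_that("missing backcast incidence years are fatal and named", {
  cfg <- default_config()
  ages <- cfg$age_min:cfg$age_max
  short <- matrix(1e-3, length(ages), 30,
                  dimnames = list(age = ages, year = 1972:2001))
  expect_error(
    compute_prevalence(short, rs_one, flat_lifetable(0),
                       flat_population(1000), cfg, 1990:1995),
    "earliest missing: 1924")
})

test_that("expected mortality follows the excess-death decrement", {
  cfg <- default_config()
  years <- 1991:1996
  rates <- rate_matrix(0, c(1990, years), cfg)
  rates["50", "1990"] <- 5e-3                       # single diagnosis cohort
  pop <- flat_population(10000)
  lt0 <- flat_lifetable(0)
  lam <- 0.3
  rs_exp <- function(d, g, y) exp(-lam * d)
  mort <- compute_expected_mortality(rates, rs_exp, lt0, pop, cfg, years)
  N <- 5e-3 * 10000
  k <- years - 1990
  expect_equal(mort$expected, N * (exp(-lam * (k - 1)) - exp(-lam * k)),
               tolerance = 1e-12)

  # universal cure -> no expected cancer deaths
  mort1 <- compute_expected_mortality(rates, rs_one, lt0, pop, cfg, years)
  expect_true(all(mort1$expected == 0))
})

test_that("direct counting applies the mid-year rule", {
  cfg <- default_config()
  pop <- flat_population(10000)
  cases <- rbind(
    make_cases(50, 1990, year_death = 2000, cause_death = "other"),
    make_cases(55, 1985),
    make_cases(80, 1990))                 # attains 90 by 2000 -> excluded
  res <- counting_prevalence(cases, pop, 2000, cfg)
  expect_equal(res$count, 1)              # only the 55-year-old survivor
  expect_equal(res$per_100k, 1e5 * 1 / (67 * 10000))

  # no deaths: everyone still in the age range counts
  res2 <- counting_prevalence(cases[2:3, ], pop, 1994, cfg)
  expect_equal(res2$count, 2)                    # the 80-year-old is now 84
  expect_error(counting_prevalence(cases, pop, 2010, cfg), "follow-up")
})

test_that("mortality validation summarises relative differences", {
  exp_s <- data.frame(year = 1990:1994, expected = c(100, 110, 121, 0, 90))
  obs_eq <- data.frame(year = 1990:1994, observed = c(100, 110, 121, 0, 90))
  v <- mortality_validation(exp_s, obs_eq)
  expect_true(all(v$rel_diff[v$observed > 0] == 0))

  obs <- data.frame(year = 1990:1994,
                    observed = c(100, 110, 121, 0, 90) / 1.1)
  obs$observed[4] <- 0
  v2 <- mortality_validation(exp_s, obs)
  expect_true(is.na(v2$rel_diff[v2$year == 1993]))
  expect_equal(attr(v2, "mard"), 0.1, tolerance = 1e-9)
})
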