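test_that("incidence tabulation counts cells and conserves totals", {
  cfg <- default_config()
  pop <- flat_population(10000)
  cases <- make_cases(c(50, 50), c(1990, 1990))
  tab <- tabulate_incidence(cases, pop, cfg)
  expect_equal(tab$dx_count["50", "1990"], 2)
  expect_equal(tab$person_years["50", "1990"], 10000)
  expect_equal(sum(tab$dx_count), nrow(cases))

  none <- tabulate_incidence(cases[0, ], pop, cfg)
  expect_true(all(none$dx_count == 0))
  expect_equal(none$person_years, tab$person_years)

  reg <- small_registry()
  el <- filter_eligible(reg$cases, cfg)
  tab2 <- tabulate_incidence(el, reg$population, cfg)
  expect_equal(sum(tab2$dx_count), nrow(el))

  # population that misses required cells is fatal
  pop_small <- flat_population(10000, ages = 18:60)
  expect_error(tabulate_incidence(cases, pop_small, cfg), "ages")
})

test_that("the candidate set is the nine degree-coded models", {
  specs <- apc_model_specs()
  expect_equal(names(specs),
               c("APC101", "APC102", "APC201", "APC202", "APC103",
                 "APC301", "APC203", "APC302", "APC303"))
  for (s in specs) {
    expect_equal(s$deg_period, 0L)
    expect_equal(s$label,
                 sprintf("APC%d%d%d", s$deg_age, s$deg_period, s$deg_cohort))
  }
})

test_that("a constant-rate law is recovered as a null model", {
  cfg <- default_config()
  rate <- 1e-3
  pop <- flat_population(50000)
  set.seed(11)
  grid <- expand.grid(age = 18:84, year = 1972:2007)
  counts <- stats::rpois(nrow(grid), rate * 50000)
  cases <- make_cases(rep(grid$age, counts), rep(grid$year, counts))
  tab <- tabulate_incidence(cases, pop, cfg)
  fit <- fit_apc(tab, apc_spec(1, 0, 1))
  cf <- coef(fit); se <- fit$se
  expect_lt(abs(cf[["intercept"]] - log(rate)), 3 * se[["intercept"]])
  expect_lt(abs(cf[["age1"]]), 3 * se[["age1"]])
  expect_lt(abs(cf[["cohort1"]]), 3 * se[["cohort1"]])
})

test_that("the Poisson fit matches an independent Newton-Raphson oracle", {
  cfg <- default_config()
  truth <- c(intercept = -7, age1 = 0.5, age2 = -0.15, cohort1 = 0.1)
  pop <- flat_population(2e5)
  grid <- expand.grid(age = 18:84, year = 1972:2007)
  xa <- (grid$age - 50) / 10
  xc <- (grid$year - grid$age - 1940) / 10
  eta <- truth[1] + truth[2] * xa + truth[3] * xa^2 + truth[4] * xc
  set.seed(21)
  counts <- stats::rpois(nrow(grid), exp(eta) * 2e5)
  cases <- make_cases(rep(grid$age, counts), rep(grid$year, counts))
  tab <- tabulate_incidence(cases, pop, cfg)
  fit <- fit_apc(tab, apc_spec(2, 0, 1))

  X <- cbind(1, xa, xa^2, xc)
  oracle <- nr_poisson(X, counts, rep(log(2e5), nrow(grid)))
  expect_equal(unname(coef(fit)), oracle$coef, tolerance = 1e-6)
  se <- sqrt(diag(oracle$vcov))
  expect_true(all(abs(oracle$coef - truth) < 3 * se))
})

test_that("model ranking prefers the generating law and respects nesting", {
  cfg <- default_config()
  # pronounced cubic structure in both age and cohort
  truth <- c(-7, 0.6, -0.2, 0.08, 0.15, 0.03, 0.015)
  pop <- flat_population(2e5)
  grid <- expand.grid(age = 18:84, year = 1972:2007)
  xa <- (grid$age - 50) / 10
  xc <- (grid$year - grid$age - 1940) / 10
  eta <- truth[1] + truth[2] * xa + truth[3] * xa^2 + truth[4] * xa^3 +
    truth[5] * xc + truth[6] * xc^2 + truth[7] * xc^3
  set.seed(31)
  counts <- stats::rpois(nrow(grid), exp(eta) * 2e5)
  cases <- make_cases(rep(grid$age, counts), rep(grid$year, counts))
  tab <- tabulate_incidence(cases, pop, cfg)
  fits <- lapply(apc_model_specs(), function(sp) fit_apc(tab, sp))
  sel <- model_selection_table(fits)
  expect_equal(sel$label[1], "APC303")
  dev <- sel$deviance[match(c("APC101", "APC303"), sel$label)]
  expect_lte(dev[2], dev[1])          # nesting monotonicity

  # single fit -> one-row table; mixed grids are fatal
  expect_equal(nrow(model_selection_table(fits["APC303"])), 1L)
  other <- tabulate_incidence(cases[1:100, ], pop, cfg)
  other_fit <- suppressWarnings(fit_apc(other, apc_spec(1, 0, 1)))
  expect_error(model_selection_table(list(fits$APC303, other_fit)),
               "same incidence table")
})

test_that("projection extends the fitted surface as the polynomial dictates", {
  an <- default_analysis()
  fit <- an$apc
  # over the fitting years, projection reproduces the fitted rates
  proj <- project_incidence(fit, fit$years)
  expect_equal(proj[, "1990"], predict(fit, fit$ages, 1990),
               ignore_attr = TRUE)

  # positive linear cohort trend -> rates strictly increasing in year
  cfg <- default_config()
  pop <- flat_population(1e5)
  grid <- expand.grid(age = 18:84, year = 1972:2007)
  set.seed(41)
  xc <- (grid$year - grid$age - 1940) / 10
  counts <- stats::rpois(nrow(grid), exp(-7 + 0.3 * xc) * 1e5)
  tab <- tabulate_incidence(make_cases(rep(grid$age, counts),
                                       rep(grid$year, counts)), pop, cfg)
  f1 <- fit_apc(tab, apc_spec(1, 0, 1))
  r <- project_incidence(f1, 1950:2030)["50", ]
  expect_true(all(diff(r) > 0))

  expect_error(predict(fit, 95, 2000), "outside the modelled range")
})

test_that("tenfold person-years shrink standard errors about sqrt(10)-fold", {
  cfg <- default_config()
  grid <- expand.grid(age = 18:84, year = 1972:2007)
  xa <- (grid$age - 50) / 10
  xc <- (grid$year - grid$age - 1940) / 10
  eta <- -7 + 0.5 * xa - 0.15 * xa^2 + 0.1 * xc
  set.seed(51)
  se_at <- function(py) {
    counts <- stats::rpois(nrow(grid), exp(eta) * py)
    tab <- tabulate_incidence(make_cases(rep(grid$age, counts),
                                         rep(grid$year, counts)),
                              flat_population(py), cfg)
    fit_apc(tab, apc_spec(2, 0, 1))$se
  }
  ratio <- se_at(3e4) / se_at(3e5)
  expect_true(all(abs(ratio - sqrt(10)) < 0.25 * sqrt(10)))
})
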