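test_that("degenerate generating laws behave as limits demand", {
  cfg <- default_config()

  # rate 0 -> no cases at all
  p0 <- sim_params(apc_true = c(intercept = -Inf, age1 = 0, age2 = 0,
                                age3 = 0, cohort1 = 0, cohort2 = 0,
                                cohort3 = 0), seed = 1L)
  reg0 <- simulate_registry(p0, cfg)
  expect_equal(nrow(reg0$cases), 0L)

  # universal cure and no background mortality -> nobody dies
  p1 <- sim_params(
    birth_scale = 34000 / 40,
    cure_true = list("18-49" = c(logit_c = 30, slope = 0),
                     "50-69" = c(logit_c = 30, slope = 0),
                     "70-84" = c(logit_c = 30, slope = 0)),
    background = c(a0 = 0, b = 0.095, improvement = 0), seed = 2L)
  reg1 <- simulate_registry(p1, cfg)
  expect_gt(nrow(reg1$cases), 100)
  expect_true(all(reg1$cases$vital_status == "alive"))

  # immortal-limit identity: oracle prevalence at T = cumulative cases
  # still inside the eligible age range
  for (T in c(1980, 2007)) {
    orc <- oracle_prevalence(reg1$cases, T, cfg)
    manual <- sum(reg1$cases$year_dx <= T &
                    reg1$cases$age_dx + (T - reg1$cases$year_dx) <= cfg$age_max)
    expect_equal(attr(orc, "total"), manual)
  }

  # degenerate population is fatal
  expect_error(simulate_registry(sim_params(birth_scale = 0, seed = 3L), cfg),
               "degenerate population")
})

test_that("the same seed reproduces the registry byte for byte", {
  cfg <- default_config()
  p <- sim_params(birth_scale = 34000 / 40, seed = 77L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_registry(simulate_registry(p, cfg), d1)
  write_registry(simulate_registry(p, cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("digest of", f))
  }
})

test_that("cell counts follow the generating Poisson law", {
  cfg <- default_config()
  p <- sim_params(birth_scale = 34000 / 3, seed = 99L)
  reg <- simulate_registry(p, cfg)
  expect_gt(nrow(reg$cases), 40000)

  pop <- prevmod:::build_true_population(
    p, cfg, (cfg$obs_year_min - (cfg$age_max - cfg$age_min)):cfg$obs_year_max)
  ages <- cfg$age_min:cfg$age_max
  years <- cfg$obs_year_min:cfg$obs_year_max
  py <- unclass(pop)[match(ages, as.integer(rownames(pop))),
                     match(years, as.integer(colnames(pop)))]
  mu <- outer(ages, years, function(a, y) prevmod:::true_rate(p, a, y)) * py
  win <- reg$cases[reg$cases$year_dx >= cfg$obs_year_min, ]
  obs <- table(factor(win$age_dx, levels = ages),
               factor(win$year_dx, levels = years))
  keep <- mu >= 5                       # chi-square validity
  x2 <- sum((as.numeric(obs)[keep] - mu[keep])^2 / mu[keep])
  pval <- stats::pchisq(x2, df = sum(keep), lower.tail = FALSE)
  expect_gt(pval, 0.001)
  expect_lt(pval, 0.999)
})

test_that("net survival of non-cured cases follows the Weibull law", {
  an <- default_analysis()
  tr <- an$reg$cases
  wb <- an$reg$params$weibull_true[["50-69"]]
  grp <- !tr$cured & !is.na(tr$t_weibull) &
    tr$age_dx >= 50 & tr$age_dx <= 69
  tw <- tr$t_weibull[grp]
  expect_gt(length(tw), 20000)
  tw <- tw[seq_len(20000)]
  ks <- suppressWarnings(
    stats::ks.test(tw, stats::pweibull, shape = wb[["gamma"]],
                   scale = 1 / wb[["lambda"]]))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("the counting oracle honours the mid-year rule", {
  cfg <- default_config()
  one <- make_cases(50, 1990, year_death = 1993, cause_death = "cancer")
  for (yr in 1990:1992)
    expect_equal(attr(oracle_prevalence(one, yr, cfg), "total"), 1)
  expect_equal(attr(oracle_prevalence(one, 1993, cfg), "total"), 0)

  # no cases -> all-zero table; strata sum to the direct total
  empty <- oracle_prevalence(one[0, ], 2000, cfg)
  expect_true(all(empty == 0))

  reg <- small_registry()
  orc <- oracle_prevalence(reg$cases, 2000, cfg)
  expect_equal(sum(orc), attr(orc, "total"))

  expect_error(oracle_prevalence(one, 2020, cfg), "horizon")
})
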