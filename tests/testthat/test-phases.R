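toy_surface <- function(N, A, cfg = default_config(), year = 2000L,
                        age = 50L) {
  ndur <- length(N)
  cnt <- array(N, c(1, 1, ndur),
               dimnames = list(age = age, year = year,
                               duration = 0:(ndur - 1)))
  exc <- array(A, dim(cnt), dimnames = dimnames(cnt))
  structure(list(count = cnt, excess_deaths = exc, ages = age,
                 years = year, config = cfg),
            class = "prevalence_surface")
}

test_that("phase decomposition traces the exclusion rules by hand", {
  cfg <- default_config()
  # 10 newly diagnosed, 2 of whom die of the cancer within the year
  surf <- toy_surface(N = c(10, rep(0, 10)), A = c(2, rep(0, 10)))
  ph <- decompose_phases(surf, NULL, cfg)
  m <- ph$counts[, "50-69", "2000"]
  expect_equal(unname(m[c("initial", "last_year")]), c(8, 2))
  expect_equal(unname(m[c("monitoring", "long_term")]), c(0, 0))

  # no cancer deaths -> pure duration bands
  surf2 <- toy_surface(N = c(5, rep(2, 9), 7, 3), A = rep(0, 12))
  ph2 <- decompose_phases(surf2, NULL, cfg)
  m2 <- ph2$counts[, "50-69", "2000"]
  expect_equal(unname(m2[c("initial", "monitoring", "long_term",
                           "last_year")]),
               c(5, 18, 10, 0))
})

test_that("phases partition prevalence exactly for every year and age group", {
  an <- default_analysis()
  cfg <- an$cfg
  years <- cfg$obs_year_min:cfg$proj_year_max
  ph <- decompose_phases(an$surface, an$mortality, cfg, years)
  byg <- prevalence_by_age_group(an$surface)
  phase_sum <- apply(ph$counts, c(2, 3), sum)
  expect_equal(phase_sum, byg[, colnames(phase_sum)], tolerance = 1e-9,
               ignore_attr = TRUE)

  # sub-phase application conserves every cell total
  ep <- list(p_monitoring = 0.021, p_long_term = 0.015)
  ph2 <- apply_subphase(ph, ep, 2008:2017)
  expect_equal(apply(ph2$counts, c(2, 3), sum), phase_sum)
  expect_true(all(ph2$counts["subphase_event", , as.character(2008:2017)] > 0))
})

test_that("raising the long-term cutoff moves mass but not totals", {
  an <- default_analysis()
  cfg10 <- an$cfg
  cfg15 <- analysis_config(long_term_cutoff_years = 15L)
  ph10 <- decompose_phases(an$surface, an$mortality, cfg10, 2007)
  ph15 <- decompose_phases(an$surface, an$mortality, cfg15, 2007)
  expect_equal(sum(ph10$counts), sum(ph15$counts), tolerance = 1e-9)
  expect_gt(sum(ph15$counts["monitoring", , ]),
            sum(ph10$counts["monitoring", , ]))
  expect_lt(sum(ph15$counts["long_term", , ]),
            sum(ph10$counts["long_term", , ]))
})

test_that("event proportions follow the 120-day and one-year survival rules", {
  cfg <- default_config()
  # 1000 monitoring members (diagnosed 2000), 21 qualifying events in 2006;
  # 200 long-term members (diagnosed 1990), 3 qualifying events
  cases <- rbind(make_cases(rep(50, 1000), rep(2000, 1000)),
                 make_cases(rep(50, 200), rep(1990, 200),
                            case_id = sprintf("L%04d", 1:200)))
  events <- data.frame(
    case_id = c(cases$case_id[1:21], sprintf("L%04d", 1:3)),
    event_year = 2006L,
    event_type = "metastasis",
    days_since_dx = 400L, stringsAsFactors = FALSE)
  ep <- estimate_event_proportions(cases, events, cfg)
  expect_equal(ep$p_monitoring, 0.021)
  expect_equal(ep$p_long_term, 0.015)

  # an event 100 days after diagnosis is excluded by the 120-day rule
  ev100 <- events[1, ]; ev100$days_since_dx <- 100L
  ep100 <- estimate_event_proportions(cases, ev100, cfg)
  expect_equal(ep100$p_monitoring, 0)

  # death within a year of the event moves the case to last-year-of-life
  cases2 <- cases
  cases2$vital_status[1] <- "dead"
  cases2$year_death[1] <- 2007L
  cases2$cause_death[1] <- "other"
  ep2 <- estimate_event_proportions(cases2, events, cfg)
  expect_equal(ep2$events_monitoring, 20L)

  # no events at all -> both proportions zero
  ep0 <- estimate_event_proportions(cases, events[0, ], cfg)
  expect_equal(ep0$p_monitoring, 0)
  expect_equal(ep0$p_long_term, 0)
})

test_that("sub-phase arithmetic matches the worked projection example", {
  cfg <- default_config()
  counts <- array(0, c(5, 3, 1),
                  dimnames = list(
                    phase = c("initial", "monitoring", "long_term",
                              "last_year", "subphase_event"),
                    age_group = c("18-49", "50-69", "70-84"),
                    year = 2017))
  counts["monitoring", "50-69", 1] <- 33096
  counts["long_term", "50-69", 1] <- 30077
  tab <- structure(list(counts = counts, years = 2017L, config = cfg),
                   class = "phase_table")
  out <- apply_subphase(tab, list(p_monitoring = 0.021, p_long_term = 0.015),
                        2017)
  expect_equal(unname(out$counts["subphase_event", "50-69", 1]), 695 + 451)
  expect_equal(unname(out$counts["monitoring", "50-69", 1]), 33096 - 695)
  expect_equal(sum(out$counts), sum(counts))

  # zero proportions leave the table unchanged
  same <- apply_subphase(tab, list(p_monitoring = 0, p_long_term = 0), 2017)
  expect_equal(same$counts, counts)
})

test_that("derived change statistics reproduce their closed forms", {
  tot <- c("2007" = 48754, "2017" = 68620)
  ss <- summary_statistics(tot, 2007, 2017)
  expect_equal(ss$percent_change, (68620 - 48754) / 48754 * 100)
  expect_equal(ss$annual_rate, ss$percent_change / 10)

  expect_equal(summary_statistics(c("2000" = 5, "2010" = 5),
                                  2000, 2010)$percent_change, 0)
  expect_message(
    ss0 <- summary_statistics(c("2000" = 0, "2010" = 5), 2000, 2010),
    "zero")
  expect_true(is.na(ss0$percent_change))
  expect_error(summary_statistics(tot, 2007, 2020), "both years")
})

test_that("model and counting phase decompositions agree on simulation", {
  an <- default_analysis()
  cfg <- an$cfg
  ph <- decompose_phases(an$surface, an$mortality, cfg, 2006)
  model <- apply(ph$counts[1:4, , 1], 1, sum)
  oracle <- rowSums(counting_phases(an$reg$cases, 2006, cfg))
  for (p in c("initial", "monitoring", "long_term", "last_year"))
    expect_lt(abs(model[[p]] / oracle[[p]] - 1), 0.05)
})
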