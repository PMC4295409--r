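#' Ground-truth parameters for the synthetic registry
#'
#' The generator emulates the statistical structure the analysis assumes:
#' Poisson diagnosis counts with a log-linear age-cohort rate (the same
#' centred covariates the incidence model uses, see [fit_apc()]), a mixture
#' cure net-survival law per survival age group with a linear-in-year logit
#' cure trend (frozen before the observation window, as the survival model
#' assumes of the past), Gompertz background mortality with a secular
#' improvement trend, a demographically self-consistent population built by
#' cohort-component bookkeeping from a growing birth series, and
#' exponential clocks for subsequent metastasis / second-primary
#' notifications among survivors.
#'
#' @param apc_true Named numeric vector of log-rate coefficients on the
#'   centred covariate scale `x_a = (age-50)/10`, `x_c = (cohort-1940)/10`:
#'   `intercept`, `age1..age3`, `cohort1..cohort3`.
#' @param cure_true Per age group, logit-scale cure-fraction intercept (at
#'   the 1990 reference year) and slope per calendar year of diagnosis.
#' @param weibull_true Per age group, Weibull scale `lambda` (1/years) and
#'   shape `gamma` for net survival of the non-cured.
#' @param background Gompertz baseline `a0` (hazard at age 0 in the 1990
#'   reference year), log-slope `b` per year of age, and proportional annual
#'   hazard improvement `improvement`.
#' @param event_rates Annual hazards of metastasis and second primary among
#'   survivors.
#' @param birth_scale,birth_growth Annual female birth-cohort size at 1950
#'   and its exponential growth rate, driving the synthetic population.
#' @param seed Integer seed (overrides the config seed when given).
#'
#' @return An object of class `prevmod_sim_params`.
#' @export
sim_params <- function(apc_true = c(intercept = -6.38,
                                    age1 = 0.90, age2 = -0.22, age3 = 0.015,
                                    cohort1 = 0.15, cohort2 = 0.015,
                                    cohort3 = 0.001),
                       cure_true = list(
                         "18-49" = c(logit_c = 0.40, slope = 0.030),
                         "50-69" = c(logit_c = 0.60, slope = 0.030),
                         "70-84" = c(logit_c = 0.20, slope = 0.025)),
                       weibull_true = list(
                         "18-49" = c(lambda = 0.20, gamma = 1.10),
                         "50-69" = c(lambda = 0.18, gamma = 1.00),
                         "70-84" = c(lambda = 0.25, gamma = 0.90)),
                       background = c(a0 = 4e-05, b = 0.095,
                                      improvement = 0.010),
                       event_rates = c(metastasis = 0.015,
                                       second_primary = 0.008),
                       birth_scale = 34000,
                       birth_growth = 0.012,
                       seed = NULL) {
  stopifnot(all(vapply(cure_true, function(p)
    is.finite(p[["logit_c"]]), logical(1))))
  for (g in names(weibull_true))
    if (any(weibull_true[[g]] <= 0))
      stop("Weibull scale and shape must be positive (group ", g, ")")
  if (any(event_rates < 0)) stop("event hazards must be nonnegative")
  p <- list(apc_true = apc_true, cure_true = cure_true,
            weibull_true = weibull_true, background = background,
            event_rates = event_rates, birth_scale = birth_scale,
            birth_growth = birth_growth, seed = seed)
  class(p) <- "prevmod_sim_params"
  p
}

# Covariate centring shared by the generator and the incidence model.
APC_AGE_CENTER <- 50
APC_COHORT_CENTER <- 1940
APC_SCALE <- 10

true_rate <- function(params, age, year) {
  b <- params$apc_true
  xa <- (age - APC_AGE_CENTER) / APC_SCALE
  xc <- (year - age - APC_COHORT_CENTER) / APC_SCALE
  eta <- b[["intercept"]] +
    b[["age1"]] * xa + b[["age2"]] * xa^2 + b[["age3"]] * xa^3 +
    b[["cohort1"]] * xc + b[["cohort2"]] * xc^2 + b[["cohort3"]] * xc^3
  exp(eta)
}

# Generator qx: Gompertz in age with a secular improvement trend, frozen
# outside the observation window (the structure the analysis assumes of
# years it cannot observe).
true_qx <- function(params, age, year, cfg) {
  y <- pmin(pmax(year, cfg$obs_year_min), cfg$obs_year_max)
  bg <- params$background
  mu <- bg[["a0"]] * exp(bg[["b"]] * age) *
    exp(-bg[["improvement"]] * (y - 1990))
  1 - exp(-pmin(mu, 20))
}

true_cure_fraction <- function(params, group, year, cfg) {
  y <- pmax(year, cfg$obs_year_min)
  ct <- params$cure_true[[group]]
  expit(ct[["logit_c"]] + ct[["slope"]] * (y - 1990))
}

#' True net survival of the generating law
#'
#' `RS(d) = c + (1 - c) * exp(-(lambda * d)^gamma)` with the cure fraction
#' frozen before the observation window.
#'
#' @param params A [sim_params()] object.
#' @param d Duration since diagnosis in years (vectorised).
#' @param group Survival age-group label.
#' @param year_dx Year of diagnosis.
#' @param config Analysis configuration.
#' @return Net survival probabilities.
#' @export
true_net_survival <- function(params, d, group, year_dx,
                              config = analysis_config()) {
  cf <- true_cure_fraction(params, group, year_dx, config)
  wb <- params$weibull_true[[group]]
  cf + (1 - cf) * exp(-(wb[["lambda"]] * d)^wb[["gamma"]])
}

# Cohort-component population: count(a, t) = births(t - a) * survival from
# birth along the cohort diagonal under the generator's qx. Ages above
# `age_top` are aggregated into an open class labelled age_top + 1.
build_true_population <- function(params, cfg, years, age_top = 84L,
                                  open_class = TRUE) {
  births <- function(y) params$birth_scale *
    exp(params$birth_growth * (y - 1950))
  ages_full <- 0:109
  yr_rng <- range(years)
  cohorts <- (yr_rng[1] - max(ages_full)):(yr_rng[2])
  # survival from age 0 to age a for each cohort (diagonal products)
  surv <- matrix(NA_real_, length(ages_full), length(cohorts),
                 dimnames = list(ages_full, cohorts))
  for (ci in seq_along(cohorts)) {
    qx <- true_qx(params, ages_full, cohorts[ci] + ages_full, cfg)
    surv[, ci] <- cumprod(c(1, (1 - qx)[-length(qx)]))
  }
  nyr <- length(years)
  m <- matrix(0, age_top + 2L, nyr,
              dimnames = list(age = c(0:age_top, age_top + 1L), year = years))
  for (ti in seq_len(nyr)) {
    t <- years[ti]
    co <- t - ages_full
    cnt <- births(co) * surv[cbind(seq_along(ages_full),
                                   match(co, cohorts))]
    m[seq_len(age_top + 1L), ti] <- cnt[1:(age_top + 1L)]
    m[age_top + 2L, ti] <- sum(cnt[(age_top + 2L):length(cnt)])
  }
  if (!open_class) m <- m[seq_len(age_top + 1L), , drop = FALSE]
  class(m) <- c("prevmod_population", class(m))
  m
}

#' Simulate a synthetic cancer registry
#'
#' Draws Poisson diagnosis counts per (age, year) cell from the true
#' incidence law and the true population, then assigns each case a net
#' (cancer) death year from the mixture cure law and a background death
#' year from the life table along the case's attained-age diagonal; the
#' observed death is the earlier of the two, censored at the end of the
#' observation window. Subsequent metastasis / second-primary notifications
#' are drawn from exponential clocks and recorded only while the case is
#' alive and within the window (metastases only from
#' `metastasis_lag_days` onward).
#'
#' Diagnoses occur from `obs_year_min - (age_max - age_min)` onward so that
#' complete prevalence inside the observation window has a well-defined
#' direct-counting oracle; [filter_eligible()] restricts to the window, as
#' a registry opened at `obs_year_min` would.
#'
#' All within-year timing follows the package's mid-year convention: net
#' and background death processes are discretised so that the probability
#' of being alive `d` completed years after diagnosis is exactly
#' `RS(d) * S_E(d)`.
#'
#' @param params A [sim_params()] object.
#' @param config A [analysis_config()].
#' @return A list of class `prevmod_registry` with elements `cases`
#'   (including truth columns `cured`, `t_weibull`, `cause_true`),
#'   `events`, `population` (observation-window mid-year counts, ages
#'   0-84 plus an 85+ open class), `lifetable` (ages 0-84, observation
#'   years), `params` and `config`.
#' @export
simulate_registry <- function(params = sim_params(),
                              config = analysis_config()) {
  cfg <- config
  seed <- params$seed %||% cfg$seed
  set.seed(seed)

  sim_year_min <- cfg$obs_year_min - (cfg$age_max - cfg$age_min)
  dx_years <- sim_year_min:cfg$obs_year_max
  ages <- cfg$age_min:cfg$age_max

  pop_full <- build_true_population(params, cfg, dx_years)
  pop_ages <- as.integer(rownames(pop_full))

  # expected cases per cell
  grid <- expand.grid(age = ages, year = dx_years)
  py <- pop_full[cbind(match(grid$age, pop_ages),
                       match(grid$year, dx_years))]
  if (all(py == 0)) stop("degenerate population: zero person-years everywhere")
  mu <- true_rate(params, grid$age, grid$year) * py
  n_cell <- stats::rpois(nrow(grid), mu)
  n_tot <- sum(n_cell)
  if (n_tot == 0L) {
    return(structure(list(cases = empty_cases(),
                          events = data.frame(case_id = character(),
                                              event_year = integer(),
                                              event_type = character(),
                                              days_since_dx = integer()),
                          population = window_population(pop_full, cfg),
                          lifetable = true_lifetable(params, cfg),
                          params = params, config = cfg),
                     class = "prevmod_registry"))
  }

  idx <- rep.int(seq_len(nrow(grid)), n_cell)
  age_dx <- grid$age[idx]
  year_dx <- grid$year[idx]
  L <- cfg$obs_year_max - year_dx          # censoring duration (years)

  # net (cancer) death year: P(K_c > d) = RS_true(d)
  group <- as.character(assign_age_group(age_dx, cfg))
  cured <- rep(FALSE, n_tot)
  t_weibull <- rep(NA_real_, n_tot)
  k_cancer <- rep(Inf, n_tot)
  for (g in age_group_labels(cfg)) {
    gi <- which(group == g)
    if (!length(gi)) next
    cf <- true_cure_fraction(params, g, year_dx[gi], cfg)
    is_cured <- stats::runif(length(gi)) < cf
    cured[gi] <- is_cured
    nn <- gi[!is_cured]
    if (length(nn)) {
      wb <- params$weibull_true[[g]]
      tw <- stats::rweibull(length(nn), shape = wb[["gamma"]],
                            scale = 1 / wb[["lambda"]])
      t_weibull[nn] <- tw
      k_cancer[nn] <- ceiling(tw)
    }
  }

  # background death year along the (age, year) diagonal, cell by cell
  k_background <- rep(Inf, n_tot)
  u_bg <- stats::runif(n_tot)
  cell_of <- idx
  for (ci in unique(cell_of)) {
    rows <- which(cell_of == ci)
    Lc <- cfg$obs_year_max - grid$year[ci]
    if (Lc < 1) next
    dd <- 0:(Lc - 1)
    p_surv <- 1 - true_qx(params, pmin(grid$age[ci] + dd, cfg$age_max),
                          grid$year[ci] + dd, cfg)
    cum <- cumprod(p_surv)
    # P(K_b >= d + 1) = cum[d]; K_b = #(cum >= u) + 1, Inf if survives all
    kb <- rowSums(outer(u_bg[rows], cum, "<=")) + 1
    kb[kb > Lc] <- Inf
    k_background[rows] <- kb
  }

  k_obs <- pmin(k_cancer, k_background)
  dead <- is.finite(k_obs) & k_obs <= L
  year_death <- ifelse(dead, year_dx + k_obs, NA_integer_)
  cause <- ifelse(dead,
                  ifelse(k_cancer <= k_background, "cancer", "other"),
                  NA_character_)

  cases <- data.frame(
    case_id = sprintf("C%07d", seq_len(n_tot)),
    age_dx = age_dx, year_dx = year_dx,
    vital_status = ifelse(dead, "dead", "alive"),
    year_death = as.integer(year_death),
    cause_death = cause,
    dco_flag = FALSE,
    cured = cured, t_weibull = t_weibull,
    cause_true = cause,
    stringsAsFactors = FALSE
  )

  events <- simulate_events(cases, k_obs, L, params, cfg)

  structure(list(cases = cases, events = events,
                 population = window_population(pop_full, cfg),
                 lifetable = true_lifetable(params, cfg),
                 params = params, config = cfg),
            class = "prevmod_registry")
}

# death occurs in duration interval (K-1, K]; events are recorded while
# the case is alive (event time < K - 0.5, i.e. before the death year's
# mid-year on average) and notified by the end of the window.
simulate_events <- function(cases, k_obs, L, params, cfg) {
  n <- nrow(cases)
  out <- list()
  lag_years <- cfg$metastasis_lag_days / 365.25
  rates <- params$event_rates
  for (type in c("metastasis", "second_primary")) {
    h <- rates[[type]]
    if (h <= 0) next
    tt <- stats::rexp(n, rate = h)
    cal <- cases$year_dx + 0.5 + tt
    ok <- tt < pmin(k_obs - 0.5, L + 0.5) & floor(cal) <= cfg$obs_year_max
    if (type == "metastasis") ok <- ok & tt >= lag_years
    if (!any(ok)) next
    out[[type]] <- data.frame(
      case_id = cases$case_id[ok],
      event_year = as.integer(floor(cal[ok])),
      event_type = type,
      days_since_dx = as.integer(round(tt[ok] * 365.25)),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out))
    return(data.frame(case_id = character(), event_year = integer(),
                      event_type = character(), days_since_dx = integer(),
                      stringsAsFactors = FALSE))
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  ev[order(ev$case_id, ev$event_year), ]
}

window_population <- function(pop_full, cfg) {
  keep <- as.integer(colnames(pop_full)) >= cfg$obs_year_min
  m <- pop_full[, keep, drop = FALSE]
  class(m) <- c("prevmod_population", "matrix", "array")
  m
}

true_lifetable <- function(params, cfg) {
  ages <- 0:cfg$age_max
  years <- cfg$obs_year_min:cfg$obs_year_max
  m <- outer(ages, years, function(a, y) true_qx(params, a, y, cfg))
  dimnames(m) <- list(age = ages, year = years)
  class(m) <- c("prevmod_lifetable", class(m))
  m
}

#' @export
print.prevmod_registry <- function(x, ...) {
  n_win <- sum(x$cases$year_dx >= x$config$obs_year_min)
  cat("synthetic cancer registry\n")
  cat(sprintf("  %d cases (%d within the %d-%d observation window)\n",
              nrow(x$cases), n_win, x$config$obs_year_min,
              x$config$obs_year_max))
  cat(sprintf("  %d subsequent-event notifications\n", nrow(x$events)))
  invisible(x)
}

#' Write a simulated registry to a directory
#'
#' Writes `cases.csv`, `events.csv`, `population.csv`, `lifetable.csv` and
#' `truth.json` (the generating parameters) into `dir`.
#'
#' @param registry A `prevmod_registry` from [simulate_registry()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cases(registry$cases, file.path(dir, "cases.csv"))
  write_events(registry$events, file.path(dir, "events.csv"))
  write_population(registry$population, file.path(dir, "population.csv"))
  write_lifetable(registry$lifetable, file.path(dir, "lifetable.csv"))
  truth <- registry$params
  class(truth) <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Direct-counting prevalence oracle
#'
#' Counts simulated cases truly alive at mid-year of `year` (follow-up
#' within the simulation is complete to the end of the observation window,
#' so observed death years are the truth for any `year` inside it), by
#' attained-age group and duration band. This is the ground truth against
#' which the modelled prevalence surface is tested.
#'
#' @param cases Case data frame with complete follow-up through `year`
#'   (e.g. the `cases` element of [simulate_registry()]).
#' @param year Index calendar year.
#' @param config A [analysis_config()].
#' @return A matrix of counts (age groups x duration bands `0`,
#'   `1-(cutoff-1)`, `cutoff+`), with the grand total as attribute
#'   `"total"`.
#' @export
oracle_prevalence <- function(cases, year, config = analysis_config()) {
  cfg <- config
  if (year > cfg$obs_year_max || year < cfg$obs_year_min)
    stop("oracle year ", year, " is outside the simulated horizon ",
         cfg$obs_year_min, "-", cfg$obs_year_max)
  alive <- is.na(cases$year_death) | cases$year_death > year
  d <- year - cases$year_dx
  attained <- cases$age_dx + d
  keep <- alive & d >= 0 & attained <= cfg$age_max & !isTRUE_vec(cases$dco_flag)
  grp <- assign_age_group(attained[keep], cfg)
  cut <- cfg$long_term_cutoff_years
  bands <- c("0", paste0("1-", cut - 1L), paste0(cut, "+"))
  band <- factor(bands[findInterval(d[keep], c(0, 1, cut))], levels = bands)
  m <- table(grp, band)
  out <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  names(dimnames(out)) <- c("age_group", "duration")
  attr(out, "total") <- sum(out)
  attr(out, "year") <- year
  out
}
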