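#' Expected (background) survival factor
#'
#' Cumulative probability of surviving background (all-cause) mortality
#' for `d` years from diagnosis, taken along the diagnosis-cohort diagonal
#' of the life table: `S_E = prod_{k=0}^{d-1} (1 - qx(age_dx + k,
#' year_dx + k))`. Requests beyond the life-table grid use frozen-edge
#' extension.
#'
#' @param lifetable A `prevmod_lifetable`.
#' @param age_dx,year_dx Age and calendar year at diagnosis (scalars).
#' @param d Duration(s) in completed years.
#' @return Probabilities in `[0, 1]`; `d = 0` gives exactly 1.
#' @export
expected_survival_factor <- function(lifetable, age_dx, year_dx, d) {
  dmax <- max(d)
  if (dmax == 0) return(rep(1, length(d)))
  k <- 0:(dmax - 1)
  cum <- c(1, cumprod(1 - qx_at(lifetable, age_dx + k, year_dx + k)))
  cum[d + 1]
}

#' Project a population forward (cohort component)
#'
#' Advances each cohort with survival frozen at the last observed year:
#' `count(a+1, t+1) = count(a, t) * (1 - qx(a, t_last))`; the youngest-age
#' inflow is held at its last observed value. If the top age row is an
#' open class it accumulates survivors of the closed ages.
#'
#' @param population A `prevmod_population` covering the last observed
#'   year.
#' @param lifetable A `prevmod_lifetable` covering the last observed year.
#' @param years Future years to append (must start after the last observed
#'   year).
#' @return A `prevmod_population` spanning the observed plus projected
#'   years.
#' @export
project_population <- function(population, lifetable, years) {
  ages <- as.integer(rownames(population))
  obs_years <- as.integer(colnames(population))
  t_last <- max(obs_years)
  years <- sort(as.integer(years))
  years <- years[years > t_last]
  if (!length(years)) return(population)
  if (any(diff(c(t_last, years)) != 1L))
    stop("projection years must continue contiguously from ", t_last)
  lt_max_age <- max(as.integer(rownames(lifetable)))
  open_top <- max(ages) > lt_max_age   # open class coded above the life table
  q_frozen <- qx_at(lifetable, pmin(ages, lt_max_age), rep(t_last, length(ages)))
  m <- unclass(population)
  for (t in years) {
    prev <- m[, ncol(m)]
    nxt <- numeric(length(ages))
    nxt[1] <- prev[1]                          # stable inflow
    surv <- prev * (1 - q_frozen)
    nxt[2:length(ages)] <- surv[1:(length(ages) - 1)]
    if (open_top)
      nxt[length(ages)] <- nxt[length(ages)] + surv[length(ages)]
    m <- cbind(m, nxt)
    colnames(m)[ncol(m)] <- t
  }
  names(dimnames(m)) <- c("age", "year")
  class(m) <- c("prevmod_population", "matrix", "array")
  m
}

# Reconstruct the population before the observed window by reverse
# survival along cohort diagonals (no migration, survival frozen at the
# earliest observed year -- the mirror of the forward projection).
# Cells whose diagonal exits the age grid before reaching the observed
# window are NA.
backcast_population <- function(population, lifetable, years) {
  ages <- as.integer(rownames(population))
  obs_years <- as.integer(colnames(population))
  t_min <- min(obs_years)
  years <- sort(as.integer(years))
  years <- years[years < t_min]
  if (!length(years)) return(population)
  amax <- max(ages)
  m_obs <- unclass(population)
  out <- matrix(NA_real_, length(ages), length(years),
                dimnames = list(age = ages, year = years))
  for (ti in seq_along(years)) {
    t <- years[ti]
    delta <- t_min - t
    a_then <- ages + delta
    ok <- a_then <= amax
    for (i in which(ok)) {
      kk <- 0:(delta - 1)
      s <- prod(1 - qx_at(lifetable, ages[i] + kk, t + kk))
      out[i, ti] <- m_obs[match(a_then[i], ages), 1] / s
    }
  }
  m <- cbind(out, m_obs)
  names(dimnames(m)) <- c("age", "year")
  class(m) <- c("prevmod_population", "matrix", "array")
  m
}

# --- the convolution engine shared by prevalence and mortality ---------

# Builds expected diagnosis counts, expected-survival diagonals and the
# net-survival array over the full diagnosis span implied by `years`,
# then forms
#   N(a, t, d) = I(a-d, t-d) PY(a-d, t-d) RS(d) S_E(d)   (prevalence)
#   A(a, t, d) = I PY S_E(d) [RS(d) - RS(d+1)]           (excess deaths,
#                occurring between mid-year t and mid-year t+1)
prevalence_engine <- function(rates, rs, lifetable, population, cfg, years) {
  years <- sort(as.integer(years))
  ages <- cfg$age_min:cfg$age_max
  span <- cfg$age_max - cfg$age_min
  dx_years <- (min(years) - span):max(years)

  if (inherits(rates, "apc_fit")) {
    rate_m <- project_incidence(rates, dx_years)
  } else {
    have <- as.integer(colnames(rates))
    missing_years <- setdiff(dx_years, have)
    if (length(missing_years))
      stop("incidence surface is missing diagnosis years back to ",
           min(dx_years), " (earliest missing: ", min(missing_years), ")")
    rate_m <- rates[, as.character(dx_years), drop = FALSE]
  }
  if (is.function(rs)) rs_fun <- rs else rs_fun <- survival_surface(rs)

  pop <- population
  obs_pop_years <- as.integer(colnames(pop))
  if (max(years) > max(obs_pop_years))
    pop <- project_population(pop, lifetable, (max(obs_pop_years) + 1):max(years))
  if (min(dx_years) < min(obs_pop_years))
    pop <- backcast_population(pop, lifetable,
                               min(dx_years):(min(obs_pop_years) - 1))
  pop_ages <- as.integer(rownames(pop))
  py <- unclass(pop)[match(ages, pop_ages),
                     match(dx_years, as.integer(colnames(pop))),
                     drop = FALSE]

  idx_mat <- rate_m * py              # expected diagnoses per (age, year)

  # expected-survival diagonals: Q[cohort, age] = survival from age_min
  cohorts <- (min(dx_years) - cfg$age_max):(max(dx_years) - cfg$age_min)
  Q <- matrix(1, length(cohorts), length(ages),
              dimnames = list(cohort = cohorts, age = ages))
  for (ci in seq_along(cohorts)) {
    q <- qx_at(lifetable, ages[-length(ages)],
               cohorts[ci] + ages[-length(ages)])
    Q[ci, ] <- c(1, cumprod(1 - q))
  }

  # net survival RS[group, dx_year, d + 1] for d = 0..span + 1
  glabs <- age_group_labels(cfg)
  dmax <- span + 1L
  RSarr <- array(NA_real_, c(length(glabs), length(dx_years), dmax + 1L),
                 dimnames = list(glabs, dx_years, 0:dmax))
  for (gi in seq_along(glabs)) {
    grid <- expand.grid(d = 0:dmax, y = dx_years)
    v <- rs_fun(grid$d, glabs[gi], grid$y)
    RSarr[gi, , ] <- matrix(v, length(dx_years), dmax + 1L, byrow = TRUE)
  }
  gidx <- as.integer(assign_age_group(ages, cfg))   # group of each dx age

  nA <- length(ages); nT <- length(years)
  P <- array(0, c(nA, nT, span + 1L),
             dimnames = list(age = ages, year = years, duration = 0:span))
  A <- array(0, c(nA, nT, span + 1L), dimnames = dimnames(P))
  yr0 <- min(dx_years)
  for (d in 0:span) {
    a_sel <- ages[ages - d >= cfg$age_min]           # attained ages valid at d
    ai <- match(a_sel, ages)
    a0 <- a_sel - d
    a0i <- match(a0, ages)
    for (ti in seq_len(nT)) {
      y0 <- years[ti] - d
      y0i <- y0 - yr0 + 1L
      base <- idx_mat[a0i, y0i]
      if (anyNA(base))
        stop("population backcast undefined for diagnosis year ", y0,
             "; cannot form prevalence for year ", years[ti])
      co_i <- (y0 - a0) - cohorts[1] + 1L
      se_d <- Q[cbind(co_i, ai)] / Q[cbind(co_i, a0i)]
      rs_d <- RSarr[cbind(gidx[a0i], y0i, d + 1L)]
      rs_d1 <- RSarr[cbind(gidx[a0i], y0i, d + 2L)]
      P[ai, ti, d + 1L] <- base * se_d * rs_d
      A[ai, ti, d + 1L] <- base * se_d * (rs_d - rs_d1)
    }
  }
  pop_1884 <- colSums(unclass(pop)[match(ages, pop_ages),
                                   match(years, as.integer(colnames(pop))),
                                   drop = FALSE])
  list(P = P, A = A, ages = ages, years = years,
       population_18_84 = pop_1884, cfg = cfg)
}

#' Compute the complete prevalence surface
#'
#' Convolves modelled incidence with modelled net survival and expected
#' survival through the discrete transition identity
#' `N(a, t, d) = I(a-d, t-d) PY(a-d, t-d) RS(d; g(a-d), t-d)
#'  S_E(a-d, t-d, d)`:
#' the expected number of people attaining age `a` in calendar year `t`
#' who were diagnosed `d` completed years earlier and are still alive at
#' mid-year. Incidence is evaluated back to
#' `min(years) - (age_max - age_min)` so every prevalent case could have
#' been diagnosed at an eligible age; person-years before the observed
#' population window come from a reverse-survival backcast and those after
#' it from the cohort-component projection.
#'
#' @param rates An `apc_fit`, or a rate matrix (ages x diagnosis years
#'   covering the needed span).
#' @param rs A `cure_fit` or a function `(d, age_group, year_dx)`.
#' @param lifetable A `prevmod_lifetable`.
#' @param population A `prevmod_population` (observed window; projected /
#'   backcast as needed).
#' @param config A [analysis_config()].
#' @param years Calendar years for which prevalence is computed.
#' @return A `prevalence_surface`: 3-d array of expected counts
#'   (attained age x year x duration) with year totals, age-group
#'   marginals, the 18-84 population denominator and the excess-death
#'   decomposition attached. Years within `age_max - age_min` years of the
#'   start of the incidence backcast window are listed in the
#'   `backcast_sensitive` element.
#' @export
compute_prevalence <- function(rates, rs, lifetable, population,
                               config = analysis_config(),
                               years = config$obs_year_min:config$proj_year_max) {
  eng <- prevalence_engine(rates, rs, lifetable, population, config, years)
  structure(list(count = eng$P, excess_deaths = eng$A,
                 ages = eng$ages, years = eng$years,
                 population_18_84 = eng$population_18_84,
                 backcast_sensitive =
                   eng$years[eng$years < config$obs_year_min + 18L],
                 config = config),
            class = "prevalence_surface")
}

#' @export
print.prevalence_surface <- function(x, ...) {
  tot <- prevalence_totals(x)
  cat(sprintf("complete prevalence surface, years %d-%d, ages %d-%d\n",
              min(x$years), max(x$years), min(x$ages), max(x$ages)))
  show <- round(tot[as.character(intersect(
    c(min(x$years), pretty(x$years)), x$years))])
  print(show[!is.na(show)])
  invisible(x)
}

#' @export
summary.prevalence_surface <- function(object, ...) {
  tot <- prevalence_totals(object)
  data.frame(year = object$years, prevalence = as.numeric(tot),
             population_18_84 = as.numeric(object$population_18_84),
             per_100k = 1e5 * as.numeric(tot) /
               as.numeric(object$population_18_84))
}

#' @export
as.data.frame.prevalence_surface <- function(x, ...) {
  df <- as.data.frame.table(x$count, stringsAsFactors = FALSE,
                            responseName = "count")
  names(df)[1:3] <- c("age", "year", "duration")
  df$age <- as.integer(df$age); df$year <- as.integer(df$year)
  df$duration <- as.integer(df$duration)
  df[df$count > 0 | df$duration <= df$age - min(x$ages), ]
}

#' Prevalence marginal totals
#'
#' @param surface A `prevalence_surface`.
#' @return `prevalence_totals()`: named vector of expected prevalent
#'   counts per year; `prevalence_by_age_group()`: matrix (attained-age
#'   group x year).
#' @export
prevalence_totals <- function(surface) {
  apply(surface$count, 2, sum)
}

#' @rdname prevalence_totals
#' @export
prevalence_by_age_group <- function(surface) {
  grp <- assign_age_group(surface$ages, surface$config)
  by_age <- apply(surface$count, c(1, 2), sum)
  rowsum(by_age, grp)
}

#' Expected cancer mortality from the fitted system
#'
#' Accumulates the excess-death decrement of every diagnosis cohort:
#' deaths registered in calendar year `t` are
#' `D(t) = sum_{a0, k>=1} I(a0, t-k) PY S_E(a0, t-k, k-1)
#'  [RS(k-1) - RS(k)]`
#' restricted to cohorts still inside the eligible age range at their last
#' prevalent mid-year (`a0 + k - 1 <= age_max`). Under the mid-year
#' convention these are the people prevalent at mid-year `t-1` who die of
#' the cancer before mid-year `t`. Comparing this series with observed
#' cancer deaths validates the incidence and survival models jointly.
#'
#' @inheritParams compute_prevalence
#' @param years Calendar years of death.
#' @return A `mortality_series` data frame (`year`, `expected`).
#' @export
compute_expected_mortality <- function(rates, rs, lifetable, population,
                                       config = analysis_config(),
                                       years = config$obs_year_min:config$proj_year_max) {
  years <- sort(as.integer(years))
  eng <- prevalence_engine(rates, rs, lifetable, population, config,
                           years - 1L)
  d <- data.frame(year = years, expected = as.numeric(apply(eng$A, 2, sum)))
  class(d) <- c("mortality_series", "data.frame")
  d
}

#' Count observed cancer deaths by calendar year
#'
#' Deaths from the cancer among people who were inside the eligible age
#' range at the mid-year preceding death (the same accounting as
#' [compute_expected_mortality()]).
#'
#' @param cases Case data frame with complete follow-up over `years`.
#' @param years Calendar years.
#' @param config A [analysis_config()].
#' @return Data frame (`year`, `observed`).
#' @export
observed_cancer_deaths <- function(cases, years,
                                   config = analysis_config()) {
  dead <- !is.na(cases$year_death) & cases$cause_death == "cancer"
  attained_prev <- cases$age_dx + (cases$year_death - 1L - cases$year_dx)
  ok <- dead & attained_prev <= config$age_max &
    cases$year_death > cases$year_dx
  counts <- table(factor(cases$year_death[ok], levels = years))
  data.frame(year = as.integer(years), observed = as.integer(counts))
}

#' Direct-counting prevalence
#'
#' Counts registered cases diagnosed since the start of the observation
#' window who are alive at mid-year of `year` (death year beyond `year`)
#' and still within the eligible age range, and expresses them per
#' 100,000 of the mid-year population aged `age_min`-`age_max`.
#'
#' @param cases Eligible case data frame with follow-up complete through
#'   `year`.
#' @param population A `prevmod_population` covering `year`.
#' @param year Index year (must not exceed the observation window).
#' @param config A [analysis_config()].
#' @return A list with `count`, `per_100k` and `year`.
#' @export
counting_prevalence <- function(cases, population, year,
                                config = analysis_config()) {
  cfg <- config
  if (year > cfg$obs_year_max)
    stop("follow-up is complete only to ", cfg$obs_year_max,
         "; cannot count prevalence for ", year)
  alive <- is.na(cases$year_death) | cases$year_death > year
  d <- year - cases$year_dx
  attained <- cases$age_dx + d
  n <- sum(alive & d >= 0 & cases$year_dx >= cfg$obs_year_min &
             attained <= cfg$age_max)
  pop_ages <- as.integer(rownames(population))
  denom <- sum(unclass(population)[
    pop_ages >= cfg$age_min & pop_ages <= cfg$age_max,
    as.character(year)])
  list(count = n, per_100k = 1e5 * n / denom, year = year)
}

#' Validate expected against observed cancer mortality
#'
#' @param expected A `mortality_series` (or data frame with `year`,
#'   `expected`).
#' @param observed Data frame with `year` and `observed` (integer death
#'   counts), e.g. from [observed_cancer_deaths()].
#' @return A `mortality_validation` data frame with per-year relative
#'   differences `(expected - observed) / observed` over the overlapping
#'   years; years with zero observed deaths are reported as `NA` and
#'   excluded from the mean absolute relative difference (attribute
#'   `"mard"`).
#' @export
mortality_validation <- function(expected, observed) {
  m <- merge(as.data.frame(expected), as.data.frame(observed), by = "year")
  if (!nrow(m)) stop("expected and observed series do not overlap")
  m$rel_diff <- ifelse(m$observed == 0, NA_real_,
                       (m$expected - m$observed) / m$observed)
  out <- m[, c("year", "expected", "observed", "rel_diff")]
  attr(out, "mard") <- mean(abs(out$rel_diff), na.rm = TRUE)
  class(out) <- c("mortality_validation", "data.frame")
  out
}

#' @export
print.mortality_validation <- function(x, ...) {
  cat(sprintf(
    "mortality validation over %d years: mean |rel diff| = %.3f\n",
    nrow(x), attr(x, "mard")))
  print.data.frame(utils::head(x, 8), digits = 4)
  if (nrow(x) > 8) cat("  ...", nrow(x) - 8, "more rows\n")
  invisible(x)
}
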