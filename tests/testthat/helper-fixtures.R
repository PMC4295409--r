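# Shared fixtures. Expensive objects are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default study conditions
default_config <- function() analysis_config()

# a reduced registry (~4.5k window cases) for cheap structural tests
small_registry <- function() cached("small_registry", {
  simulate_registry(sim_params(birth_scale = 34000 / 20, seed = 424242L),
                    default_config())
})

# the default-scale registry plus the fitted analysis chain, shared by the
# acceptance tests and the heavier property tests
default_analysis <- function() cached("default_analysis", {
  cfg <- default_config()
  reg <- simulate_registry(sim_params(), cfg)
  eligible <- filter_eligible(reg$cases, cfg)
  inc <- tabulate_incidence(eligible, reg$population, cfg)
  apc <- fit_apc(inc, apc_spec(3, 0, 3))
  rstab <- tabulate_pohar_perme(eligible, reg$lifetable, cfg)
  cure <- fit_mixture_cure(rstab, cfg)
  years <- cfg$obs_year_min:cfg$proj_year_max
  surface <- compute_prevalence(apc, cure, reg$lifetable, reg$population,
                                cfg, years)
  mortality <- compute_expected_mortality(apc, cure, reg$lifetable,
                                          reg$population, cfg,
                                          c(years, max(years) + 1L))
  list(cfg = cfg, reg = reg, eligible = eligible, inc = inc, apc = apc,
       rstab = rstab, cure = cure, surface = surface,
       mortality = mortality)
})

# hand-built case records (alive unless a death year is given)
make_cases <- function(age_dx, year_dx, year_death = NA_integer_,
                       cause_death = NA_character_, dco_flag = FALSE,
                       case_id = NULL) {
  n <- max(length(age_dx), length(year_dx), length(year_death))
  year_death <- rep_len(as.integer(year_death), n)
  data.frame(
    case_id = case_id %||% sprintf("T%04d", seq_len(n)),
    age_dx = rep_len(as.integer(age_dx), n),
    year_dx = rep_len(as.integer(year_dx), n),
    vital_status = ifelse(is.na(year_death), "alive", "dead"),
    year_death = year_death,
    cause_death = ifelse(is.na(year_death), NA_character_,
                         rep_len(cause_death, n)),
    dco_flag = rep_len(dco_flag, n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# constant life table (qx identical everywhere) over given grid
flat_lifetable <- function(qx, ages = 0:84, years = 1972:2007) {
  as_lifetable(expand.grid(age = ages, year = years, qx = qx))
}

# flat population
flat_population <- function(count, ages = 18:84, years = 1972:2007) {
  as_population(expand.grid(age = ages, year = years, count = count))
}

# single-stratum configuration: one age group, one diagnosis period
single_stratum_config <- function(min_at_risk = 1L)
  analysis_config(age_groups = list(c(18L, 84L)),
                  periods = list(c(1972L, 2007L)),
                  min_at_risk = min_at_risk)

# classic actuarial observed-survival estimator (independent oracle for the
# Pohar Perme identity when expected mortality is zero), using the same
# interval and cohort-approach conventions as the package
actuarial_oracle <- function(K, L, J) {
  rs <- numeric(J)
  cum <- 1
  for (j in seq_len(J)) {
    elig <- L >= j
    n <- sum(elig & K >= j)
    d <- sum(elig & K == j)
    if (n == 0) return(rs[seq_len(j - 1)])
    cum <- cum * (1 - d / n)
    rs[j] <- cum
  }
  rs
}

# independently coded Newton-Raphson Poisson regression with offset
nr_poisson <- function(X, y, offset, tol = 1e-10, maxit = 50) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(sum(y) / sum(exp(offset)))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta + offset)
    mu <- exp(eta)
    score <- crossprod(X, y - mu)
    info <- crossprod(X * mu, X)
    step <- solve(info, score)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  list(coef = beta, vcov = solve(info))
}
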