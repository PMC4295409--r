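#' Tabulate incidence counts and person-years
#'
#' Cross-tabulates eligible cases by single year of age at diagnosis and
#' calendar year, attaching mid-year population counts as person-years.
#'
#' @param cases Eligible case data frame (see [filter_eligible()]).
#' @param population A `prevmod_population`.
#' @param config A [analysis_config()].
#' @return A `prevmod_incidence` list with matrices `dx_count` and
#'   `person_years` (ages x years over the observation window).
#' @export
tabulate_incidence <- function(cases, population,
                               config = analysis_config()) {
  cfg <- config
  ages <- cfg$age_min:cfg$age_max
  years <- cfg$obs_year_min:cfg$obs_year_max
  pop_ages <- as.integer(rownames(population))
  pop_years <- as.integer(colnames(population))
  if (!all(ages %in% pop_ages) || !all(years %in% pop_years)) {
    miss_a <- setdiff(ages, pop_ages); miss_y <- setdiff(years, pop_years)
    stop("population table does not cover required cells: ",
         if (length(miss_a)) paste("ages", paste(miss_a, collapse = ",")),
         if (length(miss_y)) paste(" years", paste(miss_y, collapse = ",")))
  }
  counts <- matrix(0, length(ages), length(years),
                   dimnames = list(age = ages, year = years))
  if (nrow(cases)) {
    bad <- cases$age_dx < cfg$age_min | cases$age_dx > cfg$age_max |
      cases$year_dx < cfg$obs_year_min | cases$year_dx > cfg$obs_year_max
    if (any(bad))
      stop(sum(bad), " case(s) fall outside the tabulation grid; ",
           "apply filter_eligible() first")
    tb <- table(factor(cases$age_dx, levels = ages),
                factor(cases$year_dx, levels = years))
    counts[] <- as.numeric(tb)
  }
  py <- unclass(population)[match(ages, pop_ages),
                            match(years, pop_years), drop = FALSE]
  dimnames(py) <- dimnames(counts)
  structure(list(dx_count = counts, person_years = py,
                 ages = ages, years = years),
            class = "prevmod_incidence")
}

#' @export
print.prevmod_incidence <- function(x, ...) {
  cat(sprintf("incidence table: %d diagnoses, ages %d-%d, years %d-%d\n",
              sum(x$dx_count), min(x$ages), max(x$ages),
              min(x$years), max(x$years)))
  invisible(x)
}

#' Age-period-cohort model specifications
#'
#' An `APCdac` label encodes the polynomial degrees of the age, period and
#' cohort terms of the log-linear rate model. `apc_model_specs()` returns
#' the nine candidate specifications with period degree 0 (drift absorbed
#' into the cohort polynomial): APC101, 102, 201, 202, 103, 301, 203, 302
#' and 303.
#'
#' @param deg_age,deg_period,deg_cohort Polynomial degrees.
#' @return `apc_spec()`: a single spec; `apc_model_specs()`: the candidate
#'   list.
#' @export
apc_spec <- function(deg_age, deg_period, deg_cohort) {
  stopifnot(deg_age >= 0, deg_period >= 0, deg_cohort >= 0)
  structure(list(deg_age = as.integer(deg_age),
                 deg_period = as.integer(deg_period),
                 deg_cohort = as.integer(deg_cohort),
                 label = sprintf("APC%d%d%d", deg_age, deg_period,
                                 deg_cohort)),
            class = "apc_spec")
}

#' @rdname apc_spec
#' @export
apc_model_specs <- function() {
  degs <- list(c(1, 0, 1), c(1, 0, 2), c(2, 0, 1), c(2, 0, 2), c(1, 0, 3),
               c(3, 0, 1), c(2, 0, 3), c(3, 0, 2), c(3, 0, 3))
  out <- lapply(degs, function(d) apc_spec(d[1], d[2], d[3]))
  names(out) <- vapply(out, `[[`, character(1), "label")
  out
}

apc_design <- function(age, year, spec, transform) {
  xa <- (age - transform$age_center) / transform$scale
  xp <- (year - transform$period_center) / transform$scale
  xc <- (year - age - transform$cohort_center) / transform$scale
  cols <- list()
  if (spec$deg_age > 0)
    for (i in seq_len(spec$deg_age)) cols[[paste0("age", i)]] <- xa^i
  if (spec$deg_period > 0)
    for (i in seq_len(spec$deg_period)) cols[[paste0("period", i)]] <- xp^i
  if (spec$deg_cohort > 0)
    for (i in seq_len(spec$deg_cohort)) cols[[paste0("cohort", i)]] <- xc^i
  do.call(cbind, c(list(intercept = rep(1, length(age))), cols))
}

#' Fit an age-period-cohort Poisson model
#'
#' Maximises the Poisson likelihood of the cell counts with a log
#' person-years offset and log rate
#' `alpha0 + sum_i alpha_i a'^i + sum_j pi_j p'^j + sum_k gamma_k c'^k`,
#' where `a' = (age - 50)/10`, `p' = (year - period_center)/10` and
#' `c' = (cohort - 1940)/10` are centred and scaled covariates (cubic terms
#' in raw years are numerically ill-conditioned; the transform is stored in
#' the fit). The deviance reported is the likelihood-ratio statistic
#' against the saturated model.
#'
#' @param table A `prevmod_incidence` from [tabulate_incidence()].
#' @param spec An [apc_spec()].
#' @param transform Optional covariate transform override (list with
#'   `age_center`, `period_center`, `cohort_center`, `scale`).
#' @return An object of class `apc_fit` with coefficients, standard
#'   errors, deviance, residual df and the stored transform.
#' @export
fit_apc <- function(table, spec, transform = NULL) {
  stopifnot(inherits(table, "prevmod_incidence"), inherits(spec, "apc_spec"))
  grid <- expand.grid(age = table$ages, year = table$years)
  y <- as.vector(table$dx_count)
  py <- as.vector(table$person_years)
  keep <- py > 0
  if (!any(keep)) stop("incidence table has no cells with person-years")
  if (any(!keep & y > 0))
    stop("cells with diagnoses but zero person-years present")
  if (any(!keep))
    warning(sum(!keep), " cell(s) with zero person-years dropped")
  transform <- transform %||% list(
    age_center = APC_AGE_CENTER,
    period_center = round(mean(table$years)),
    cohort_center = round(mean(table$years)) - APC_AGE_CENTER,
    scale = APC_SCALE)
  X <- apc_design(grid$age[keep], grid$year[keep], spec, transform)
  dat <- data.frame(.y = y[keep], .off = log(py[keep]))
  dat <- cbind(dat, as.data.frame(X[, -1, drop = FALSE]))
  fml <- stats::as.formula(paste(
    ".y ~", if (ncol(X) > 1)
      paste(colnames(X)[-1], collapse = " + ") else "1",
    "+ offset(.off)"))
  fit <- stats::glm(fml, family = stats::poisson(), data = dat,
                    control = stats::glm.control(maxit = 100))
  if (!fit$converged)
    stop("APC Poisson fit did not converge within 100 iterations ",
         "(deviance ", format(fit$deviance), ")")
  cf <- stats::coef(fit)
  names(cf)[1] <- "intercept"
  se <- sqrt(diag(stats::vcov(fit)))
  names(se) <- names(cf)
  structure(list(spec = spec, coefficients = cf, se = se,
                 vcov = stats::vcov(fit),
                 deviance = fit$deviance, df = fit$df.residual,
                 null_deviance = fit$null.deviance,
                 transform = transform,
                 ages = table$ages, years = table$years,
                 data_signature = c(n_cells = sum(keep), n_cases = sum(y),
                                    py_total = sum(py))),
            class = "apc_fit")
}

#' @export
print.apc_fit <- function(x, ...) {
  cat(sprintf("%s Poisson incidence model (%d cases, %d cells)\n",
              x$spec$label, x$data_signature[["n_cases"]],
              x$data_signature[["n_cells"]]))
  cat(sprintf("  deviance (LRS vs saturated): %.1f on %d df\n",
              x$deviance, x$df))
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @export
coef.apc_fit <- function(object, ...) object$coefficients

#' @export
summary.apc_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(spec = object$spec, coefficients = tab,
                 deviance = object$deviance, df = object$df),
            class = "summary.apc_fit")
}

#' @export
print.summary.apc_fit <- function(x, ...) {
  cat(x$spec$label, "coefficients (centred covariate scale):\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("deviance %.2f on %d df\n", x$deviance, x$df))
  invisible(x)
}

#' Predict incidence rates from an APC fit
#'
#' @param object An `apc_fit`.
#' @param age,year Vectors of ages and calendar years (recycled to common
#'   length). The cohort covariate extends naturally as `year - age`, so
#'   prediction is valid beyond the fitting window in both directions.
#' @param ... Unused.
#' @return Rates per person-year.
#' @export
predict.apc_fit <- function(object, age, year, ...) {
  n <- max(length(age), length(year))
  age <- rep_len(age, n); year <- rep_len(year, n)
  if (any(age < min(object$ages) | age > max(object$ages)))
    stop("requested age outside the modelled range ",
         min(object$ages), "-", max(object$ages))
  X <- apc_design(age, year, object$spec, object$transform)
  as.vector(exp(X %*% object$coefficients))
}

#' Project incidence rates over a year range
#'
#' Evaluates the fitted polynomial log rate over all modelled ages for the
#' requested years (before or after the fitting window; the cohort index
#' continues as `year - age`).
#'
#' @param fit An `apc_fit`.
#' @param years Integer vector of calendar years.
#' @return A matrix of rates per person-year (ages x years).
#' @export
project_incidence <- function(fit, years) {
  ages <- fit$ages
  grid <- expand.grid(age = ages, year = years)
  r <- predict(fit, grid$age, grid$year)
  matrix(r, length(ages), length(years),
         dimnames = list(age = ages, year = years))
}

#' Rank candidate APC models by likelihood-ratio statistic
#'
#' @param fits List of `apc_fit` objects fitted to the same incidence
#'   table.
#' @param pin Optional model label to mark as selected irrespective of
#'   rank (model choice may combine the LRS with epidemiological
#'   knowledge; the table reports, it does not force).
#' @return A data frame (label, deviance, df, selected) sorted by
#'   ascending deviance.
#' @export
model_selection_table <- function(fits, pin = NULL) {
  sigs <- lapply(fits, `[[`, "data_signature")
  if (length(unique(lapply(sigs, unname))) > 1L)
    stop("fits were not produced from the same incidence table")
  tab <- data.frame(
    label = vapply(fits, function(f) f$spec$label, character(1)),
    deviance = vapply(fits, `[[`, numeric(1), "deviance"),
    df = vapply(fits, `[[`, integer(1), "df"),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$deviance), ]
  rownames(tab) <- NULL
  tab$selected <- if (is.null(pin)) seq_len(nrow(tab)) == 1L else
    tab$label == pin
  if (!is.null(pin) && !any(tab$selected))
    stop("pinned model ", pin, " not among the fitted candidates")
  tab
}
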