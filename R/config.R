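#' Analysis configuration
#'
#' Builds the configuration object consumed by every stage of the pipeline:
#' the eligible age range, the observation and projection windows, the
#' diagnosis periods and age groups used for survival tabulation, and the
#' timing conventions for the phase-of-care analysis.
#'
#' Time is discretised to integer calendar years; diagnoses are placed at
#' mid-year, durations are measured mid-year to mid-year in completed years,
#' and a person is prevalent in year `t` when their death year exceeds `t`.
#' Ages are attained-age integers; the eligible range is the closed interval
#' `[age_min, age_max]`. The population table may carry an `85+` open class
#' but it is excluded from all estimates.
#'
#' @param age_min,age_max Eligible age at diagnosis, inclusive.
#' @param obs_year_min,obs_year_max Observation (registry) window; follow-up
#'   is complete to the end of `obs_year_max`.
#' @param proj_year_max Last projection year.
#' @param periods List of length-2 integer vectors giving the diagnosis
#'   periods for survival tabulation; they must partition the observation
#'   years.
#' @param age_groups List of length-2 integer vectors giving the survival
#'   age groups; they must partition `[age_min, age_max]`.
#' @param long_term_cutoff_years Years since diagnosis after which a survivor
#'   is counted as a long-term survivor.
#' @param metastasis_lag_days Minimum delay after first diagnosis for a
#'   subsequent notification to count as a metastasis.
#' @param subphase_reference_year Calendar year used to estimate the
#'   metastasis/second-primary sub-phase proportions.
#' @param max_follow_up_intervals Maximum number of annual follow-up
#'   intervals tabulated per survival stratum.
#' @param min_at_risk Minimum (unweighted) number at risk for a survival
#'   interval to be tabulated.
#' @param seed Integer random seed used by the synthetic registry generator.
#'
#' @return An object of class `prevmod_config` (a named list).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$age_groups
analysis_config <- function(age_min = 18L,
                            age_max = 84L,
                            obs_year_min = 1972L,
                            obs_year_max = 2007L,
                            proj_year_max = 2017L,
                            periods = list(c(1972L, 1980L), c(1981L, 1989L),
                                           c(1990L, 1995L), c(1996L, 2001L),
                                           c(2002L, 2007L)),
                            age_groups = list(c(18L, 49L), c(50L, 69L),
                                              c(70L, 84L)),
                            long_term_cutoff_years = 10L,
                            metastasis_lag_days = 120L,
                            subphase_reference_year = 2006L,
                            max_follow_up_intervals = 25L,
                            min_at_risk = 10L,
                            seed = 20070101L) {
  cfg <- list(
    age_min = as.integer(age_min),
    age_max = as.integer(age_max),
    obs_year_min = as.integer(obs_year_min),
    obs_year_max = as.integer(obs_year_max),
    proj_year_max = as.integer(proj_year_max),
    periods = lapply(periods, function(p) as.integer(p[1:2])),
    age_groups = lapply(age_groups, function(g) as.integer(g[1:2])),
    long_term_cutoff_years = as.integer(long_term_cutoff_years),
    metastasis_lag_days = as.integer(metastasis_lag_days),
    subphase_reference_year = as.integer(subphase_reference_year),
    max_follow_up_intervals = as.integer(max_follow_up_intervals),
    min_at_risk = as.integer(min_at_risk),
    seed = as.integer(seed)
  )
  class(cfg) <- "prevmod_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$age_min >= 0L, cfg$age_max >= cfg$age_min,
            cfg$obs_year_max >= cfg$obs_year_min,
            cfg$proj_year_max >= cfg$obs_year_max,
            cfg$long_term_cutoff_years >= 1L)
  # periods must partition the observation years, in order and contiguous
  yrs <- unlist(lapply(cfg$periods, function(p) seq.int(p[1], p[2])))
  if (!identical(sort(yrs), seq.int(cfg$obs_year_min, cfg$obs_year_max)))
    stop("diagnosis periods must partition the observation years ",
         cfg$obs_year_min, "-", cfg$obs_year_max)
  ags <- unlist(lapply(cfg$age_groups, function(g) seq.int(g[1], g[2])))
  if (!identical(sort(ags), seq.int(cfg$age_min, cfg$age_max)))
    stop("survival age groups must partition ages ",
         cfg$age_min, "-", cfg$age_max)
  ref <- cfg$subphase_reference_year
  if (ref < cfg$obs_year_min || ref > cfg$obs_year_max - 1L)
    stop("subphase_reference_year needs at least one year of follow-up ",
         "inside the observation window")
  invisible(cfg)
}

#' @export
print.prevmod_config <- function(x, ...) {
  cat("prevmod analysis configuration\n")
  cat(sprintf("  ages %d-%d, observed %d-%d, projected to %d\n",
              x$age_min, x$age_max, x$obs_year_min, x$obs_year_max,
              x$proj_year_max))
  cat("  diagnosis periods:",
      paste(vapply(x$periods, function(p) paste(p, collapse = "-"),
                   character(1)), collapse = ", "), "\n")
  cat("  age groups:",
      paste(vapply(x$age_groups, function(g) paste(g, collapse = "-"),
                   character(1)), collapse = ", "), "\n")
  cat(sprintf("  long-term cutoff %d y, metastasis lag %d d, sub-phase ref %d\n",
              x$long_term_cutoff_years, x$metastasis_lag_days,
              x$subphase_reference_year))
  invisible(x)
}

#' Load a configuration from a YAML file
#'
#' Reads a flat-key YAML file whose keys are the arguments of
#' [analysis_config()]; `periods` and `age_groups` are lists of two-element
#' ranges. Keys absent from the file keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `prevmod_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(analysis_config, raw)
}

# ---- small shared helpers ----

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

period_label <- function(p) paste0(p[1], "-", p[2])
age_group_label <- function(g) paste0(g[1], "-", g[2])

age_group_labels <- function(cfg)
  vapply(cfg$age_groups, age_group_label, character(1))

#' @keywords internal
assign_age_group <- function(age, cfg) {
  labs <- age_group_labels(cfg)
  breaks <- c(vapply(cfg$age_groups, `[`, integer(1), 1L), cfg$age_max + 1L)
  idx <- findInterval(age, breaks)
  idx[age < cfg$age_min | age > cfg$age_max] <- NA_integer_
  factor(labs[idx], levels = labs)
}

assign_period <- function(year, cfg) {
  labs <- vapply(cfg$periods, period_label, character(1))
  breaks <- c(vapply(cfg$periods, `[`, integer(1), 1L), cfg$obs_year_max + 1L)
  idx <- findInterval(year, breaks)
  idx[year < cfg$obs_year_min | year > cfg$obs_year_max] <- NA_integer_
  factor(labs[idx], levels = labs)
}

period_midpoint <- function(p) mean(as.numeric(p[1:2]))

`%||%` <- function(a, b) if (is.null(a)) b else a
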