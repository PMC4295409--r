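#' @title Registry case files
#' @description
#' Case records are exchanged as a flat CSV (`cases.csv`) with one row per
#' registered first-primary case, plus a long-format companion
#' (`events.csv`) holding subsequent metastasis / second-primary
#' notifications. Columns of `cases.csv`:
#'
#' * `case_id` — opaque identifier (string)
#' * `age_dx` — integer age at diagnosis (years)
#' * `year_dx` — integer calendar year of diagnosis
#' * `vital_status` — `"alive"` or `"dead"` at the end of follow-up
#' * `year_death` — integer calendar year of death (empty when alive)
#' * `cause_death` — `"cancer"` or `"other"` (empty when alive)
#' * `dco_flag` — `TRUE` for death-certificate-only or post-mortem
#'   first identification
#'
#' Columns of `events.csv`: `case_id`, `event_year`, `event_type`
#' (`"metastasis"` or `"second_primary"`), and optionally
#' `days_since_dx` (integer days from first diagnosis to the event
#' notification, used by the metastasis lag rule when present).
#' @name registry-files
NULL

CASE_COLUMNS <- c("case_id", "age_dx", "year_dx", "vital_status",
                  "year_death", "cause_death", "dco_flag")

#' Read case records
#'
#' @param path Path to a `cases.csv` file (see [registry-files]).
#' @param config A [analysis_config()] object (used only for basic
#'   plausibility reporting; no filtering is applied here).
#' @return A data frame of case records. Malformed rows raise an error that
#'   reports the offending row numbers.
#' @export
read_cases <- function(path, config = analysis_config()) {
  if (!file.exists(path)) stop("case file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(case_id = "character"))
  missing_cols <- setdiff(CASE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("case file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) return(empty_cases())
  df$age_dx <- coerce_int(df$age_dx, "age_dx")
  df$year_dx <- coerce_int(df$year_dx, "year_dx")
  df$year_death <- coerce_int(df$year_death, "year_death", allow_na = TRUE)
  df$dco_flag <- as.logical(df$dco_flag)
  df$cause_death[!is.na(df$cause_death) & df$cause_death == ""] <- NA
  validate_cases(df)
  df
}

empty_cases <- function() {
  data.frame(case_id = character(), age_dx = integer(), year_dx = integer(),
             vital_status = character(), year_death = integer(),
             cause_death = character(), dco_flag = logical(),
             stringsAsFactors = FALSE)
}

coerce_int <- function(x, name, allow_na = FALSE) {
  if (is.character(x)) x[x == ""] <- NA
  out <- suppressWarnings(as.integer(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop("non-integer ", name, " in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (!allow_na && anyNA(out))
    stop("missing ", name, " in row(s): ",
         paste(utils::head(which(is.na(out)), 10), collapse = ", "))
  out
}

#' Validate case-record invariants
#'
#' Checks the case-level invariants: a death year is present if and only if
#' the vital status is `dead`, the cause of death is present for every dead
#' case, ages are nonnegative and death never precedes diagnosis.
#'
#' @param cases A case data frame.
#' @return The input, invisibly; errors name the offending rows.
#' @export
validate_cases <- function(cases) {
  vs_ok <- cases$vital_status %in% c("alive", "dead")
  if (any(!vs_ok))
    stop("invalid vital_status in row(s): ",
         paste(utils::head(which(!vs_ok), 10), collapse = ", "))
  dead <- cases$vital_status == "dead"
  bad <- which(dead & is.na(cases$year_death))
  if (length(bad))
    stop("vital_status is 'dead' but year_death missing in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  bad <- which(!dead & !is.na(cases$year_death))
  if (length(bad))
    stop("year_death present for alive case(s) in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  bad <- which(dead & (is.na(cases$cause_death) |
                         !cases$cause_death %in% c("cancer", "other")))
  if (length(bad))
    stop("cause_death missing or invalid for dead case(s) in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  bad <- which(cases$age_dx < 0L)
  if (length(bad))
    stop("negative age_dx in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  bad <- which(dead & cases$year_death < cases$year_dx)
  if (length(bad))
    stop("year_death precedes year_dx in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  invisible(cases)
}

#' Write case records
#'
#' @param cases A case data frame (extra columns beyond the documented
#'   schema are dropped).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path) {
  utils::write.csv(cases[, CASE_COLUMNS, drop = FALSE], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write subsequent-event notifications
#'
#' @param path CSV path (see [registry-files] for the schema).
#' @return A data frame with columns `case_id`, `event_year`, `event_type`
#'   and, when present in the file, `days_since_dx`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(case_id = "character"))
  need <- c("case_id", "event_year", "event_type")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("event file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df)) {
    df$event_year <- coerce_int(df$event_year, "event_year")
    ok <- df$event_type %in% c("metastasis", "second_primary")
    if (any(!ok))
      stop("invalid event_type in row(s): ",
           paste(utils::head(which(!ok), 10), collapse = ", "))
  }
  df
}

#' @rdname read_events
#' @param events Event data frame.
#' @export
write_events <- function(events, path) {
  keep <- intersect(c("case_id", "event_year", "event_type", "days_since_dx"),
                    names(events))
  utils::write.csv(events[, keep, drop = FALSE], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read a population table
#'
#' Mid-year person counts by single year of age and calendar year
#' (`population.csv`: columns `age`, `year`, `count`). An open `85+` class
#' may be coded as the highest age present; it is carried but excluded from
#' all estimates.
#'
#' @param path CSV path.
#' @return A `prevmod_population`: a matrix of counts with ages as rows and
#'   calendar years as columns.
#' @export
read_population <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "year", "count")
  if (length(setdiff(need, names(df))))
    stop("population file must have columns age, year, count")
  as_population(df)
}

#' Construct a population table from a long data frame
#'
#' @param df Data frame with columns `age`, `year`, `count`.
#' @return A `prevmod_population` matrix (ages x years).
#' @export
as_population <- function(df) {
  if (any(df$count < 0)) stop("population counts must be nonnegative")
  ages <- sort(unique(df$age)); years <- sort(unique(df$year))
  m <- matrix(NA_real_, length(ages), length(years),
              dimnames = list(age = ages, year = years))
  m[cbind(match(df$age, ages), match(df$year, years))] <- df$count
  if (anyNA(m))
    stop("population grid is not rectangular over its age x year range")
  class(m) <- c("prevmod_population", class(m))
  m
}

#' @rdname read_population
#' @param population A `prevmod_population`.
#' @export
write_population <- function(population, path) {
  df <- as.data.frame.table(unclass(population), stringsAsFactors = FALSE,
                            responseName = "count")
  names(df)[1:2] <- c("age", "year")
  df$age <- as.integer(df$age); df$year <- as.integer(df$year)
  utils::write.csv(df[order(df$year, df$age), ], path, row.names = FALSE)
  invisible(path)
}

#' Read an all-cause life table
#'
#' Annual death probabilities `qx` by single year of age and calendar year
#' (`lifetable.csv`: columns `age`, `year`, `qx`). At the grid edges `qx` is
#' extended by freezing: requests below/above the covered years use the
#' first/last year's column, and ages above the highest tabulated age use
#' the highest age's value.
#'
#' @param path CSV path.
#' @return A `prevmod_lifetable`: a matrix of `qx` with ages as rows and
#'   calendar years as columns.
#' @export
read_lifetable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "year", "qx")
  if (length(setdiff(need, names(df))))
    stop("life table file must have columns age, year, qx")
  as_lifetable(df)
}

#' Construct a life table from a long data frame
#'
#' @param df Data frame with columns `age`, `year`, `qx`.
#' @return A `prevmod_lifetable` matrix (ages x years).
#' @export
as_lifetable <- function(df) {
  if (any(df$qx < 0 | df$qx > 1)) stop("qx must lie in [0, 1]")
  ages <- sort(unique(df$age)); years <- sort(unique(df$year))
  m <- matrix(NA_real_, length(ages), length(years),
              dimnames = list(age = ages, year = years))
  m[cbind(match(df$age, ages), match(df$year, years))] <- df$qx
  if (anyNA(m))
    stop("life table grid is not rectangular over its age x year range")
  class(m) <- c("prevmod_lifetable", class(m))
  m
}

#' @rdname read_lifetable
#' @param lifetable A `prevmod_lifetable`.
#' @export
write_lifetable <- function(lifetable, path) {
  df <- as.data.frame.table(unclass(lifetable), stringsAsFactors = FALSE,
                            responseName = "qx")
  names(df)[1:2] <- c("age", "year")
  df$age <- as.integer(df$age); df$year <- as.integer(df$year)
  utils::write.csv(df[order(df$year, df$age), ], path, row.names = FALSE)
  invisible(path)
}

# qx lookup with frozen-edge extension in both age and year.
qx_at <- function(lifetable, age, year) {
  ages <- as.integer(rownames(lifetable))
  years <- as.integer(colnames(lifetable))
  i <- pmin(pmax(match_clamp(age, ages), 1L), nrow(lifetable))
  j <- pmin(pmax(match_clamp(year, years), 1L), ncol(lifetable))
  lifetable[cbind(i, j)]
}

match_clamp <- function(x, grid) {
  idx <- match(x, grid)
  idx[is.na(idx) & x < grid[1]] <- 1L
  idx[is.na(idx) & x > grid[length(grid)]] <- length(grid)
  if (anyNA(idx)) stop("value falls inside the grid range but off the grid")
  idx
}

#' Filter cases to the eligible analysis population
#'
#' Retains cases aged within `[age_min, age_max]` at diagnosis, diagnosed
#' within the observation window, and not identified through death
#' certificate only or post-mortem. The exclusion tally is attached as the
#' `"exclusions"` attribute (counts by reason).
#'
#' @param cases Case data frame.
#' @param config A [analysis_config()].
#' @return The eligible subset, with an `"exclusions"` attribute.
#' @export
filter_eligible <- function(cases, config = analysis_config()) {
  age_ok <- cases$age_dx >= config$age_min & cases$age_dx <= config$age_max
  year_ok <- cases$year_dx >= config$obs_year_min &
    cases$year_dx <= config$obs_year_max
  dco <- isTRUE_vec(cases$dco_flag)
  keep <- age_ok & year_ok & !dco
  tally <- c(
    "age outside range" = sum(!age_ok),
    "diagnosis outside window" = sum(age_ok & !year_ok),
    "DCO/post-mortem" = sum(age_ok & year_ok & dco)
  )
  out <- cases[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- tally
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
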