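#' Decompose prevalence into phases of care
#'
#' Splits the modelled prevalent population of each year into mutually
#' exclusive phases of the survivorship trajectory:
#'
#' * `last_year` — alive at mid-year but dying of the cancer within the
#'   next 12 months (the expected cancer deaths of the following calendar
#'   year, allocated across age/duration strata proportionally to each
#'   stratum's modelled excess deaths);
#' * `initial` — within the first 12 months of diagnosis (duration 0),
#'   excluding its last-year-of-life allocation;
#' * `monitoring` — durations 1 to `long_term_cutoff_years - 1`, minus
#'   allocation;
#' * `long_term` — durations at or beyond the cutoff, minus allocation;
#' * `subphase_event` — zero here; filled by [apply_subphase()].
#'
#' Phase counts sum to total prevalence exactly for every year and age
#' group (a person occupies exactly one phase at a time).
#'
#' @param surface A `prevalence_surface` (carries the excess-death
#'   decomposition used for allocation).
#' @param deaths Optional `mortality_series` giving expected cancer deaths
#'   per calendar year; it must cover `years + 1`. When `NULL`, the
#'   surface's own excess-death decomposition is used directly (the two
#'   agree when the deaths series came from
#'   [compute_expected_mortality()] on the same inputs).
#' @param config A [analysis_config()].
#' @param years Years to decompose (subset of the surface years).
#' @return A `phase_table`: counts array (phase x age group x year).
#' @export
decompose_phases <- function(surface, deaths = NULL,
                             config = analysis_config(),
                             years = surface$years) {
  cfg <- config
  years <- sort(as.integer(years))
  if (!all(years %in% surface$years))
    stop("surface does not cover requested years")
  cut <- cfg$long_term_cutoff_years
  ndur <- dim(surface$count)[3]
  if (ndur < cut + 1L) stop("surface is missing duration strata")
  glabs <- age_group_labels(cfg)
  grp <- assign_age_group(surface$ages, cfg)
  phases <- c("initial", "monitoring", "long_term", "last_year",
              "subphase_event")
  out <- array(0, c(length(phases), length(glabs), length(years)),
               dimnames = list(phase = phases, age_group = glabs,
                               year = years))
  clipped <- FALSE
  for (ti in seq_along(years)) {
    t <- years[ti]
    si <- match(t, surface$years)
    N <- array(surface$count[, si, ],
               c(length(surface$ages), ndur))    # age x duration
    A <- array(surface$excess_deaths[, si, ], dim(N))
    if (!is.null(deaths)) {
      target <- deaths$expected[match(t + 1L, deaths$year)]
      if (is.na(target))
        stop("deaths series must cover year ", t + 1L,
             " to size the last-year-of-life phase at ", t)
      tot_A <- sum(A)
      alloc <- if (tot_A > 0) A * (target / tot_A) else A
    } else alloc <- A
    over <- alloc > N
    if (any(over)) {
      clipped <- TRUE
      alloc[over] <- N[over]
    }
    rem <- N - alloc
    dur <- as.integer(dimnames(surface$count)[[3]])
    d_init <- dur == 0L
    d_mon <- dur >= 1L & dur < cut
    d_lt <- dur >= cut
    out["initial", , ti] <- rowsum_by(rem[, d_init, drop = FALSE], grp)
    out["monitoring", , ti] <- rowsum_by(rem[, d_mon, drop = FALSE], grp)
    out["long_term", , ti] <- rowsum_by(rem[, d_lt, drop = FALSE], grp)
    out["last_year", , ti] <- rowsum_by(alloc, grp)
  }
  if (clipped)
    warning("death allocation exceeded a stratum's prevalence; clipped to 0")
  structure(list(counts = out, years = years, config = cfg),
            class = "phase_table")
}

rowsum_by <- function(m, grp) {
  v <- rowSums(m)
  as.numeric(rowsum(v, grp))
}

#' @export
print.phase_table <- function(x, ...) {
  t_last <- max(x$years)
  cat("phase-of-care prevalence,", min(x$years), "-", t_last, "\n")
  m <- x$counts[, , as.character(t_last)]
  m <- cbind(m, Total = rowSums(m))
  m <- rbind(m, Total = colSums(m))
  cat("counts for", t_last, ":\n")
  print(round(m))
  invisible(x)
}

#' @export
as.data.frame.phase_table <- function(x, ...) {
  df <- as.data.frame.table(x$counts, stringsAsFactors = FALSE,
                            responseName = "count")
  df$year <- as.integer(df$year)
  df
}

#' Total prevalence per year implied by a phase table
#'
#' @param table A `phase_table`.
#' @return Named numeric vector (year totals).
#' @export
phase_totals <- function(table) {
  apply(table$counts, 3, sum)
}

# per-case phase assignment at mid-year `year` (NA when not prevalent).
# Requires follow-up through year + 1 to identify the last-year phase.
case_phase <- function(cases, year, config) {
  cfg <- config
  d <- year - cases$year_dx
  attained <- cases$age_dx + d
  alive <- is.na(cases$year_death) | cases$year_death > year
  prevalent <- alive & d >= 0 & attained <= cfg$age_max
  phase <- rep(NA_character_, nrow(cases))
  dying <- !is.na(cases$year_death) & cases$year_death == year + 1L &
    !is.na(cases$cause_death) & cases$cause_death == "cancer"
  cut <- cfg$long_term_cutoff_years
  phase[prevalent & dying] <- "last_year"
  rest <- prevalent & !dying
  phase[rest & d == 0L] <- "initial"
  phase[rest & d >= 1L & d < cut] <- "monitoring"
  phase[rest & d >= cut] <- "long_term"
  phase
}

#' Direct-counting phase decomposition
#'
#' Assigns every prevalent case to its phase of care at mid-year of
#' `year` directly from individual follow-up (the counting analogue of
#' [decompose_phases()], and the oracle for it on simulated registries
#' with complete follow-up).
#'
#' @param cases Case data frame with follow-up complete through
#'   `year + 1`.
#' @param year Index year (at most `obs_year_max - 1`).
#' @param config A [analysis_config()].
#' @return Counts matrix (phase x attained-age group).
#' @export
counting_phases <- function(cases, year, config = analysis_config()) {
  cfg <- config
  if (year + 1L > cfg$obs_year_max)
    stop("need follow-up through ", year + 1L,
         " to identify the last-year-of-life phase")
  ph <- case_phase(cases, year, cfg)
  keep <- !is.na(ph)
  grp <- assign_age_group(cases$age_dx[keep] + (year - cases$year_dx[keep]),
                          cfg)
  phases <- c("initial", "monitoring", "long_term", "last_year")
  m <- table(factor(ph[keep], levels = phases), grp)
  out <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  names(dimnames(out)) <- c("phase", "age_group")
  out
}

#' Estimate metastasis / second-primary sub-phase proportions
#'
#' Among members of the post-treatment monitoring and long-term survivor
#' phases in the reference year, computes the fraction who presented a
#' qualifying subsequent event in that year — a metastasis notified at
#' least `metastasis_lag_days` after first diagnosis, or a second primary
#' — and survived at least one year after the event (those who died
#' within a year belong to the last-year-of-life phase instead).
#'
#' When the event file carries `days_since_dx`, the metastasis lag rule
#' is applied in days; otherwise same-year notifications (the only ones
#' the annual resolution cannot adjudicate) are excluded.
#'
#' @param cases Case data frame with follow-up through the year after the
#'   reference year.
#' @param events Event data frame (see [read_events()]).
#' @param config A [analysis_config()]; `subphase_reference_year` sets
#'   the reference year.
#' @return An `event_proportions` list: `p_monitoring`, `p_long_term`,
#'   numerators/denominators and the reference year.
#' @export
estimate_event_proportions <- function(cases, events,
                                       config = analysis_config()) {
  cfg <- config
  ref <- cfg$subphase_reference_year
  ph <- case_phase(cases, ref, cfg)
  qualifying <- events$event_year == ref
  if ("days_since_dx" %in% names(events)) {
    lag_ok <- events$event_type != "metastasis" |
      (!is.na(events$days_since_dx) &
         events$days_since_dx >= cfg$metastasis_lag_days)
  } else {
    yr_dx <- cases$year_dx[match(events$case_id, cases$case_id)]
    lag_ok <- events$event_type != "metastasis" | events$event_year > yr_dx
  }
  ev_ids <- unique(events$case_id[qualifying & lag_ok])
  has_event <- cases$case_id %in% ev_ids
  survived <- is.na(cases$year_death) | cases$year_death >= ref + 2L
  out <- list(reference_year = ref)
  for (phase in c("monitoring", "long_term")) {
    denom <- sum(ph == phase, na.rm = TRUE)
    if (denom == 0L)
      stop("no cases in the ", phase, " phase in ", ref)
    num <- sum(ph == phase & has_event & survived, na.rm = TRUE)
    key <- if (phase == "monitoring") "p_monitoring" else "p_long_term"
    out[[key]] <- num / denom
    out[[paste0("n_", phase)]] <- denom
    out[[paste0("events_", phase)]] <- num
  }
  class(out) <- "event_proportions"
  out
}

#' @export
print.event_proportions <- function(x, ...) {
  cat(sprintf(
    "subsequent-event proportions in %d:\n  monitoring %d/%d = %.3f%%\n  long-term  %d/%d = %.3f%%\n",
    x$reference_year, x$events_monitoring, x$n_monitoring,
    100 * x$p_monitoring, x$events_long_term, x$n_long_term,
    100 * x$p_long_term))
  invisible(x)
}

#' Apply sub-phase proportions to projected phases
#'
#' Moves `round(p_monitoring * monitoring)` and
#' `round(p_long_term * long_term)` cases from their parent phases into
#' the treatment-for-metastases/second-cancer sub-phase, per age group
#' and year. The moved counts are subtracted from the parents, so the
#' total is conserved exactly.
#'
#' @param table A `phase_table`.
#' @param props An `event_proportions` (or list with `p_monitoring`,
#'   `p_long_term`).
#' @param years Years to apply to (default: all years of the table).
#' @return The updated `phase_table`.
#' @export
apply_subphase <- function(table, props, years = table$years) {
  years <- intersect(as.integer(years), table$years)
  cnt <- table$counts
  for (t in as.character(years)) {
    mv_m <- round(props$p_monitoring * cnt["monitoring", , t])
    mv_l <- round(props$p_long_term * cnt["long_term", , t])
    cnt["monitoring", , t] <- cnt["monitoring", , t] - mv_m
    cnt["long_term", , t] <- cnt["long_term", , t] - mv_l
    cnt["subphase_event", , t] <- cnt["subphase_event", , t] + mv_m + mv_l
  }
  table$counts <- cnt
  table
}

#' Derived change statistics between two years
#'
#' Percent change `(N_b - N_a) / N_a * 100` and the average annual linear
#' rate of increase (percent change divided by the number of years).
#'
#' @param totals Named numeric vector of year totals (names are years),
#'   e.g. from [prevalence_totals()] or [phase_totals()].
#' @param from,to The two years to compare.
#' @return List with `percent_change`, `annual_rate`, `from`, `to`;
#'   values are `NA` (with a message) when the baseline is zero.
#' @export
summary_statistics <- function(totals, from, to) {
  if (!all(as.character(c(from, to)) %in% names(totals)))
    stop("totals must contain both years ", from, " and ", to)
  na <- totals[[as.character(from)]]
  nb <- totals[[as.character(to)]]
  if (na == 0) {
    message("baseline total is zero; percent change undefined")
    return(list(percent_change = NA_real_, annual_rate = NA_real_,
                from = from, to = to))
  }
  pc <- (nb - na) / na * 100
  list(percent_change = pc, annual_rate = pc / (to - from),
       from = from, to = to)
}

#' Share of survivors requiring active treatment
#'
#' Initial-care plus sub-phase counts as a fraction of total prevalence —
#' the "will require active treatment" headline statistic.
#'
#' @param table A `phase_table` (after [apply_subphase()]).
#' @param year Index year.
#' @return Fraction in `[0, 1]`.
#' @export
active_treatment_share <- function(table, year) {
  m <- table$counts[, , as.character(year)]
  (sum(m["initial", ]) + sum(m["subphase_event", ])) / sum(m)
}
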