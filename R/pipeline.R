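#' Run the full prevalence analysis pipeline
#'
#' Orchestrates the end-to-end analysis: registry input (read from a
#' directory of CSVs, or simulated), eligibility filtering, incidence
#' tabulation and candidate APC fits with model selection, Pohar Perme
#' net-survival tabulation and mixture cure fit, the prevalence /
#' mortality convolution, mortality validation, phase-of-care
#' decomposition and the metastasis/second-primary sub-phase. Stage
#' progress is logged to standard error; tabular outputs, a report and a
#' manifest with file digests are written to `out_dir`.
#'
#' @param config A [analysis_config()], or the path to a YAML file for
#'   [read_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param input_dir Directory containing `cases.csv`, `events.csv`,
#'   `population.csv`, `lifetable.csv`; when `NULL` a registry is
#'   simulated with `params`.
#' @param params [sim_params()] used when simulating.
#' @param model Label of the APC model used for projection (`NULL` lets
#'   the likelihood-ratio statistic decide). The cubic age + cubic cohort
#'   model is the default projection model.
#' @return (Invisibly) a list with every intermediate object: `registry`,
#'   `eligible`, `incidence`, `apc_fits`, `selection`, `apc`, `relsurv`,
#'   `cure`, `surface`, `mortality`, `validation`, `counting`, `phases`,
#'   `event_props`, `report`, `manifest`.
#' @export
run_pipeline <- function(config = analysis_config(), out_dir = NULL,
                         input_dir = NULL, params = sim_params(),
                         model = "APC303") {
  if (is.character(config)) config <- read_config(config)
  cfg <- config
  stage <- function(...) message("[prevmod] ", sprintf(...))

  if (is.null(input_dir)) {
    stage("simulating synthetic registry (seed %d)",
          params$seed %||% cfg$seed)
    reg <- simulate_registry(params, cfg)
  } else {
    stage("reading registry from %s", input_dir)
    reg <- list(
      cases = read_cases(file.path(input_dir, "cases.csv"), cfg),
      events = read_events(file.path(input_dir, "events.csv")),
      population = read_population(file.path(input_dir, "population.csv")),
      lifetable = read_lifetable(file.path(input_dir, "lifetable.csv")),
      config = cfg)
    class(reg) <- "prevmod_registry"
  }

  stage("filtering eligible cases")
  eligible <- filter_eligible(reg$cases, cfg)
  excl <- attr(eligible, "exclusions")
  stage("  %d eligible; excluded: %s", nrow(eligible),
        paste(names(excl), excl, sep = "=", collapse = ", "))

  stage("tabulating incidence and fitting candidate APC models")
  inc <- tabulate_incidence(eligible, reg$population, cfg)
  fits <- lapply(apc_model_specs(), function(sp) fit_apc(inc, sp))
  selection <- model_selection_table(fits, pin = model)
  chosen <- selection$label[selection$selected][1]
  stage("  projection model: %s (deviance %.1f)", chosen,
        selection$deviance[selection$label == chosen])
  apc <- fits[[chosen]]

  stage("tabulating Pohar Perme net survival and fitting cure model")
  rstab <- tabulate_pohar_perme(eligible, reg$lifetable, cfg)
  cure <- fit_mixture_cure(rstab, cfg)

  years <- cfg$obs_year_min:cfg$proj_year_max
  stage("computing prevalence surface %d-%d", min(years), max(years))
  surface <- compute_prevalence(apc, cure, reg$lifetable, reg$population,
                                cfg, years)
  stage("computing expected mortality and validating")
  mortality <- compute_expected_mortality(apc, cure, reg$lifetable,
                                          reg$population, cfg,
                                          c(years, max(years) + 1L))
  obs_deaths <- observed_cancer_deaths(reg$cases,
                                       cfg$obs_year_min:cfg$obs_year_max,
                                       cfg)
  validation <- mortality_validation(mortality, obs_deaths)
  stage("  mean |relative difference| = %.3f", attr(validation, "mard"))
  counting <- counting_prevalence(eligible, reg$population,
                                  cfg$obs_year_max, cfg)

  stage("decomposing phases of care and applying the sub-phase")
  phases <- decompose_phases(surface, mortality, cfg, years)
  event_props <- estimate_event_proportions(reg$cases, reg$events, cfg)
  proj_years <- (cfg$obs_year_max + 1L):cfg$proj_year_max
  phases <- apply_subphase(phases, event_props, proj_years)

  report <- make_report(list(surface = surface, phases = phases,
                             config = cfg, event_props = event_props))

  result <- list(registry = reg, eligible = eligible, incidence = inc,
                 apc_fits = fits, selection = selection, apc = apc,
                 relsurv = rstab, cure = cure, surface = surface,
                 mortality = mortality, validation = validation,
                 counting = counting, phases = phases,
                 event_props = event_props, report = report,
                 config = cfg)
  if (!is.null(out_dir)) {
    stage("writing outputs to %s", out_dir)
    result$manifest <- write_pipeline_outputs(result, out_dir)
  }
  invisible(result)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  fp <- function(f) file.path(out_dir, f)

  utils::write.csv(res$selection, fp("model_selection.csv"),
                   row.names = FALSE)
  apc <- res$apc
  jsonlite::write_json(
    list(spec = unclass(apc$spec), transform = apc$transform,
         coefficients = as.list(apc$coefficients), se = as.list(apc$se),
         deviance = apc$deviance, df = apc$df),
    fp("apc_fit.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rate_df <- as.data.frame.table(
    project_incidence(apc, cfg$obs_year_min:cfg$proj_year_max),
    stringsAsFactors = FALSE, responseName = "rate")
  names(rate_df)[1:2] <- c("age", "year")
  utils::write.csv(rate_df, fp("incidence_rates.csv"), row.names = FALSE)
  write_relsurv(res$relsurv, fp("relsurv.csv"))
  write_cure_fit(res$cure, fp("cure_fit.json"))
  utils::write.csv(summary(res$surface), fp("prevalence_summary.csv"),
                   row.names = FALSE)
  byg <- prevalence_by_age_group(res$surface)
  byg_df <- data.frame(age_group = rownames(byg),
                       round(byg, 2), check.names = FALSE)
  utils::write.csv(byg_df, fp("prevalence_by_age_group.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$validation),
                   fp("mortality_validation.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$phases), fp("phase_table.csv"),
                   row.names = FALSE)
  writeLines(res$report$markdown, fp("report.md"))
  jsonlite::write_json(res$report$stats, fp("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("prevmod")),
    seed = cfg$seed,
    config = unclass(cfg),
    files = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest
}

#' Build the report tables and derived statistics
#'
#' Produces the two headline tables — prevalence by year and age group,
#' and the final-year phase-of-care decomposition with column
#' percentages — plus the derived statistics block (percent change and
#' average annual linear rate of increase over the projection decade, and
#' the active-treatment share). Percentage denominators: age-group
#' columns are percentages of the year's total; phase rows are
#' percentages of their age-group column total.
#'
#' @param x A [run_pipeline()] result (or a list with `surface`,
#'   `phases`, `config`), or a directory written by `run_pipeline()`.
#' @return A list with `table1` (data frame), `table2` (data frame),
#'   `stats` (list) and `markdown` (character vector).
#' @export
make_report <- function(x) {
  if (is.character(x)) stop("pass the run_pipeline() result list")
  surface <- x$surface; phases <- x$phases; cfg <- x$config
  tot <- prevalence_totals(surface)
  byg <- prevalence_by_age_group(surface)

  mids <- if (cfg$proj_year_max >= cfg$obs_year_max + 4L)
    seq(cfg$obs_year_max + 4L, cfg$proj_year_max, by = 2L) else integer()
  report_years <- intersect(
    unique(c(cfg$obs_year_max, mids, cfg$proj_year_max)), surface$years)
  t1 <- data.frame(year = report_years)
  for (g in rownames(byg)) {
    n <- byg[g, as.character(report_years)]
    t1[[g]] <- round(n)
    t1[[paste0(g, "_pct")]] <-
      round(100 * n / tot[as.character(report_years)], 1)
  }
  t1$total <- round(tot[as.character(report_years)])

  yr <- max(phases$years)
  m <- phases$counts[, , as.character(yr)]
  col_tot <- colSums(m)
  t2 <- data.frame(phase = rownames(m), round(m), check.names = FALSE)
  for (g in colnames(m))
    t2[[paste0(g, "_pct")]] <-
      ifelse(rep(col_tot[g] > 0, nrow(m)),
             round(100 * m[, g] / col_tot[g], 1), NA_real_)
  t2$total <- round(rowSums(m))
  grand <- sum(m)
  t2$total_pct <- if (grand > 0) round(100 * rowSums(m) / grand, 1) else
    NA_real_

  ss <- summary_statistics(tot, cfg$obs_year_max, cfg$proj_year_max)
  stats <- list(
    total_last_observed = unname(tot[as.character(cfg$obs_year_max)]),
    total_projected = unname(tot[as.character(cfg$proj_year_max)]),
    percent_change = ss$percent_change,
    annual_rate = ss$annual_rate,
    active_treatment_share = active_treatment_share(phases, yr))
  if (!is.null(x$event_props))
    stats$subphase_proportions <- list(
      monitoring = x$event_props$p_monitoring,
      long_term = x$event_props$p_long_term,
      reference_year = x$event_props$reference_year)

  md <- c(
    "# Prevalence analysis report", "",
    sprintf("Total prevalence: %s (%d) -> %s (%d), %+.1f%% (%.2f%%/year).",
            format(round(stats$total_last_observed), big.mark = ","),
            cfg$obs_year_max,
            format(round(stats$total_projected), big.mark = ","),
            cfg$proj_year_max, stats$percent_change, stats$annual_rate),
    sprintf("Active treatment (initial care + subsequent events): %.0f%% of survivors in %d.",
            100 * stats$active_treatment_share, yr), "",
    "## Prevalence by age group (column % of year total)", "",
    df_to_md(t1),
    "",
    sprintf("## Phases of care in %d (%% of age-group column)", yr), "",
    df_to_md(t2))

  list(table1 = t1, table2 = t2, stats = stats, markdown = md)
}

df_to_md <- function(df) {
  hdr <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r)
    paste("|", paste(r, collapse = " | "), "|"))
  c(hdr, sep, rows)
}
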