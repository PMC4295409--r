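#' Tabulate net survival with the Pohar Perme actuarial estimator
#'
#' Computes cumulative net (relative) survival over annual follow-up
#' intervals for each survival age group (by age at diagnosis) and
#' diagnosis period, using the Pohar Perme inverse-expected-survival
#' weighting in actuarial (life-table) form with the cohort approach:
#' interval `j` of a stratum is tabulated only from cases whose potential
#' follow-up (to the end of the observation window) reaches `j`, so
#' administrative censoring never cuts an interval in half.
#'
#' For interval `j` (durations `(j-1, j]` since mid-year of diagnosis),
#' each case at risk is weighted by the inverse of its cumulative expected
#' survival `1 / S_E(j-1)` taken along its diagnosis-cohort diagonal of
#' the life table (age and calendar year advancing together). The interval
#' net survival factor is
#' `(1 - D*/N*) / (1 - E*/N*)`,
#' with `D*`, `N*`, `E*` the weighted deaths, number at risk and expected
#' deaths; cumulative net survival is the product of the factors. With
#' `qx = 0` everywhere the weights are 1 and the estimator reduces exactly
#' to the classic actuarial observed-survival estimator. Net survival is
#' not bounded above by 1 and may slightly exceed it.
#'
#' Deaths recorded in the year of diagnosis are assigned to interval 1.
#' Standard errors are Greenwood-style on the weighted counts
#' (approximate, used to weight the cure-model fit).
#'
#' @param cases Eligible case data frame.
#' @param lifetable A `prevmod_lifetable` covering the attained ages and
#'   years reached (edges frozen beyond the grid).
#' @param config A [analysis_config()].
#' @return A `relsurv_table` data frame with columns `age_group`,
#'   `period`, `interval`, `rs`, `se`, `n_at_risk` (weighted) and
#'   `n_events`; strata with no tabulable intervals are absent (with a
#'   warning).
#' @export
tabulate_pohar_perme <- function(cases, lifetable,
                                 config = analysis_config()) {
  cfg <- config
  if (!nrow(cases)) stop("no cases to tabulate")
  a0 <- cases$age_dx
  y0 <- cases$year_dx
  K <- ifelse(is.na(cases$year_death), Inf,
              pmax(1L, cases$year_death - y0))
  L <- cfg$obs_year_max - y0
  J_cap <- min(cfg$max_follow_up_intervals, max(L))

  # cumulative expected survival S_E(d), d = 0..J_cap, per case
  n <- length(a0)
  cumS <- matrix(1, n, J_cap + 1L)       # column d+1 holds S_E(d)
  for (d in seq_len(J_cap))
    cumS[, d + 1L] <- cumS[, d] * (1 - qx_at(lifetable, a0 + d - 1L,
                                             y0 + d - 1L))

  group <- assign_age_group(a0, cfg)
  period <- assign_period(y0, cfg)
  out <- list()
  for (g in levels(group)) for (p in levels(period)) {
    idx <- which(group == g & period == p)
    if (!length(idx)) {
      warning("empty survival stratum: ", g, " / ", p)
      next
    }
    rows <- tabulate_stratum(idx, K, L, a0, y0, cumS, lifetable,
                             J_cap, cfg$min_at_risk)
    if (is.null(rows)) {
      warning("no tabulable intervals for stratum ", g, " / ", p)
      next
    }
    rows$age_group <- g; rows$period <- p
    out[[paste(g, p)]] <- rows
  }
  if (!length(out)) stop("no stratum produced any tabulable interval")
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab <- tab[, c("age_group", "period", "interval", "rs", "se",
                 "n_at_risk", "n_events")]
  attr(tab, "config") <- cfg
  class(tab) <- c("relsurv_table", "data.frame")
  tab
}

tabulate_stratum <- function(idx, K, L, a0, y0, cumS, lifetable,
                             J_cap, min_at_risk) {
  rs <- 1; var_acc <- 0
  recs <- list()
  for (j in seq_len(J_cap)) {
    elig <- idx[L[idx] >= j]                 # cohort approach
    at_risk <- elig[K[elig] >= j]
    if (length(at_risk) < min_at_risk) break
    w <- 1 / cumS[at_risk, j]
    Nw <- sum(w)
    died <- K[at_risk] == j
    Dw <- sum(w[died])
    Ew <- sum(w * qx_at(lifetable, a0[at_risk] + j - 1L,
                        y0[at_risk] + j - 1L))
    obs_fac <- 1 - Dw / Nw
    exp_fac <- 1 - Ew / Nw
    if (exp_fac <= 0) break
    rs <- rs * obs_fac / exp_fac
    if (Nw > Dw) var_acc <- var_acc + Dw / (Nw * (Nw - Dw))
    recs[[j]] <- data.frame(interval = j, rs = rs,
                            se = rs * sqrt(var_acc),
                            n_at_risk = Nw, n_events = sum(died))
  }
  if (!length(recs)) return(NULL)
  do.call(rbind, recs)
}

#' @export
print.relsurv_table <- function(x, ...) {
  cat("Pohar Perme net survival tabulation\n")
  strata <- unique(x[, c("age_group", "period")])
  cat(sprintf("  %d strata, intervals 1-%d\n", nrow(strata),
              max(x$interval)))
  print.data.frame(utils::head(x, 12), digits = 4)
  if (nrow(x) > 12) cat("  ...", nrow(x) - 12, "more rows\n")
  invisible(x)
}

#' Write / read a net-survival tabulation
#'
#' @param table A `relsurv_table`.
#' @param path CSV path.
#' @export
write_relsurv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
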