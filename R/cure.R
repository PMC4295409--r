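#' Fit a mixture cure model to tabulated net survival
#'
#' Models cumulative net survival at duration `t` for diagnosis year `y`
#' within each survival age group `g` as
#' `RS(t; g, y) = c(g, y) + (1 - c(g, y)) * exp(-(lambda(g, y) * t)^gamma(g))`,
#' with a linear trend on the logit of the cure fraction,
#' `logit c = q_g + s_g (y - y_ref)`, a log-linear trend on the Weibull
#' scale, `log lambda = l_g + m_g (y - y_ref)`, and an age-group-specific
#' shape `gamma_g`. The parameters are estimated per age group by
#' inverse-variance-weighted least squares against the tabulated values,
#' each tabulation point placed at its diagnosis-period midpoint (the
#' natural second step after tabulating survival, which keeps the survival
#' model decoupled from the individual-level data).
#'
#' @param table A `relsurv_table` from [tabulate_pohar_perme()], or any
#'   data frame with columns `age_group`, `period`, `interval`, `rs`, `se`
#'   (set `se` to 0 or `NA` for unweighted fitting).
#' @param config A [analysis_config()].
#' @param y_ref Reference diagnosis year for the trends (default: the
#'   midpoint of the observation window, rounded).
#' @return An object of class `cure_fit`: per-group parameter estimates
#'   `(q, s, l, m, log_gamma)` with approximate standard errors, fitted
#'   residuals, and boundary flags (cure fraction within 0.005 of 0 or 1
#'   at an observed period midpoint).
#' @export
fit_mixture_cure <- function(table, config = analysis_config(),
                             y_ref = NULL) {
  cfg <- config
  y_ref <- y_ref %||% round(mean(c(cfg$obs_year_min, cfg$obs_year_max)))
  need <- c("age_group", "period", "interval", "rs")
  if (length(setdiff(need, names(table))))
    stop("tabulation must have columns ", paste(need, collapse = ", "))
  if (is.null(table$se)) table$se <- NA_real_
  pmid <- vapply(strsplit(as.character(table$period), "-"),
                 function(p) mean(as.numeric(p)), numeric(1))
  groups <- unique(as.character(table$age_group))
  fits <- list()
  for (g in groups) {
    sub <- table[table$age_group == g, , drop = FALSE]
    ymid <- pmid[table$age_group == g]
    if (length(unique(ymid)) < 2L)
      stop("age group ", g, " needs >= 2 diagnosis periods to fit a trend")
    fits[[g]] <- fit_cure_group(sub$rs, sub$se, sub$interval, ymid, y_ref, g)
  }
  structure(list(groups = fits, y_ref = y_ref,
                 obs_year_min = cfg$obs_year_min,
                 obs_year_max = cfg$obs_year_max),
            class = "cure_fit")
}

cure_rs <- function(theta, t, y, y_ref) {
  cf <- expit(theta[[1]] + theta[[2]] * (y - y_ref))
  lam <- exp(theta[[3]] + theta[[4]] * (y - y_ref))
  gam <- exp(theta[[5]])
  unname(cf + (1 - cf) * exp(-(lam * t)^gam))
}

fit_cure_group <- function(rs, se, t, y, y_ref, label) {
  w <- cure_weights(se)
  obj <- function(theta) {
    r <- rs - cure_rs(theta, t, y, y_ref)
    sum(w * r^2)
  }
  # starting values: the long-duration plateau approximates the cure level
  plateau <- stats::weighted.mean(rs[t >= stats::quantile(t, 0.7)],
                                  w[t >= stats::quantile(t, 0.7)])
  q0 <- logit(min(max(plateau, 0.02), 0.98))
  starts <- list(c(q0, 0, log(0.3), 0, 0),
                 c(q0, 0.02, log(0.15), 0, log(1.2)),
                 c(0, 0, log(0.5), 0, 0))
  best <- NULL
  for (s0 in starts) {
    res <- tryCatch(
      stats::nlminb(s0, obj,
                    lower = c(-8, -0.5, -6, -0.5, log(0.2)),
                    upper = c(8, 0.5, 3, 0.5, log(6)),
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$objective < best$objective))
      best <- res
  }
  if (is.null(best))
    stop("mixture cure fit failed for age group ", label)
  if (best$convergence != 0 && best$objective > 1e-6) {
    res2 <- stats::optim(best$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 2000))
    if (res2$value < best$objective)
      best <- list(par = res2$par, objective = res2$value,
                   convergence = res2$convergence)
  }
  theta <- best$par
  names(theta) <- c("q", "s", "l", "m", "log_gamma")
  resid <- rs - cure_rs(theta, t, y, y_ref)
  vc <- cure_vcov(theta, rs, w, t, y, y_ref)
  cf_obs <- expit(theta[1] + theta[2] * (unique(y) - y_ref))
  boundary <- any(cf_obs > 0.995) || any(cf_obs < 0.005)
  if (boundary)
    warning("cure fraction at a boundary for age group ", label)
  list(theta = theta, se = sqrt(pmax(diag(vc), 0)), vcov = vc,
       objective = best$objective, residuals = resid,
       boundary = boundary, n_points = length(rs))
}

cure_weights <- function(se) {
  pos <- is.finite(se) & se > 0
  if (!any(pos)) return(rep(1, length(se)))
  floor_se <- min(se[pos])
  1 / pmax(se, floor_se, na.rm = TRUE)^2
}

# Gauss-Newton covariance: vcov = sigma^2 (J' W J)^{-1}, sigma^2 the
# weighted residual mean square. Approximate; used for recovery checks.
cure_vcov <- function(theta, rs, w, t, y, y_ref) {
  eps <- 1e-5
  J <- vapply(seq_along(theta), function(k) {
    th1 <- theta; th1[k] <- th1[k] + eps
    th0 <- theta; th0[k] <- th0[k] - eps
    (cure_rs(th1, t, y, y_ref) - cure_rs(th0, t, y, y_ref)) / (2 * eps)
  }, numeric(length(rs)))
  r <- rs - cure_rs(theta, t, y, y_ref)
  p <- length(theta)
  dfree <- max(length(rs) - p, 1)
  sigma2 <- sum(w * r^2) / dfree
  H <- crossprod(J * sqrt(w))
  Hi <- tryCatch(solve(H), error = function(e)
    MASSlike_ginv(H))
  sigma2 * Hi
}

# tiny pseudo-inverse fallback for near-singular Gauss-Newton Hessians
MASSlike_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.cure_fit <- function(x, ...) {
  cat("mixture cure model (weighted least squares on tabulated net survival)\n")
  cat("  reference year:", x$y_ref, "\n")
  for (g in names(x$groups)) {
    f <- x$groups[[g]]
    cf <- expit(f$theta[["q"]])
    cat(sprintf(
      "  %s: cure %.3f at %d (logit slope %+.4f/y), lambda %.3f, gamma %.2f%s\n",
      g, cf, x$y_ref, f$theta[["s"]], exp(f$theta[["l"]]),
      exp(f$theta[["log_gamma"]]),
      if (f$boundary) " [boundary]" else ""))
  }
  invisible(x)
}

#' @export
coef.cure_fit <- function(object, ...) {
  do.call(rbind, lapply(object$groups, `[[`, "theta"))
}

#' Evaluate modelled net survival
#'
#' Evaluates the fitted mixture cure net survival `RS(d; g, year_dx)`.
#' For diagnosis years before the observation window the parameters are
#' frozen at their `obs_year_min` values (constant-trend backcast); after
#' the window the fitted linear trends continue.
#'
#' @param object A `cure_fit`.
#' @param d Duration(s) since diagnosis, years (nonnegative).
#' @param age_group Survival age-group label.
#' @param year_dx Diagnosis year(s).
#' @param ... Unused.
#' @return Net survival values (recycled to the common length of `d` and
#'   `year_dx`).
#' @export
predict.cure_fit <- function(object, d, age_group, year_dx, ...) {
  if (any(d < 0)) stop("duration d must be nonnegative")
  f <- object$groups[[age_group]]
  if (is.null(f)) stop("unknown age group: ", age_group)
  n <- max(length(d), length(year_dx))
  d <- rep_len(d, n); year_dx <- rep_len(year_dx, n)
  y_eff <- pmax(year_dx, object$obs_year_min)
  cure_rs(f$theta, d, y_eff, object$y_ref)
}

#' Net-survival surface evaluator
#'
#' Wraps a fitted cure model as a plain function
#' `RS(d, age_group, year_dx)`, total on `d >= 0` and any diagnosis year
#' (frozen before the observation window, trend continued after it).
#'
#' @param params A `cure_fit`.
#' @param config Unused; accepted for interface symmetry.
#' @return A function `(d, age_group, year_dx) -> net survival`.
#' @export
survival_surface <- function(params, config = NULL) {
  force(params)
  function(d, age_group, year_dx) predict(params, d, age_group, year_dx)
}

#' @export
plot.cure_fit <- function(x, table = NULL, age_group = NULL, ...) {
  g <- age_group %||% names(x$groups)[1]
  d <- seq(0, 25, by = 0.25)
  years <- c(x$obs_year_min, x$y_ref, x$obs_year_max)
  cols <- c("grey60", "grey35", "black")
  plot(NA, xlim = range(d), ylim = c(0, 1.05), xlab = "years since diagnosis",
       ylab = "net survival", main = paste("mixture cure fit,", g), ...)
  for (i in seq_along(years))
    graphics::lines(d, predict(x, d, g, years[i]), col = cols[i], lwd = 2)
  if (!is.null(table)) {
    sub <- table[table$age_group == g, ]
    graphics::points(sub$interval, sub$rs, pch = 1, cex = 0.6)
  }
  graphics::legend("bottomleft", legend = years, col = cols, lwd = 2,
                   title = "diagnosis year", bty = "n")
  invisible(x)
}

#' Serialise a cure fit to JSON
#'
#' @param fit A `cure_fit`.
#' @param path Output path.
#' @export
write_cure_fit <- function(fit, path) {
  out <- list(y_ref = fit$y_ref, obs_year_min = fit$obs_year_min,
              obs_year_max = fit$obs_year_max,
              groups = lapply(fit$groups, function(f)
                list(theta = as.list(f$theta), se = as.list(f$se),
                     boundary = f$boundary)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
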