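# Growth physiology: growth-rate fitting on exponential windows, OD-to-dry-
# weight conversion, specific exchange rates normalized to biomass, yields,
# and carbon-uptake partitioning.

#' Fit a specific growth rate on an exponential window
#'
#' Balanced exponential growth: mu is the slope of ln(OD) against time over
#' the user-specified window. A window whose log-linear fit has R^2 < 0.95 is
#' flagged (not rejected).
#'
#' @param od_series data.frame(time, od), od > 0
#' @param window c(t_start, t_end); default spans the whole series
#' @return a `growth_phenotype`: mu, se, r2, window, n, flag
#' @export
fit_growth <- function(od_series, window = range(od_series$time)) {
  d <- od_series[od_series$time >= window[1] & od_series$time <= window[2], ]
  if (nrow(d) < 3) stop("need at least 3 points in the growth window")
  if (any(d$od <= 0)) stop("OD values must be > 0")
  fit <- stats::lm(log(d$od) ~ d$time)
  mu <- unname(stats::coef(fit)[2])
  sm <- suppressWarnings(summary(fit))  # noiseless series fit perfectly
  se <- sm$coefficients[2, 2]
  r2 <- sm$r.squared
  structure(list(mu = mu, se = se, r2 = r2, window = window, n = nrow(d),
                 flag = is.na(r2) || r2 < 0.95,
                 od0 = exp(unname(stats::coef(fit)[1]))),
            class = "growth_phenotype")
}

#' @export
print.growth_phenotype <- function(x, ...) {
  cat(sprintf("mu = %.4f +/- %.4f h^-1 (R^2 %.3f, n = %d%s)\n",
              x$mu, x$se, x$r2, x$n, if (x$flag) ", FLAGGED" else ""))
  invisible(x)
}

#' Linear OD to cell-dry-weight conversion
#'
#' Ordinary least-squares line (intercept not forced through the origin);
#' flags fits with R^2 <= 0.750.
#'
#' @param pairs data.frame(od, cdw) with >= 3 rows; cdw in g/L
#' @return list(slope, intercept, r2, flag)
#' @export
od_to_cdw_fit <- function(pairs) {
  if (nrow(pairs) < 3) stop("need at least 3 OD/CDW pairs")
  fit <- stats::lm(cdw ~ od, data = pairs)
  r2 <- suppressWarnings(summary(fit))$r.squared
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2, flag = is.na(r2) || r2 <= 0.750)
}

#' Specific uptake / secretion rates from concentration-vs-biomass regression
#'
#' During balanced exponential growth, concentration changes linearly with
#' biomass; with slope s (mmol per g CDW per L) the specific rate is
#' q = mu * |s| (mmol gCDW^-1 h^-1). Rates are reported positive with a
#' `role` flag (uptake when concentration falls, secretion when it rises).
#'
#' @param conc_series data.frame(time, conc) on the exponential window
#' @param cdw_series data.frame(time, cdw) on the same times (g/L)
#' @param mu specific growth rate (h^-1)
#' @return list(q, role, slope, r2, yield) where `yield` (g CDW per mmol,
#'   uptake only) comes from the same regression
#' @export
exchange_rates <- function(conc_series, cdw_series, mu) {
  d <- merge(conc_series, cdw_series, by = "time")
  if (nrow(d) < 3) stop("need at least 3 common time points")
  if (max(d$cdw) <= min(d$cdw))
    stop("biomass is not increasing on the window")
  fit <- stats::lm(conc ~ cdw, data = d)
  s <- unname(stats::coef(fit)[2])
  r2 <- suppressWarnings(summary(fit))$r.squared
  role <- if (s < 0) "uptake" else if (s > 0) "secretion" else "none"
  list(q = mu * abs(s), role = role, slope = s, r2 = r2,
       yield = if (role == "uptake") 1 / abs(s) else NA_real_)
}

#' Partition total carbon uptake into biomass, secretion and other
#'
#' All rates are converted to carbon-mmol using the supplied carbon counts;
#' "other" is the residual (CO2 and unaccounted losses).
#'
#' @param q_uptake substrate uptake rate (mmol gCDW^-1 h^-1)
#' @param uptake_carbons substrate carbon number
#' @param secretion_rates named vector of secretion rates (mmol gCDW^-1 h^-1)
#' @param secretion_carbons named carbon counts matching `secretion_rates`
#' @param biomass_demand `precursor_demand` (carbon efflux into biomass)
#' @param precursor_carbons carbon counts (default [PRECURSOR_CARBONS])
#' @return named fractions c(biomass, secretion, other), summing to 1
#' @export
carbon_partition <- function(q_uptake, uptake_carbons,
                             secretion_rates = numeric(0),
                             secretion_carbons = numeric(0),
                             biomass_demand = NULL,
                             precursor_carbons = PRECURSOR_CARBONS) {
  cu <- q_uptake * uptake_carbons
  cs <- if (length(secretion_rates) > 0)
    sum(secretion_rates * secretion_carbons[names(secretion_rates)]) else 0
  cb <- if (!is.null(biomass_demand))
    sum(biomass_demand$rates * precursor_carbons[names(biomass_demand$rates)]) else 0
  if (cs + cb > cu + 1e-9)
    stop("infeasible partition: secreted + biomass carbon exceeds uptake carbon")
  c(biomass = cb / cu, secretion = cs / cu, other = 1 - (cb + cs) / cu)
}
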