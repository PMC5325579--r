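#' Classify an annual nitrogen rate
#'
#' Rates are grouped into none (0), low (0-100], mid (100-200) and high
#' (>= 200) kg N ha^-1 yr^-1.
#'
#' @param n_rate annual N rate (kg N ha^-1 yr^-1)
#' @return one of \code{"none"}, \code{"low"}, \code{"mid"}, \code{"high"}
#' @export
classify_n_level <- function(n_rate) {
  if (any(n_rate < 0)) stop("n_rate must be >= 0")
  vapply(n_rate, function(x) {
    if (x == 0) "none"
    else if (x <= 100) "low"
    else if (x < 200) "mid"
    else "high"
  }, character(1))
}

#' Classify an annual organic-matter addition rate
#'
#' Rates are grouped into none (0), mid (0-10] and high (> 10) t dry matter
#' ha^-1 yr^-1; the boundary rate of exactly 10 is assigned to mid.
#'
#' @param om_rate annual OM rate (t DM ha^-1 yr^-1)
#' @return one of \code{"none"}, \code{"mid"}, \code{"high"}
#' @export
classify_om_level <- function(om_rate) {
  if (any(om_rate < 0)) stop("om_rate must be >= 0")
  vapply(om_rate, function(x) {
    if (x == 0) "none" else if (x <= 10) "mid" else "high"
  }, character(1))
}

#' Effect parameters for the management multiplier
#'
#' Fertilization and amendment effects are parameterized on the log scale
#' (\code{ferteff = exp(lambda_fert)}, \code{omeff = exp(lambda_om)}) so the
#' exponentiated effects are positive by construction; a lambda of zero is
#' an effect of one (practice has no influence on decay). The tillage effect
#' is fixed, not fitted: either CENTURY's default 5.5 applied for the single
#' month in which tillage occurs, or the annualized equivalent 1.4 applied
#' over the 12 months following tillage.
#'
#' @param lambda_fert named vector over classes \code{low}, \code{mid},
#'   \code{high} (log scale)
#' @param lambda_om named vector over classes \code{mid}, \code{high}
#' @param clteff_mode \code{"annualized"} or \code{"century_default"}
#' @param clteff_value tillage multiplier; defaults to 1.4 (annualized) or
#'   5.5 (single month)
#' @return object of class \code{effect_parameters}
#' @export
effect_parameters <- function(lambda_fert = c(low = 0, mid = 0, high = 0),
                              lambda_om = c(mid = 0, high = 0),
                              clteff_mode = c("annualized",
                                              "century_default"),
                              clteff_value = NULL) {
  clteff_mode <- match.arg(clteff_mode)
  if (is.null(clteff_value))
    clteff_value <- if (clteff_mode == "annualized") 1.4 else 5.5
  structure(list(lambda_fert = lambda_fert, lambda_om = lambda_om,
                 clteff_mode = clteff_mode, clteff_value = clteff_value),
            class = "effect_parameters")
}

#' Monthly tillage-effect series from tillage events
#'
#' In \code{"century_default"} mode the multiplier equals the tillage value
#' (default 5.5) in each event month and 1 elsewhere; in \code{"annualized"}
#' mode it equals the annualized value (default 1.4) for the 12 months
#' starting at each event and 1 elsewhere. Overlapping windows take the
#' maximum and never compound.
#'
#' @param events data.frame with columns \code{year}, \code{month} (1-12),
#'   or NULL/empty for no tillage
#' @param mode \code{"annualized"} or \code{"century_default"}
#' @param n_months series length
#' @param start_year calendar year of month index 0
#' @param value multiplier; defaults by mode (1.4 / 5.5)
#' @return numeric vector of length \code{n_months}
#' @export
tillage_effect_series <- function(events, mode = c("annualized",
                                                   "century_default"),
                                  n_months, start_year = 1, value = NULL) {
  mode <- match.arg(mode)
  if (n_months < 1) stop("n_months must be >= 1")
  if (is.null(value)) value <- if (mode == "annualized") 1.4 else 5.5
  s <- rep(1, n_months)
  if (is.null(events) || NROW(events) == 0) return(s)
  idx <- (events$year - start_year) * 12 + events$month  # 1-based index
  for (i in idx) {
    if (i < 1 || i > n_months) next
    span <- if (mode == "annualized") i:min(i + 11, n_months) else i
    s[span] <- pmax(s[span], value)
  }
  s
}

#' Monthly management-multiplier series for a treatment
#'
#' Computes \code{mgmteff = clteff * ferteff * omeff} month by month.
#' Fertilization and amendment effects apply for all 12 months of each
#' application year (\code{exp(lambda)} of that year's rate class, 1 in
#' years without the practice); the tillage effect follows
#' \code{\link{tillage_effect_series}}.
#'
#' @param n_years number of simulated years
#' @param n_rate_by_year annual N rates, length \code{n_years} (recycled if
#'   scalar)
#' @param om_rate_by_year annual OM rates, likewise
#' @param tillage_events data.frame(year, month) of tillage events (years
#'   counted from \code{start_year}); or NULL
#' @param params an \code{effect_parameters}
#' @param start_year calendar year of month index 0
#' @return numeric vector of length \code{12 * n_years}
#' @examples
#' p <- effect_parameters(lambda_fert = c(low = 0, mid = 0,
#'                                        high = log(1.59)))
#' ev <- data.frame(year = 1, month = 1)
#' m <- management_series(1, 336, 0, ev, p)
#' m[1]  # 1.4 * 1.59 = 2.226
#' @export
management_series <- function(n_years, n_rate_by_year, om_rate_by_year = 0,
                              tillage_events = NULL,
                              params = effect_parameters(),
                              start_year = 1) {
  n_months <- 12L * n_years
  n_rate_by_year <- rep_len(n_rate_by_year, n_years)
  om_rate_by_year <- rep_len(om_rate_by_year, n_years)
  clt <- tillage_effect_series(tillage_events, params$clteff_mode,
                               n_months, start_year,
                               params$clteff_value)
  fert <- vapply(classify_n_level(n_rate_by_year), function(cl) {
    if (cl == "none") 1 else exp(params$lambda_fert[[cl]])
  }, numeric(1))
  om <- vapply(classify_om_level(om_rate_by_year), function(cl) {
    if (cl == "none") 1 else exp(params$lambda_om[[cl]])
  }, numeric(1))
  unname(clt * rep(fert, each = 12) * rep(om, each = 12))
}

#' Management multiplier for a single month
#'
#' @param month 1-based month index into the treatment's series
#' @inheritParams management_series
#' @return dimensionless multiplier (> 0)
#' @export
management_multiplier <- function(month, n_years, n_rate_by_year,
                                  om_rate_by_year = 0,
                                  tillage_events = NULL,
                                  params = effect_parameters(),
                                  start_year = 1) {
  management_series(n_years, n_rate_by_year, om_rate_by_year,
                    tillage_events, params, start_year)[month]
}
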