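#' Write a study dataset to a directory of delimited-text files
#'
#' Emits \code{sites.csv} (site_id, clay, sand, start_year, n_years,
#' initial_soc, prior_land_use), \code{treatments.csv} (site_id,
#' treatment_id, rotation, tillage, n_rate_kg_ha, om_rate_t_ha,
#' initial_soc), \code{defac.csv} (site_id, month_index, defac),
#' \code{yields.csv} (site_id, treatment_id, year, crop, yield_Mg_ha) and
#' \code{observations.csv} (site_id, treatment_id, year, soc_Mg_ha).
#'
#' @param study a \code{soc_study}
#' @param dir output directory (created if missing)
#' @return \code{dir}, invisibly
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sites <- do.call(rbind, lapply(study$sites, function(s)
    data.frame(site_id = s$site_id, clay = s$clay, sand = s$sand,
               start_year = s$start_year, n_years = s$n_years,
               initial_soc = s$initial_soc,
               prior_land_use = s$prior_land_use)))
  trts <- do.call(rbind, lapply(study$sites, function(s)
    do.call(rbind, lapply(s$treatments, function(tr)
      data.frame(site_id = s$site_id, treatment_id = tr$treatment_id,
                 rotation = tr$rotation, tillage = tr$tillage,
                 n_rate_kg_ha = tr$n_rate[1], om_rate_t_ha = tr$om_rate[1],
                 initial_soc = if (is.null(tr$initial_soc)) NA
                               else tr$initial_soc)))))
  defac <- do.call(rbind, lapply(study$sites, function(s)
    data.frame(site_id = s$site_id,
               month_index = seq_along(s$defac) - 1L, defac = s$defac)))
  yields <- do.call(rbind, lapply(study$sites, function(s)
    do.call(rbind, lapply(s$treatments, function(tr)
      if (is.null(tr$yields)) NULL
      else data.frame(site_id = s$site_id,
                      treatment_id = tr$treatment_id,
                      year = tr$yields$year, crop = tr$yields$crop,
                      yield_Mg_ha = tr$yields$yield)))))
  obs <- do.call(rbind, lapply(study$sites, function(s)
    do.call(rbind, lapply(s$treatments, function(tr)
      data.frame(site_id = s$site_id, treatment_id = tr$treatment_id,
                 year = tr$observations$year,
                 soc_Mg_ha = tr$observations$soc)))))
  write.csv(sites, file.path(dir, "sites.csv"), row.names = FALSE)
  write.csv(trts, file.path(dir, "treatments.csv"), row.names = FALSE)
  write.csv(defac, file.path(dir, "defac.csv"), row.names = FALSE)
  if (!is.null(yields))
    write.csv(yields, file.path(dir, "yields.csv"), row.names = FALSE)
  write.csv(obs, file.path(dir, "observations.csv"), row.names = FALSE)
  invisible(dir)
}

.read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("missing file: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop(basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "))
  d
}

#' Read a study dataset from a directory of delimited-text files
#'
#' Inverse of \code{\link{write_study}}. All structural invariants are
#' validated: numeric fields, defac series lengths, and the inclusion rule
#' that every treatment carries at least two dated SOC observations.
#'
#' @param dir directory containing the study files
#' @return a \code{soc_study}
#' @export
read_study <- function(dir) {
  sites_f <- file.path(dir, "sites.csv")
  if (!file.exists(sites_f)) stop("no sites found in ", dir)
  sites_d <- .read_csv_checked(sites_f,
                               c("site_id", "clay", "sand", "start_year",
                                 "n_years", "initial_soc"))
  if (nrow(sites_d) == 0) stop("no sites found in ", dir)
  trts_d <- .read_csv_checked(file.path(dir, "treatments.csv"),
                              c("site_id", "treatment_id", "rotation",
                                "tillage", "n_rate_kg_ha", "om_rate_t_ha"))
  defac_d <- .read_csv_checked(file.path(dir, "defac.csv"),
                               c("site_id", "month_index", "defac"))
  yields_f <- file.path(dir, "yields.csv")
  yields_d <- if (file.exists(yields_f))
    .read_csv_checked(yields_f, c("site_id", "treatment_id", "year",
                                  "crop", "yield_Mg_ha")) else NULL
  obs_d <- .read_csv_checked(file.path(dir, "observations.csv"),
                             c("site_id", "treatment_id", "year",
                               "soc_Mg_ha"))
  for (col in c("year", "soc_Mg_ha"))
    if (!is.numeric(obs_d[[col]]))
      stop("observations.csv: column ", col, " must be numeric")

  sites <- list()
  for (i in seq_len(nrow(sites_d))) {
    sd <- sites_d[i, ]
    dts <- defac_d[defac_d$site_id == sd$site_id, ]
    dts <- dts[order(dts$month_index), ]
    trs <- trts_d[trts_d$site_id == sd$site_id, ]
    trts <- list()
    for (j in seq_len(nrow(trs))) {
      tj <- trs[j, ]
      yl <- if (!is.null(yields_d)) {
        y <- yields_d[yields_d$site_id == sd$site_id &
                        yields_d$treatment_id == tj$treatment_id, ]
        if (nrow(y)) data.frame(year = y$year, crop = y$crop,
                                yield = y$yield_Mg_ha) else NULL
      } else NULL
      ob <- obs_d[obs_d$site_id == sd$site_id &
                    obs_d$treatment_id == tj$treatment_id, ]
      if (nrow(ob) < 2)
        stop("treatments.csv row for '", tj$treatment_id, "' at '",
             sd$site_id, "': fewer than two SOC observations; inverse ",
             "modeling requires at least two per treatment")
      trts[[j]] <- soc_treatment(
        tj$treatment_id, tj$rotation, tj$tillage,
        tj$n_rate_kg_ha, tj$om_rate_t_ha, yields = yl,
        observations = data.frame(year = ob$year, soc = ob$soc_Mg_ha),
        initial_soc = if (!is.null(tj$initial_soc) &&
                          !is.na(tj$initial_soc)) tj$initial_soc
                      else NULL)
    }
    sites[[i]] <- soc_site(sd$site_id, sd$clay, sd$sand, sd$start_year,
                           sd$n_years, sd$initial_soc, dts$defac, trts,
                           if ("prior_land_use" %in% names(sd))
                             sd$prior_land_use else NA_character_)
  }
  soc_study(sites)
}

#' Write a fit report: JSON summary plus residual table
#'
#' The JSON carries natural-scale estimates (exponentiated management
#' effects alongside their log-scale values), standard errors, the full
#' covariance matrix, test statistics and goodness of fit;
#' \code{residuals.csv} lists per-observation site, treatment, year,
#' observed, fitted and residual. Optional Monte-Carlo interval tables are
#' written as \code{intervals_*.csv}.
#'
#' @param fit a \code{soc_fit}
#' @param dir output directory
#' @param intervals optional named list of interval data.frames
#' @return \code{dir}, invisibly
#' @export
write_report <- function(fit, dir, intervals = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cov <- fit$covariance
  cov <- (cov + t(cov)) / 2  # enforce exact symmetry on output
  report <- list(
    parameters = fit$parameters[, c("name", "kind", "transformed",
                                    "estimate", "std_error", "null",
                                    "t", "p_value")],
    covariance = list(names = colnames(cov), matrix = unname(cov)),
    n_obs = fit$n_obs, n_par = fit$n_par, df = fit$df,
    ssr = fit$ssr, sigma2 = fit$sigma2, r_squared = fit$r_squared,
    convergence = fit$convergence)
  jsonlite::write_json(report, file.path(dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  resid_tab <- cbind(fit$meta,
                     fitted = fit$fitted, residual = fit$residuals)
  write.csv(resid_tab, file.path(dir, "residuals.csv"),
            row.names = FALSE)
  if (!is.null(intervals))
    for (nm in names(intervals))
      write.csv(intervals[[nm]],
                file.path(dir, paste0("intervals_", nm, ".csv")),
                row.names = FALSE)
  invisible(dir)
}

#' Read a fit report JSON back into a summary list
#'
#' @param path path to \code{fit.json}
#' @return list with parameter table and covariance matrix
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  cov <- as.matrix(rep$covariance$matrix)
  dimnames(cov) <- list(rep$covariance$names, rep$covariance$names)
  rep$covariance <- cov
  rep
}
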