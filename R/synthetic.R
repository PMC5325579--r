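#' Generate a seasonal monthly decomposition-factor series
#'
#' A clamped sinusoid with optional white noise:
#' \code{clamp(mean_level + amplitude * sin(2*pi*(m - phase)/12) + noise,
#' 0, 1)}. Emulates the seasonal soil temperature/moisture signal that a
#' full ecosystem model would provide.
#'
#' @param n_months series length
#' @param amplitude seasonal amplitude (default 0.25)
#' @param mean_level annual mean (default 0.35)
#' @param phase month offset of the seasonal peak
#' @param noise_sd white-noise standard deviation (default 0.03)
#' @param seed integer seed
#' @return numeric vector in \code{[0, 1]}
#' @export
generate_defac <- function(n_months, amplitude = 0.25, mean_level = 0.35,
                           phase = 4, noise_sd = 0.03, seed = 1) {
  set.seed(seed)
  m <- seq_len(n_months)
  x <- mean_level + amplitude * sin(2 * pi * (m - phase) / 12) +
    rnorm(n_months, 0, noise_sd)
  pmin(pmax(x, 0), 1)
}

#' True parameters for a synthetic study
#'
#' Ground truth used to generate data and score recovery. Defaults place
#' the fertilization effects in the range reported for long-term corn
#' systems (decay accelerated up to ~1.5-fold at high N rates).
#'
#' @param lambda_fert log fertilization effects by class
#' @param lambda_om log amendment effects by class
#' @param mm optional \code{mm_parameters}; when given the study is
#'   generated under Michaelis-Menten decay (tillage effect retained,
#'   fertilization/amendment effects ignored)
#' @param soc_cv observation noise CV on SOC (default 0.10)
#' @param yield_cv lognormal yield noise CV (default 0.10)
#' @param ymax,n_half maximum yields (Mg ha^-1) and N-response scale
#'   (kg N ha^-1) of the saturating yield model
#' @param n_base baseline soil N supply (kg N ha^-1)
#' @return object of class \code{soc_truth}
#' @export
truth_parameters <- function(lambda_fert = c(low = log(1.24),
                                             mid = log(1.37),
                                             high = log(1.5)),
                             lambda_om = c(mid = log(1.07),
                                           high = log(1.26)),
                             mm = NULL,
                             soc_cv = 0.10, yield_cv = 0.10,
                             ymax = c(corn = 11, soybean = 3.2,
                                      winter_wheat = 5.5),
                             n_half = 80, n_base = 60) {
  structure(list(lambda_fert = lambda_fert, lambda_om = lambda_om,
                 mm = mm, soc_cv = soc_cv, yield_cv = yield_cv,
                 ymax = ymax, n_half = n_half, n_base = n_base,
                 f_S = NULL),
            class = "soc_truth")
}

#' Sample multi-site experimental designs
#'
#' Draws site designs with the structure of US long-term corn-system
#' experiments: 15-35 year records, corn-based rotations, N rates from 0 to
#' 336 kg N ha^-1, organic amendments at 4.5-18 t DM ha^-1 on a subset of
#' sites, conventional and no-till regimes, sparse SOC observation
#' schedules, and a prior-land-use class that sets the true initial
#' slow-pool fraction (grassland sites start with more slow-pool C than
#' long-cultivated ones).
#'
#' Every design includes an unfertilized control, and the menu guarantees
#' that low, mid and high N classes each occur across sites so all effect
#' parameters are identifiable.
#'
#' @param n_sites number of sites (default 8)
#' @param seed integer seed
#' @param n_obs_interval years between SOC samplings (range, sampled per
#'   site)
#' @return list of design lists consumed by \code{\link{generate_study}}
#' @export
synthetic_designs <- function(n_sites = 8, seed = 1,
                              n_obs_interval = c(3, 6)) {
  set.seed(seed)
  menu <- list(list(n = 84, till = "CT"), list(n = 164, till = "CT"),
               list(n = 336, till = "CT"), list(n = 250, till = "NT"),
               list(n = 84, till = "CT"), list(n = 164, till = "CT"),
               list(n = 224, till = "CT"), list(n = 150, till = "CT"))
  land_use <- rep(c("grassland", "recent_cultivation",
                    "long_cultivation"), length.out = n_sites)
  om_sites <- if (n_sites >= 4) c(2L, 4L) else 1L
  designs <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    lu <- land_use[i]
    fs <- switch(lu,
                 grassland = runif(1, 0.60, 0.80),
                 recent_cultivation = runif(1, 0.45, 0.60),
                 long_cultivation = runif(1, 0.30, 0.45))
    soc0 <- switch(lu,
                   grassland = runif(1, 45, 65),
                   recent_cultivation = runif(1, 35, 50),
                   long_cultivation = runif(1, 25, 40))
    n_years <- sample(15:35, 1)
    rot <- sample(c("CC", "CC", "CS", "CSW"), 1)
    trts <- list(list(id = "T0", rotation = rot, tillage = "CT",
                      n_rate = 0, om_rate = 0))
    extra <- menu[[((i - 1L) %% length(menu)) + 1L]]
    trts[[2]] <- list(id = "TN", rotation = rot, tillage = extra$till,
                      n_rate = extra$n, om_rate = 0)
    # guarantee a high-N treatment at every other site
    if (i %% 2 == 1)
      trts[[length(trts) + 1]] <- list(id = "TH", rotation = rot,
                                       tillage = "CT", n_rate = 336,
                                       om_rate = 0)
    if (i %in% om_sites)
      trts[[length(trts) + 1]] <- list(id = "TOM", rotation = rot,
                                       tillage = "CT", n_rate = 0,
                                       om_rate = if (i == om_sites[1]) 4.5
                                                 else 18)
    interval <- sample(seq(n_obs_interval[1], n_obs_interval[2]), 1)
    obs_years <- unique(c(seq(0, n_years, by = interval), n_years))
    designs[[i]] <- list(site_id = sprintf("site%02d", i),
                         clay = runif(1, 0.10, 0.40),
                         sand = runif(1, 0.07, 0.60),
                         prior_land_use = lu, f_S = fs,
                         initial_soc = soc0,
                         start_year = 1970, n_years = n_years,
                         obs_years = obs_years,
                         treatments = trts)
  }
  designs
}

#' Generate annual yields from a saturating nitrogen response
#'
#' \code{Y = ymax * (1 - exp(-(N + n_base)/n_half)) * eps} with lognormal
#' noise \code{eps} (mean 1, coefficient of variation \code{yield_cv});
#' soybean yields do not respond to fertilizer N.
#'
#' @param crops character vector of crop ids per year
#' @param n_rate annual N rate (scalar or per-year)
#' @param truth a \code{soc_truth}
#' @param seed integer seed
#' @return data.frame(year_offset, crop, yield)
#' @export
generate_yields <- function(crops, n_rate, truth = truth_parameters(),
                            seed = 1) {
  set.seed(seed)
  ny <- length(crops)
  n_rate <- rep_len(n_rate, ny)
  n_eff <- ifelse(crops == "soybean", 1e6, n_rate + truth$n_base)
  mu <- truth$ymax[crops] * (1 - exp(-n_eff / truth$n_half))
  cv <- truth$yield_cv
  eps <- if (cv > 0) {
    sdl <- sqrt(log(1 + cv^2))
    exp(rnorm(ny, -sdl^2 / 2, sdl))
  } else rep(1, ny)
  data.frame(year_offset = seq_len(ny) - 1L, crop = crops,
             yield = unname(mu * eps))
}

#' Generate a complete synthetic multi-site study
#'
#' Runs the forward model under the true parameters for every treatment and
#' emits sparse, noisy SOC observations (normal noise with standard
#' deviation \code{soc_cv} times the simulated value, truncated positive).
#' Returns the study together with the truth record needed to score
#' parameter recovery and interval coverage.
#'
#' @param designs from \code{\link{synthetic_designs}}, or a custom list
#' @param truth a \code{soc_truth}
#' @param seed integer seed governing all noise
#' @return list with \code{study} (a \code{soc_study}) and \code{truth}
#'   (truth parameters, per-site true f_S, and the noiseless SOC value
#'   behind every observation)
#' @export
generate_study <- function(designs, truth = truth_parameters(), seed = 1) {
  set.seed(seed)
  params <- effect_parameters(lambda_fert = truth$lambda_fert,
                              lambda_om = truth$lambda_om)
  sites <- list()
  truth_fs <- setNames(vapply(designs, `[[`, 0, "f_S"),
                       vapply(designs, `[[`, "", "site_id"))
  soc_true_rows <- list()
  for (d in designs) {
    defac <- generate_defac(12 * d$n_years,
                            seed = seed + 17L * match(d$site_id,
                                                      names(truth_fs)))
    trts <- list()
    for (tr in d$treatments) {
      crops <- rotation_crops(tr$rotation, d$n_years)
      yl <- generate_yields(crops, tr$n_rate, truth,
                            seed = seed + 1000L +
                              37L * length(soc_true_rows) +
                              7L * match(tr$id, vapply(d$treatments,
                                                       `[[`, "", "id")))
      yields <- data.frame(year = d$start_year + yl$year_offset,
                           crop = yl$crop, yield = yl$yield)
      trt_obj <- soc_treatment(tr$id, tr$rotation, tr$tillage,
                               tr$n_rate, tr$om_rate, yields = yields)
      site_tmp <- soc_site(d$site_id, d$clay, d$sand, d$start_year,
                           d$n_years, d$initial_soc, defac,
                           treatments = list(trt_obj),
                           prior_land_use = d$prior_land_use)
      fc <- build_treatment_forcing(site_tmp, trt_obj)
      kin <- century_kinetics(clay = d$clay, sand = d$sand)
      mult <- fc$clteff
      if (is.null(truth$mm)) {
        # no tillage events passed, so this contributes ferteff*omeff only
        mult <- mult * management_series(d$n_years, tr$n_rate, tr$om_rate,
                                         NULL, params)
      }
      traj <- simulate_pools(initial_condition(d$initial_soc, d$f_S),
                             list(defac = defac, mgmteff = mult,
                                  inputs = fc$inputs),
                             kin, mm = truth$mm)
      obs_idx <- d$obs_years * 12 + 1
      soc_true <- traj$total_soc[obs_idx]
      soc_obs <- soc_true
      if (truth$soc_cv > 0) {
        soc_obs <- rnorm(length(soc_true), soc_true,
                         truth$soc_cv * soc_true)
        while (any(soc_obs <= 0)) {
          bad <- soc_obs <= 0
          soc_obs[bad] <- rnorm(sum(bad), soc_true[bad],
                                truth$soc_cv * soc_true[bad])
        }
      }
      trt_obj$observations <- data.frame(
        year = d$start_year + d$obs_years, soc = soc_obs)
      trts[[tr$id]] <- trt_obj
      soc_true_rows[[length(soc_true_rows) + 1L]] <- data.frame(
        site = d$site_id, treatment = tr$id,
        year = d$start_year + d$obs_years, soc_true = soc_true)
    }
    sites[[d$site_id]] <- soc_site(d$site_id, d$clay, d$sand,
                                   d$start_year, d$n_years,
                                   d$initial_soc, defac, trts,
                                   d$prior_land_use)
  }
  truth$f_S <- truth_fs
  list(study = soc_study(sites), truth = truth,
       soc_true = do.call(rbind, soc_true_rows))
}
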