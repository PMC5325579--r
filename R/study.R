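#' Define a treatment within a site
#'
#' @param treatment_id identifier, unique within the site
#' @param rotation rotation code: \code{"CC"} (continuous corn), \code{"CS"},
#'   \code{"SC"} (corn-soybean phases) or \code{"CSW"}
#'   (corn-soybean-wheat)
#' @param tillage \code{"CT"} or \code{"NT"}
#' @param n_rate annual N rate (kg N ha^-1 yr^-1), scalar or per-year vector
#' @param om_rate annual organic-matter rate (t DM ha^-1 yr^-1)
#' @param yields data.frame with columns \code{year}, \code{crop},
#'   \code{yield} (Mg ha^-1 at field moisture)
#' @param observations data.frame with columns \code{year}, \code{soc}
#'   (Mg C ha^-1, 0-20 cm)
#' @param initial_soc optional treatment-specific initial SOC overriding the
#'   site value
#' @param f_mix optional mixing-fraction override (else by tillage regime)
#' @return object of class \code{soc_treatment}
#' @export
soc_treatment <- function(treatment_id, rotation = "CC", tillage = "CT",
                          n_rate = 0, om_rate = 0,
                          yields = NULL, observations = NULL,
                          initial_soc = NULL, f_mix = NULL) {
  if (any(n_rate < 0) || any(om_rate < 0)) stop("rates must be >= 0")
  structure(list(treatment_id = treatment_id, rotation = rotation,
                 tillage = tillage, n_rate = n_rate, om_rate = om_rate,
                 yields = yields, observations = observations,
                 initial_soc = initial_soc, f_mix = f_mix),
            class = "soc_treatment")
}

#' Define a site with its forcings and treatments
#'
#' @param site_id identifier
#' @param clay,sand soil texture fractions
#' @param start_year first simulated calendar year
#' @param n_years simulation span (years)
#' @param initial_soc SOC stock at \code{start_year} (Mg C ha^-1)
#' @param defac monthly abiotic decomposition factor, length
#'   \code{12 * n_years}
#' @param treatments list of \code{soc_treatment}
#' @param prior_land_use optional label (e.g. \code{"grassland"})
#' @return object of class \code{soc_site}
#' @export
soc_site <- function(site_id, clay, sand, start_year, n_years,
                     initial_soc, defac, treatments,
                     prior_land_use = NA_character_) {
  if (length(defac) != 12 * n_years)
    stop("defac must have length 12 * n_years")
  if (any(defac < 0)) stop("defac must be >= 0")
  names(treatments) <- vapply(treatments, `[[`, "", "treatment_id")
  structure(list(site_id = site_id, clay = clay, sand = sand,
                 start_year = start_year, n_years = n_years,
                 initial_soc = initial_soc, defac = defac,
                 treatments = treatments,
                 prior_land_use = prior_land_use),
            class = "soc_site")
}

#' Assemble a multi-site study dataset
#'
#' Validates the study against the inclusion rules used for inverse
#' modeling: every treatment must carry at least two dated SOC observations,
#' all of them within the simulated span.
#'
#' @param sites list of \code{soc_site}
#' @return object of class \code{soc_study}
#' @export
soc_study <- function(sites) {
  names(sites) <- vapply(sites, `[[`, "", "site_id")
  for (s in sites) {
    for (tr in s$treatments) {
      obs <- tr$observations
      if (is.null(obs) || nrow(obs) < 2)
        stop("treatment '", tr$treatment_id, "' at site '", s$site_id,
             "' has fewer than two SOC observations; at least two dated ",
             "observations are required for inverse modeling")
      if (any(obs$year < s$start_year |
              obs$year > s$start_year + s$n_years))
        stop("observation year outside the simulated span at site '",
             s$site_id, "'")
    }
  }
  structure(list(sites = sites), class = "soc_study")
}

#' @export
print.soc_study <- function(x, ...) {
  nt <- sum(vapply(x$sites, function(s) length(s$treatments), 0L))
  no <- sum(vapply(x$sites, function(s)
    sum(vapply(s$treatments, function(tr) nrow(tr$observations), 0L)), 0L))
  cat("SOC study:", length(x$sites), "sites,", nt, "treatments,",
      no, "SOC observations\n")
  invisible(x)
}

#' Rotation crop sequence
#' @param rotation rotation code
#' @param n_years length of sequence
#' @return character vector of crop ids per year
#' @export
rotation_crops <- function(rotation, n_years) {
  cycle <- switch(rotation,
                  CC = "corn",
                  CS = c("corn", "soybean"),
                  SC = c("soybean", "corn"),
                  CSW = c("corn", "soybean", "winter_wheat"),
                  stop("unknown rotation: ", rotation))
  rep_len(cycle, n_years)
}

# Precompute everything about one treatment that does not depend on fitted
# parameters: litter-input matrix, clteff series, annual N/OM classes, and
# observation row indices into the trajectory.
build_treatment_forcing <- function(site, trt,
                                    harvest_month = 10,
                                    tillage_month = 4,
                                    om_month = 4,
                                    om_metabolic_fraction = 0.6,
                                    om_c_conc = 0.450,
                                    clteff_mode = "annualized") {
  ny <- site$n_years
  n_months <- 12L * ny
  inputs <- matrix(0, n_months, 8, dimnames = list(NULL, POOLS))
  till <- tillage_context(trt$tillage, trt$f_mix)

  if (!is.null(trt$yields)) {
    for (r in seq_len(nrow(trt$yields))) {
      yr <- trt$yields$year[r] - site$start_year + 1L
      if (yr < 1 || yr > ny) next
      crop <- crop_indices(trt$yields$crop[r])
      Y <- trt$yields$yield[r]
      ag_total <- aboveground_litter_c(Y, crop,
                                       tillage_context("CT", f_mix = 1))
      bg <- belowground_litter_c(Y, crop)
      m <- (yr - 1L) * 12L + harvest_month
      soil_ag <- partition_litter(ag_total * till$f_mix,
                                  crop$lignin_ag, crop$n_ag)
      surf_ag <- partition_litter(ag_total * (1 - till$f_mix),
                                  crop$lignin_ag, crop$n_ag)
      soil_bg <- partition_litter(bg, crop$lignin_bg, crop$n_bg)
      inputs[m, "soil_metabolic"] <- inputs[m, "soil_metabolic"] +
        soil_ag["metabolic"] + soil_bg["metabolic"]
      inputs[m, "soil_structural"] <- inputs[m, "soil_structural"] +
        soil_ag["structural"] + soil_bg["structural"]
      inputs[m, "surface_metabolic"] <- inputs[m, "surface_metabolic"] +
        surf_ag["metabolic"]
      inputs[m, "surface_structural"] <- inputs[m, "surface_structural"] +
        surf_ag["structural"]
    }
  }

  om_rate <- rep_len(trt$om_rate, ny)
  for (yr in which(om_rate > 0)) {
    cm <- amendment_c(om_rate[yr], om_c_conc)
    m <- (yr - 1L) * 12L + om_month
    inputs[m, "soil_metabolic"] <- inputs[m, "soil_metabolic"] +
      cm * om_metabolic_fraction
    inputs[m, "soil_structural"] <- inputs[m, "soil_structural"] +
      cm * (1 - om_metabolic_fraction)
  }

  events <- if (till$regime == "CT")
    data.frame(year = site$start_year + seq_len(ny) - 1L,
               month = tillage_month)
  else NULL
  clt <- tillage_effect_series(events, clteff_mode, n_months,
                               site$start_year)

  obs <- trt$observations
  obs_idx <- if (!is.null(obs)) (obs$year - site$start_year) * 12L + 1L
  list(n_months = n_months,
       defac = site$defac,
       inputs = inputs,
       clteff = clt,
       fert_class = classify_n_level(rep_len(trt$n_rate, ny)),
       om_class = classify_om_level(om_rate),
       obs_idx = obs_idx,
       obs = if (!is.null(obs)) obs$soc,
       obs_year = if (!is.null(obs)) obs$year,
       initial_soc = if (!is.null(trt$initial_soc)) trt$initial_soc
                     else site$initial_soc)
}
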