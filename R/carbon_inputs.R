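#' Agronomic indices used to convert yields to residue carbon
#'
#' Literature-derived harvest index (HI), root-to-shoot ratio (RSR), the
#' fraction of root mass in the 0-20 cm layer (RD), grain moisture content
#' (percent) and carbon concentrations of above- and belowground residue
#' (kg C per kg dry matter), plus default residue quality (lignin and N
#' fractions) used to split litter into metabolic and structural pools.
#'
#' @param crop_id one of \code{"corn"}, \code{"soybean"},
#'   \code{"winter_wheat"}
#' @param ... overrides for any index field
#' @return object of class \code{crop_indices}
#' @export
crop_indices <- function(crop_id = c("corn", "soybean", "winter_wheat"),
                         ...) {
  crop_id <- match.arg(crop_id)
  defaults <- list(
    corn = list(HI = 0.53, RSR = 0.55, RD = 0.80, theta = 15,
                c_ag = 0.437, c_bg = 0.343,
                lignin_ag = 0.073, n_ag = 0.0066,
                lignin_bg = 0.110, n_bg = 0.0070),
    soybean = list(HI = 0.46, RSR = 0.56, RD = 0.80, theta = 13,
                   c_ag = 0.454, c_bg = 0.467,
                   lignin_ag = 0.100, n_ag = 0.0150,
                   lignin_bg = 0.120, n_bg = 0.0120),
    winter_wheat = list(HI = 0.45, RSR = 0.62, RD = 0.90, theta = 14,
                        c_ag = 0.370, c_bg = 0.296,
                        lignin_ag = 0.080, n_ag = 0.0050,
                        lignin_bg = 0.100, n_bg = 0.0060))
  x <- defaults[[crop_id]]
  ov <- list(...)
  x[names(ov)] <- ov
  x$crop_id <- crop_id
  with(x, {
    if (HI <= 0 || HI >= 1) stop("HI must be in (0, 1)")
    if (RSR <= 0) stop("RSR must be > 0")
    if (RD <= 0 || RD > 1) stop("RD must be in (0, 1]")
    if (theta < 0 || theta >= 100) stop("theta must be in [0, 100)")
    if (c_ag <= 0 || c_ag >= 1 || c_bg <= 0 || c_bg >= 1)
      stop("carbon concentrations must be in (0, 1)")
  })
  structure(x, class = "crop_indices")
}

#' Tillage context: regime and surface-mixing fraction
#'
#' Under conventional tillage (CT) most aboveground residue is incorporated
#' into the soil (default mixing fraction 0.95); under no-till (NT) almost
#' none is (default 0.05). Alternative factors (e.g. 0.85/0.15 for
#' chisel-plow systems with earthworm mixing) can be supplied.
#'
#' @param regime \code{"CT"} or \code{"NT"}
#' @param f_mix fraction of aboveground litter transferred to the soil;
#'   defaults to 0.95 (CT) or 0.05 (NT)
#' @return object of class \code{tillage_context}
#' @export
tillage_context <- function(regime = c("CT", "NT"), f_mix = NULL) {
  regime <- match.arg(regime)
  if (is.null(f_mix)) f_mix <- if (regime == "CT") 0.95 else 0.05
  if (f_mix < 0 || f_mix > 1) stop("f_mix must be in [0, 1]")
  structure(list(regime = regime, f_mix = f_mix),
            class = "tillage_context")
}

#' Aboveground residue carbon input to soil from grain yield
#'
#' \code{Y * (100 - theta)/100 * c_ag * (1 - HI)/HI * f_mix}: field-moisture
#' yield converted to dry grain, scaled to non-grain aboveground biomass by
#' the harvest index, converted to carbon and reduced to the tillage-mixed
#' soil share. The moisture term is applied as a dry-matter fraction.
#'
#' @param yield_Y grain yield at field moisture (Mg ha^-1)
#' @param crop a \code{crop_indices}
#' @param tillage a \code{tillage_context}
#' @return Mg C ha^-1
#' @examples
#' aboveground_litter_c(10, crop_indices("corn"), tillage_context("CT"))
#' @export
aboveground_litter_c <- function(yield_Y, crop, tillage) {
  if (yield_Y < 0) stop("yield must be >= 0")
  if (crop$HI == 0) stop("harvest index must be nonzero")
  yield_Y * (100 - crop$theta) / 100 * crop$c_ag *
    (1 - crop$HI) / crop$HI * tillage$f_mix
}

#' Belowground residue carbon input from grain yield
#'
#' \code{Y * (100 - theta)/100 * c_bg * RSR/HI * RD}: root production
#' inferred from aboveground production via the root-to-shoot ratio,
#' truncated to the sampled 0-20 cm depth.
#'
#' @inheritParams aboveground_litter_c
#' @return Mg C ha^-1
#' @export
belowground_litter_c <- function(yield_Y, crop) {
  if (yield_Y < 0) stop("yield must be >= 0")
  if (crop$HI == 0) stop("harvest index must be nonzero")
  yield_Y * (100 - crop$theta) / 100 * crop$c_bg *
    crop$RSR / crop$HI * crop$RD
}

#' Carbon input from an organic-matter amendment
#'
#' Amendments (e.g. manure) are assumed fully incorporated regardless of
#' tillage regime.
#'
#' @param om_rate amendment rate (t dry matter ha^-1)
#' @param c_conc carbon concentration (kg C per kg dry matter); default is
#'   the manure value 0.450
#' @return Mg C ha^-1
#' @export
amendment_c <- function(om_rate, c_conc = 0.450) {
  if (om_rate < 0) stop("om_rate must be >= 0")
  om_rate * c_conc
}

#' Spread annual carbon inputs over 12 months
#'
#' @param annual_ag,annual_bg annual above-/belowground inputs (Mg C ha^-1)
#' @param schedule either \code{"harvest"} (single pulse in
#'   \code{harvest_month}), \code{"uniform"}, or a 12-vector of weights
#'   summing to 1
#' @param harvest_month month (1-12) receiving the pulse under
#'   \code{"harvest"}
#' @return 12 x 2 matrix with columns \code{ag}, \code{bg}; each column
#'   sums exactly to its annual total
#' @export
annual_to_monthly_inputs <- function(annual_ag, annual_bg,
                                     schedule = "harvest",
                                     harvest_month = 10) {
  if (annual_ag < 0 || annual_bg < 0) stop("inputs must be >= 0")
  w <- if (identical(schedule, "harvest")) {
    v <- numeric(12); v[harvest_month] <- 1; v
  } else if (identical(schedule, "uniform")) {
    rep(1 / 12, 12)
  } else {
    as.numeric(schedule)
  }
  if (length(w) != 12 || abs(sum(w) - 1) > 1e-10)
    stop("schedule weights must be 12 values summing to 1")
  cbind(ag = w * annual_ag, bg = w * annual_bg)
}
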