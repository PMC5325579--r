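#' Kinetics configuration for the eight-pool SOC model
#'
#' Builds the decay-rate and carbon-flow parameterization of the pool
#' network: maximum annual decay coefficients, inter-pool flow fractions,
#' respired (CO2) fractions, and the texture and lignin rate modifiers.
#' Defaults follow the published CENTURY agroecosystem parameterization;
#' every value can be overridden.
#'
#' The eight pools are surface and soil structural and metabolic litter, the
#' surface microbial pool, and the active, slow and passive soil organic
#' matter pools. Texture enters twice: the respired fraction of active-pool
#' decomposition is \code{0.17 + 0.68*sand} and the active decay rate is
#' scaled by \code{1 - 0.75*(clay + silt)}. Structural litter decay is slowed
#' by lignin through \code{exp(-lignin_sensitivity * lignin_structural)}, and
#' the lignin share of decomposed structural C is routed to the slow pool.
#'
#' @param clay clay mass fraction of the soil (0-1)
#' @param sand sand mass fraction of the soil (0-1)
#' @param k0 named vector of maximum decay coefficients (yr^-1), one per pool
#' @param lignin_structural lignin fraction of structural litter (0-1)
#' @param lignin_sensitivity exponential sensitivity of structural decay to
#'   lignin content
#' @return an object of class \code{soc_kinetics}: list with \code{k0},
#'   \code{kbase} (per-month base rates including modifiers), \code{flow}
#'   (8 x 8 flow-fraction matrix), \code{co2} (respired fraction per pool),
#'   \code{clay}, \code{sand}
#' @examples
#' kin <- century_kinetics(clay = 0.24, sand = 0.09)
#' rowSums(kin$flow) + kin$co2  # each source pool's fractions sum to 1
#' @export
century_kinetics <- function(clay = 0.2, sand = 0.3,
                             k0 = c(surface_structural = 3.9,
                                    surface_metabolic = 14.8,
                                    soil_structural = 4.9,
                                    soil_metabolic = 18.5,
                                    surface_microbe = 6.0,
                                    active = 7.3,
                                    slow = 0.2,
                                    passive = 0.0045),
                             lignin_structural = 0.25,
                             lignin_sensitivity = 3) {
  if (clay < 0 || sand < 0 || clay + sand > 1)
    stop("texture fractions must be non-negative and sum to at most 1")
  if (any(k0 < 0)) stop("all k0 must be >= 0")
  k0 <- k0[POOLS]
  if (anyNA(k0)) stop("k0 must name all eight pools")
  L <- lignin_structural
  if (L < 0 || L > 1) stop("lignin_structural must be in [0, 1]")
  silt_clay <- 1 - sand

  flow <- matrix(0, 8, 8, dimnames = list(POOLS, POOLS))
  co2 <- setNames(numeric(8), POOLS)

  # Structural litter: lignin share to slow (30% respired), the rest to the
  # microbial/active chain (45% respired at the surface, 55% in soil).
  flow["surface_structural", "slow"] <- 0.7 * L
  flow["surface_structural", "surface_microbe"] <- 0.55 * (1 - L)
  co2["surface_structural"] <- 0.3 * L + 0.45 * (1 - L)
  flow["soil_structural", "slow"] <- 0.7 * L
  flow["soil_structural", "active"] <- 0.45 * (1 - L)
  co2["soil_structural"] <- 0.3 * L + 0.55 * (1 - L)

  flow["surface_metabolic", "surface_microbe"] <- 0.45
  co2["surface_metabolic"] <- 0.55
  flow["soil_metabolic", "active"] <- 0.45
  co2["soil_metabolic"] <- 0.55

  flow["surface_microbe", "slow"] <- 0.40
  co2["surface_microbe"] <- 0.60

  co2["active"] <- 0.17 + 0.68 * sand
  flow["active", "passive"] <- 0.003 + 0.032 * clay
  flow["active", "slow"] <- 1 - co2["active"] - flow["active", "passive"]

  co2["slow"] <- 0.55
  flow["slow", "passive"] <- 0.003 + 0.009 * clay
  flow["slow", "active"] <- 1 - co2["slow"] - flow["slow", "passive"]

  co2["passive"] <- 0.55
  flow["passive", "active"] <- 0.45

  stopifnot(all(abs(rowSums(flow) + co2 - 1) < 1e-10))

  texture_mod <- setNames(rep(1, 8), POOLS)
  texture_mod["active"] <- 1 - 0.75 * silt_clay
  lignin_mod <- setNames(rep(1, 8), POOLS)
  lignin_mod[c("surface_structural", "soil_structural")] <-
    exp(-lignin_sensitivity * L)

  structure(list(k0 = k0,
                 kbase = k0 / 12 * texture_mod * lignin_mod,
                 flow = flow, co2 = co2,
                 clay = clay, sand = sand,
                 lignin_structural = L,
                 lignin_sensitivity = lignin_sensitivity),
            class = "soc_kinetics")
}

#' Monthly decay-rate coefficient for one pool
#'
#' Composes the per-month rate \code{k* = (k0/12) * defac * texture *
#' lignin * m}, where the management multiplier \code{m} applies only to the
#' active and slow pools (all other pools use \code{m = 1}).
#'
#' @param pool_id one of the eight pool names
#' @param kinetics a \code{soc_kinetics} object
#' @param forcing a \code{month_forcing} (or any list with \code{defac} and
#'   \code{mgmteff})
#' @return rate coefficient (mo^-1)
#' @examples
#' kin <- century_kinetics(clay = 0, sand = 1)  # texture modifier = 1
#' f <- month_forcing(defac = 0.5)
#' decay_rate_coefficient("active", kin, f)  # 7.3/12 * 0.5
#' @export
decay_rate_coefficient <- function(pool_id, kinetics, forcing) {
  if (!pool_id %in% POOLS)
    stop("unknown pool_id: ", pool_id)
  m <- if (pool_id %in% c("active", "slow")) forcing$mgmteff else 1
  unname(kinetics$kbase[pool_id] * forcing$defac * m)
}

#' Split litter carbon into metabolic and structural fractions
#'
#' The metabolic share follows the lignin-to-nitrogen ratio rule
#' \code{F_met = 0.85 - 0.018 * (L/N)}, clamped to \code{[floor, 1]}
#' (default floor 0.20); the structural share is the remainder, so the two
#' always sum exactly to the input mass.
#'
#' @param c_mass litter carbon (Mg C ha^-1)
#' @param lignin_fraction lignin mass fraction of the litter (0-1]
#' @param n_fraction nitrogen mass fraction of the litter (0-1]
#' @param floor lower clamp on the metabolic fraction
#' @return named vector \code{c(metabolic=, structural=)}
#' @export
partition_litter <- function(c_mass, lignin_fraction, n_fraction,
                             floor = 0.20) {
  if (c_mass < 0) stop("c_mass must be >= 0")
  if (n_fraction <= 0) stop("n_fraction must be > 0 (L/N ratio undefined)")
  if (lignin_fraction < 0 || lignin_fraction > 1)
    stop("lignin_fraction must be in [0, 1]")
  fmet <- min(max(0.85 - 0.018 * lignin_fraction / n_fraction, floor), 1)
  c(metabolic = fmet * c_mass, structural = (1 - fmet) * c_mass)
}

#' @export
print.soc_kinetics <- function(x, ...) {
  cat("SOC pool kinetics (clay", x$clay, ", sand", x$sand, ")\n")
  cat("k0 (yr^-1):\n")
  print(x$k0)
  invisible(x)
}
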