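#' Michaelis-Menten decay parameters
#'
#' Parameters of the substrate-dependent alternative to the management
#' multiplier: active- and slow-pool decay is scaled by
#' \code{vmax * C_MR / (km + C_MR)}, where \code{C_MR} is the soil metabolic
#' litter mass (the fresh, microbially available substrate) at month start.
#'
#' @param vmax maximum activity multiplier at saturating substrate (> 0)
#' @param km half-saturation constant (Mg C ha^-1, > 0)
#' @return object of class \code{mm_parameters}
#' @export
mm_parameters <- function(vmax, km) {
  if (vmax <= 0) stop("vmax must be > 0")
  if (km <= 0) stop("km must be > 0")
  structure(list(vmax = vmax, km = km), class = "mm_parameters")
}

#' Michaelis-Menten activity multiplier
#'
#' \code{vmax * c_mr / (km + c_mr)}: zero without substrate, \code{vmax/2}
#' at \code{c_mr = km}, saturating at \code{vmax}.
#'
#' @param c_mr soil metabolic litter mass (Mg C ha^-1, >= 0)
#' @param params an \code{mm_parameters}
#' @return dimensionless multiplier in \code{[0, vmax)}
#' @examples
#' mm_activity(0.5, mm_parameters(vmax = 2, km = 0.5))  # 1
#' @export
mm_activity <- function(c_mr, params) {
  if (any(c_mr < 0)) stop("c_mr must be >= 0")
  params$vmax * c_mr / (params$km + c_mr)
}
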