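#' Initial condition: total SOC and its pool fractions
#'
#' Total 0-20 cm SOC and the fractions assigned to the active, slow and
#' passive pools at simulation start. By convention the active fraction is
#' small and fixed (default 0.02) and the passive fraction is set by
#' difference so that the three sum to unity.
#'
#' @param total_soc total SOC stock (Mg C ha^-1)
#' @param f_S initial slow-pool fraction
#' @param f_A initial active-pool fraction (default 0.02)
#' @param f_P initial passive-pool fraction; default \code{1 - f_A - f_S}
#' @return object of class \code{soc_initial}
#' @export
initial_condition <- function(total_soc, f_S, f_A = 0.02, f_P = NULL) {
  if (is.null(f_P)) f_P <- 1 - f_A - f_S
  fr <- c(f_A = f_A, f_S = f_S, f_P = f_P)
  if (any(fr < -1e-10) || any(fr > 1 + 1e-10))
    stop("pool fractions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 1e-10)
    stop("pool fractions must sum to 1 (got ", sum(fr), ")")
  if (total_soc < 0) stop("total_soc must be >= 0")
  structure(list(total_soc = total_soc,
                 f_A = f_A, f_S = f_S, f_P = max(f_P, 0)),
            class = "soc_initial")
}

#' Assign initial pool masses from total SOC and fractions
#'
#' Litter and surface-microbe pools start empty; the active, slow and
#' passive pools receive \code{f_A}, \code{f_S} and \code{f_P} of the total.
#'
#' @param ic an \code{initial_condition}
#' @return a pool state: list with \code{month_index = 0} and named
#'   \code{masses} vector over the eight pools
#' @examples
#' st <- initialize_pools(initial_condition(50, f_S = 0.5))
#' st$masses[c("active", "slow", "passive")]  # 1, 25, 24
#' @export
initialize_pools <- function(ic) {
  stopifnot(inherits(ic, "soc_initial"))
  masses <- setNames(numeric(8), POOLS)
  masses["active"] <- ic$f_A * ic$total_soc
  masses["slow"] <- ic$f_S * ic$total_soc
  masses["passive"] <- ic$f_P * ic$total_soc
  pool_state(masses, month_index = 0L)
}

#' Construct a pool state
#'
#' @param masses named vector of pool C masses (Mg C ha^-1); missing pools
#'   default to zero
#' @param month_index 0-based month index
#' @return object of class \code{soc_state}
#' @export
pool_state <- function(masses = NULL, month_index = 0L) {
  m <- setNames(numeric(8), POOLS)
  if (!is.null(masses)) {
    bad <- setdiff(names(masses), POOLS)
    if (length(bad)) stop("unknown pool(s): ", paste(bad, collapse = ", "))
    m[names(masses)] <- masses
  }
  if (any(m < 0)) stop("pool masses must be >= 0")
  structure(list(month_index = as.integer(month_index), masses = m),
            class = "soc_state")
}

#' Total SOC observable of a state (active + slow + passive)
#' @param state a \code{soc_state}
#' @return Mg C ha^-1
#' @export
total_soc <- function(state) unname(sum(state$masses[SOC_POOLS]))

#' One month of forcing
#'
#' Bundles the abiotic decomposition factor, litter inputs and the
#' management multiplier for one month. Aboveground litter is split between
#' the soil (fraction \code{f_mix}, mixed in by tillage) and the surface;
#' each stream is then partitioned into metabolic and structural pools by
#' its lignin-to-nitrogen ratio. Belowground litter goes entirely to the
#' soil litter pools. Alternatively a fully routed 8-pool \code{inputs}
#' vector may be given directly.
#'
#' @param defac dimensionless abiotic decomposition factor (>= 0)
#' @param litter_in_ag aboveground litter C (Mg C ha^-1 mo^-1)
#' @param litter_in_bg belowground litter C (Mg C ha^-1 mo^-1)
#' @param mgmteff management multiplier on active/slow decay (>= 0)
#' @param f_mix fraction of aboveground litter transferred to the soil
#' @param lignin_ag,n_ag,lignin_bg,n_bg litter quality used to partition
#'   each stream into metabolic vs structural
#' @param inputs optional named 8-pool input vector overriding the routing
#' @return object of class \code{soc_forcing} with \code{defac},
#'   \code{mgmteff} and a routed per-pool \code{inputs} vector
#' @export
month_forcing <- function(defac, litter_in_ag = 0, litter_in_bg = 0,
                          mgmteff = 1, f_mix = 0.95,
                          lignin_ag = 0.10, n_ag = 0.0075,
                          lignin_bg = 0.16, n_bg = 0.008,
                          inputs = NULL) {
  if (defac < 0) stop("defac must be >= 0")
  if (litter_in_ag < 0 || litter_in_bg < 0) stop("litter inputs must be >= 0")
  if (mgmteff < 0) stop("mgmteff must be >= 0")
  if (is.null(inputs)) {
    u <- setNames(numeric(8), POOLS)
    if (litter_in_ag > 0) {
      soil <- partition_litter(litter_in_ag * f_mix, lignin_ag, n_ag)
      surf <- partition_litter(litter_in_ag * (1 - f_mix), lignin_ag, n_ag)
      u["soil_metabolic"] <- u["soil_metabolic"] + soil["metabolic"]
      u["soil_structural"] <- u["soil_structural"] + soil["structural"]
      u["surface_metabolic"] <- surf["metabolic"]
      u["surface_structural"] <- surf["structural"]
    }
    if (litter_in_bg > 0) {
      bg <- partition_litter(litter_in_bg, lignin_bg, n_bg)
      u["soil_metabolic"] <- u["soil_metabolic"] + bg["metabolic"]
      u["soil_structural"] <- u["soil_structural"] + bg["structural"]
    }
  } else {
    u <- setNames(numeric(8), POOLS)
    u[names(inputs)] <- inputs
  }
  structure(list(defac = defac, mgmteff = mgmteff, inputs = u),
            class = "soc_forcing")
}

# Per-month rate vector (mo^-1) for a forcing, optionally with the
# Michaelis-Menten substrate multiplier evaluated at month-start C_MR.
.month_rates <- function(state, forcing, kinetics, mm = NULL) {
  k <- kinetics$kbase * forcing$defac
  g <- forcing$mgmteff
  if (!is.null(mm))
    g <- g * mm_activity(unname(state$masses["soil_metabolic"]), mm)
  k["active"] <- k["active"] * g
  k["slow"] <- k["slow"] * g
  k
}

# Flow/decay matrix M with M[j,i] = x_{i,j} k_i (i != j), diag -k.
.flow_matrix <- function(kinetics, k) {
  M <- t(kinetics$flow * k)
  diag(M) <- -k
  M
}

#' Advance one month with the explicit Euler scheme
#'
#' Decomposition fluxes \code{v_j = k*_j C_j(m)} use month-start masses;
#' inputs are added with the step and are not decayed within their arrival
#' month. A step that would drive any pool negative (\code{k* > 1 mo^-1})
#' raises an integration-instability error naming the pool.
#'
#' @param state a \code{soc_state}
#' @param forcing a \code{soc_forcing}
#' @param kinetics a \code{soc_kinetics}
#' @param mm optional \code{mm_parameters} enabling Michaelis-Menten decay
#' @return list with the new \code{state} and the month's \code{co2} flux
#' @export
step_euler <- function(state, forcing, kinetics, mm = NULL) {
  k <- .month_rates(state, forcing, kinetics, mm)
  C <- state$masses
  v <- k * C
  M <- .flow_matrix(kinetics, k)
  Cn <- C + drop(M %*% C) + forcing$inputs
  if (any(Cn < -1e-10)) {
    bad <- POOLS[which.min(Cn)]
    stop("integration instability: pool '", bad,
         "' went negative in an Euler step (k* = ", signif(k[bad], 4),
         " mo^-1); use smaller rates or the Crank-Nicolson integrator")
  }
  list(state = pool_state(pmax(Cn, 0), state$month_index + 1L),
       co2 = unname(sum(kinetics$co2 * v)))
}

#' Advance one month with the Crank-Nicolson scheme
#'
#' Solves the implicit linear system \code{(I - M/2) C(m+1) =
#' (I + M/2) C(m) + u} with rate coefficients frozen at month-start values,
#' so decomposition fluxes use the average of start- and end-of-month
#' masses. Second-order accurate and non-negative for \code{k* < 2 mo^-1}.
#'
#' @inheritParams step_euler
#' @return list with the new \code{state} and the month's \code{co2} flux
#' @export
step_crank_nicholson <- function(state, forcing, kinetics, mm = NULL) {
  k <- .month_rates(state, forcing, kinetics, mm)
  C <- state$masses
  M <- .flow_matrix(kinetics, k)
  I <- diag(8)
  A <- I - M / 2
  if (abs(det(A)) < 1e-12)
    stop("singular Crank-Nicolson system (rate coefficients too large)")
  Cn <- drop(solve(A, (I + M / 2) %*% C + forcing$inputs))
  if (any(Cn < -1e-10)) {
    bad <- POOLS[which.min(Cn)]
    stop("integration instability: pool '", bad, "' went negative")
  }
  v <- k * (C + pmax(Cn, 0)) / 2
  list(state = pool_state(pmax(Cn, 0), state$month_index + 1L),
       co2 = unname(sum(kinetics$co2 * v)))
}

#' Simulate the pool network over a sequence of months
#'
#' Runs the monthly model (compiled kernel) from an initial condition over a
#' forcing series. The trajectory satisfies exact carbon conservation:
#' change in total system C equals inputs minus respired CO2 every month.
#'
#' @param ic an \code{initial_condition} or a \code{soc_state}
#' @param forcings a list of \code{soc_forcing} objects, or a list with
#'   vectors \code{defac}, \code{mgmteff} and an n x 8 \code{inputs} matrix
#' @param kinetics a \code{soc_kinetics}
#' @param integrator \code{"crank_nicholson"} (default) or \code{"euler"}
#' @param mm optional \code{mm_parameters}; when given, active and slow
#'   decay is multiplied by the Michaelis-Menten activity of the soil
#'   metabolic pool (lagged one month) and \code{mgmteff} should carry the
#'   tillage effect only
#' @return object of class \code{soc_trajectory}: data.frame with
#'   \code{month_index}, one column per pool, \code{co2_flux} (NA for the
#'   initial row) and \code{total_soc}
#' @export
simulate_pools <- function(ic, forcings, kinetics,
                           integrator = c("crank_nicholson", "euler"),
                           mm = NULL) {
  integrator <- match.arg(integrator)
  state0 <- if (inherits(ic, "soc_initial")) initialize_pools(ic) else ic
  stopifnot(inherits(state0, "soc_state"))
  f <- .forcing_table(forcings)
  if (nrow(f$inputs) == 0) stop("forcings must be non-empty")
  res <- sim_pools_cpp(unname(state0$masses), unname(kinetics$kbase),
                       f$defac, f$mgmteff, f$inputs,
                       unname(kinetics$flow), unname(kinetics$co2),
                       if (integrator == "euler") 0L else 1L,
                       !is.null(mm),
                       if (is.null(mm)) 0 else mm$vmax,
                       if (is.null(mm)) 1 else mm$km,
                       which(POOLS == "active") - 1L,
                       which(POOLS == "slow") - 1L,
                       which(POOLS == "soil_metabolic") - 1L,
                       POOLS)
  traj <- as.data.frame(res$trajectory)
  names(traj) <- POOLS
  out <- cbind(month_index = seq_len(nrow(traj)) - 1L + state0$month_index,
               traj,
               co2_flux = c(NA, res$co2))
  out$total_soc <- rowSums(out[SOC_POOLS])
  class(out) <- c("soc_trajectory", "data.frame")
  out
}

# Normalize forcings (list of soc_forcing, or list(defac, mgmteff, inputs))
# to parallel vectors/matrix for the kernel.
.forcing_table <- function(forcings) {
  if (is.list(forcings) && !is.null(forcings$defac)) {
    n <- length(forcings$defac)
    inputs <- forcings$inputs
    if (is.null(inputs)) inputs <- matrix(0, n, 8)
    mgmteff <- forcings$mgmteff
    if (is.null(mgmteff)) mgmteff <- rep(1, n)
    stopifnot(nrow(inputs) == n, length(mgmteff) == n)
    return(list(defac = as.numeric(forcings$defac),
                mgmteff = as.numeric(mgmteff),
                inputs = unname(as.matrix(inputs))))
  }
  stopifnot(all(vapply(forcings, inherits, TRUE, "soc_forcing")))
  list(defac = vapply(forcings, `[[`, 0, "defac"),
       mgmteff = vapply(forcings, `[[`, 0, "mgmteff"),
       inputs = do.call(rbind, lapply(forcings, `[[`, "inputs")))
}

#' Write a simulated trajectory to delimited text
#' @param traj a \code{soc_trajectory}
#' @param path output CSV path
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
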