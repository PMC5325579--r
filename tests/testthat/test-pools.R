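test_that("pool initialization distributes total SOC by the fractions", {
  st <- initialize_pools(initial_condition(50, f_S = 0.50, f_A = 0.02))
  expect_equal(unname(st$masses[c("active", "slow", "passive")]),
               c(1, 25, 24))
  expect_equal(unname(st$masses[c("surface_structural", "soil_metabolic",
                                  "surface_microbe")]), c(0, 0, 0))
  expect_identical(st$month_index, 0L)
  # zero total
  st0 <- initialize_pools(initial_condition(0, f_S = 0.5))
  expect_true(all(st0$masses == 0))
  # boundary: f_A + f_S = 1 leaves the passive pool empty
  stb <- initialize_pools(initial_condition(50, f_S = 0.98, f_A = 0.02))
  expect_equal(unname(stb$masses["passive"]), 0)
  expect_error(initial_condition(50, f_S = 0.5, f_A = 0.02, f_P = 0.6),
               "sum to 1")
  expect_error(initial_condition(50, f_S = 1.2), "\\[0, 1\\]")
})

test_that("Euler step matches the one-pool closed form and conserves C", {
  kin <- slow_only_kinetics(0.1)
  s0 <- pool_state(c(slow = 10))
  r <- step_euler(s0, month_forcing(defac = 1), kin)
  expect_equal(unname(r$state$masses["slow"]), 10 * (1 - 0.1))
  expect_identical(r$state$month_index, 1L)
  # decomposed C is split between destinations and CO2
  expect_equal(sum(r$state$masses) + r$co2, 10)

  # zero rates: pools grow by exactly their inputs
  kin0 <- slow_only_kinetics(0)
  f <- month_forcing(defac = 1, litter_in_ag = 0.6, litter_in_bg = 0.4)
  r0 <- step_euler(pool_state(c(active = 2)), f, kin0)
  expect_equal(unname(sum(r0$state$masses)), 3)
  expect_equal(r0$co2, 0)

  # conservation identity on a full random configuration
  set.seed(3)
  kin <- century_kinetics(clay = 0.3, sand = 0.2)
  st <- pool_state(setNames(runif(8, 0, 10),
                            c("surface_structural", "surface_metabolic",
                              "soil_structural", "soil_metabolic",
                              "surface_microbe", "active", "slow",
                              "passive")))
  fr <- month_forcing(defac = 0.4, litter_in_ag = 0.5, litter_in_bg = 0.3,
                      mgmteff = 1.4)
  r <- step_euler(st, fr, kin)
  d_total <- sum(r$state$masses) - sum(st$masses)
  expect_equal(d_total, sum(fr$inputs) - r$co2, tolerance = 1e-12)
})

test_that("Crank-Nicolson step solves the implicit system exactly", {
  kin <- slow_only_kinetics(0.1)
  s0 <- pool_state(c(slow = 10))
  r <- step_crank_nicholson(s0, month_forcing(defac = 1), kin)
  expect_equal(unname(r$state$masses["slow"]), 10 * (1 - 0.05) / (1 + 0.05),
               tolerance = 1e-12)
  # with all rates zero both integrators reduce to input addition
  kin0 <- slow_only_kinetics(0)
  f <- month_forcing(defac = 1, litter_in_ag = 1)
  re <- step_euler(pool_state(), f, kin0)
  rc <- step_crank_nicholson(pool_state(), f, kin0)
  expect_equal(rc$state$masses, re$state$masses)
  # conservation under CN too
  kin <- century_kinetics(clay = 0.2, sand = 0.4)
  st <- pool_state(setNames(rep(5, 8), names(kin$k0)))
  fr <- month_forcing(defac = 0.6, litter_in_ag = 0.2, mgmteff = 2)
  r <- step_crank_nicholson(st, fr, kin)
  expect_equal(sum(r$state$masses) - sum(st$masses),
               sum(fr$inputs) - r$co2, tolerance = 1e-10)
})

test_that("Euler is first-order and Crank-Nicolson second-order accurate", {
  # one-pool decay over unit time with total rate k, n sub-steps of k/n
  decay_err <- function(n, k, stepper) {
    kin <- slow_only_kinetics(k / n)
    st <- pool_state(c(slow = 10))
    f <- month_forcing(defac = 1)
    for (i in seq_len(n)) st <- stepper(st, f, kin)$state
    abs(unname(st$masses["slow"]) - 10 * exp(-k))
  }
  k <- 0.8
  e1 <- decay_err(8, k, step_euler); e2 <- decay_err(16, k, step_euler)
  expect_equal(e1 / e2, 2, tolerance = 0.15)
  c1 <- decay_err(8, k, step_crank_nicholson)
  c2 <- decay_err(16, k, step_crank_nicholson)
  expect_equal(c1 / c2, 4, tolerance = 0.15)
  expect_lt(c1, e1)  # CN beats Euler at equal step size
})

test_that("Euler refuses a step that drives a pool negative", {
  kin <- slow_only_kinetics(1.5)
  s0 <- pool_state(c(slow = 10))
  expect_error(step_euler(s0, month_forcing(defac = 1), kin),
               "slow")
  # the same configuration is stable under Crank-Nicolson
  r <- step_crank_nicholson(s0, month_forcing(defac = 1), kin)
  expect_gte(min(r$state$masses), 0)
})

test_that("simulate_pools: trajectory shape, conservation, monotone decay", {
  kin <- century_kinetics(clay = 0.25, sand = 0.3)
  n <- 36
  # zero inputs, zero rates: constant trajectory
  tr <- simulate_pools(initial_condition(40, 0.6),
                       list(defac = rep(0, n)), kin)
  expect_equal(nrow(tr), n + 1)
  expect_true(all(abs(tr$total_soc - 40) < 1e-12))
  # zero inputs, positive rates: total SOC non-increasing
  tr2 <- simulate_pools(initial_condition(40, 0.6),
                        list(defac = rep(0.5, n)), kin)
  expect_true(all(diff(tr2$total_soc) <= 1e-12))
  # cumulative balance over the run
  u <- matrix(0.4 / 8, n, 8)
  tr3 <- simulate_pools(initial_condition(40, 0.6),
                        list(defac = rep(0.5, n), inputs = u), kin)
  tot <- rowSums(tr3[, c("surface_structural", "surface_metabolic",
                         "soil_structural", "soil_metabolic",
                         "surface_microbe", "active", "slow", "passive")])
  expect_equal(tot[n + 1] - tot[1], n * 0.4 - sum(tr3$co2_flux[-1]),
               tolerance = 1e-9)
  expect_error(simulate_pools(initial_condition(40, 0.6),
                              list(defac = numeric(0)), kin),
               "non-empty")
})

test_that("constant forcing drives the system to the linear steady state", {
  # raise the passive-pool rate so the fixed point is reached in a
  # practical number of months
  k0 <- c(surface_structural = 3.9, surface_metabolic = 14.8,
          soil_structural = 4.9, soil_metabolic = 18.5,
          surface_microbe = 6.0, active = 7.3, slow = 0.2,
          passive = 0.5)
  kin <- century_kinetics(clay = 0.25, sand = 0.3, k0 = k0)
  defac <- 0.4; mgmt <- 1.2
  u <- setNames(rep(0.02, 8), names(kin$k0))
  n <- 6000
  tr <- simulate_pools(initial_condition(30, 0.5),
                       list(defac = rep(defac, n),
                            mgmteff = rep(mgmt, n),
                            inputs = matrix(u, n, 8, byrow = TRUE)), kin)
  Cend <- as.numeric(tr[n + 1, names(kin$k0)])
  # fixed point of the monthly map: M C* + u = 0
  k <- kin$kbase * defac
  k["active"] <- k["active"] * mgmt; k["slow"] <- k["slow"] * mgmt
  M <- t(kin$flow * k); diag(M) <- -k
  Cstar <- solve(M, -u)
  expect_equal(Cend, unname(Cstar), tolerance = 1e-6)
  # brute-force long-run agrees with the last step barely moving
  expect_lt(max(abs(as.numeric(tr[n + 1, names(kin$k0)]) -
                      as.numeric(tr[n, names(kin$k0)]))), 1e-8)
})

test_that("simulate_pools agrees with repeated single steps", {
  kin <- century_kinetics(clay = 0.3, sand = 0.15)
  set.seed(4)
  n <- 18
  fr <- lapply(seq_len(n), function(i)
    month_forcing(defac = runif(1, 0, 0.6),
                  litter_in_ag = runif(1, 0, 0.5),
                  litter_in_bg = runif(1, 0, 0.3),
                  mgmteff = runif(1, 0.8, 2)))
  for (stepper in list(step_euler, step_crank_nicholson)) {
    st <- initialize_pools(initial_condition(45, 0.55))
    for (i in seq_len(n)) st <- stepper(st, fr[[i]], kin)$state
    integ <- if (identical(stepper, step_euler)) "euler"
             else "crank_nicholson"
    tr <- simulate_pools(initial_condition(45, 0.55), fr, kin,
                         integrator = integ)
    expect_equal(as.numeric(tr[n + 1, names(kin$k0)]),
                 unname(st$masses), tolerance = 1e-10)
  }
})

test_that("management multiplier leaves litter pool trajectories unchanged", {
  kin <- century_kinetics(clay = 0.2, sand = 0.3)
  n <- 24
  u <- matrix(0, n, 8); u[, 3] <- 0.2  # soil structural input stream
  base <- list(defac = rep(0.4, n), inputs = u)
  tr1 <- simulate_pools(initial_condition(40, 0.6),
                        c(base, list(mgmteff = rep(1, n))), kin)
  tr2 <- simulate_pools(initial_condition(40, 0.6),
                        c(base, list(mgmteff = rep(2, n))), kin)
  litter <- c("surface_structural", "surface_metabolic",
              "soil_structural", "soil_metabolic", "surface_microbe")
  expect_equal(tr1[, litter], tr2[, litter], tolerance = 1e-12)
  expect_true(any(abs(tr1$active - tr2$active) > 1e-6))
})
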