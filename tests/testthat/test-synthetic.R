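test_that("seasonal defac series is clamped, periodic and seeded", {
  d <- generate_defac(120, seed = 3)
  expect_length(d, 120)
  expect_true(all(d >= 0 & d <= 1))
  expect_identical(d, generate_defac(120, seed = 3))
  expect_false(identical(d, generate_defac(120, seed = 4)))
  # no amplitude, no noise: constant at the mean level
  flat <- generate_defac(24, amplitude = 0, noise_sd = 0, seed = 1)
  expect_equal(flat, rep(0.35, 24))
  # seasonal signal present: monthly means vary across the year
  dm <- colMeans(matrix(generate_defac(600, seed = 5), ncol = 12,
                        byrow = TRUE))
  expect_gt(diff(range(dm)), 0.3)
})

test_that("yield generator: saturating N response with configured noise", {
  tru <- truth_parameters(yield_cv = 0)
  y0 <- generate_yields(rep("corn", 5), 0, tru, seed = 1)
  y336 <- generate_yields(rep("corn", 5), 336, tru, seed = 1)
  expect_equal(length(unique(y0$yield)), 1)  # deterministic at cv = 0
  expect_gt(mean(y336$yield), mean(y0$yield))
  # soybean does not respond to N
  s0 <- generate_yields(rep("soybean", 3), 0, tru, seed = 1)
  s336 <- generate_yields(rep("soybean", 3), 336, tru, seed = 1)
  expect_equal(s0$yield, s336$yield)
  # empirical CV close to configured
  tru2 <- truth_parameters(yield_cv = 0.10)
  y <- generate_yields(rep("corn", 1000), 150, tru2, seed = 2)
  expect_equal(sd(y$yield) / mean(y$yield), 0.10, tolerance = 0.02)
})

test_that("generated study structure matches its design", {
  gs <- noisy_study()
  des <- synthetic_designs(n_sites = 2, seed = 11)
  expect_length(gs$study$sites, 2)
  for (i in 1:2) {
    s <- gs$study$sites[[i]]
    expect_length(s$defac, 12 * des[[i]]$n_years)
    for (tr in s$treatments)
      expect_equal(nrow(tr$observations), length(des[[i]]$obs_years))
  }
  # truth record aligns with the pooled observation table
  prob <- build_problem(gs$study)
  expect_equal(nrow(gs$soc_true), prob$n_obs)
  expect_equal(gs$soc_true$year, prob$meta$year)
  # reproducible end to end
  gs2 <- generate_study(synthetic_designs(n_sites = 2, seed = 11),
                        truth_parameters(), seed = 11)
  expect_equal(gs2$study, gs$study)
})

test_that("noiseless observations equal the forward trajectory exactly", {
  gs <- noiseless_study()
  prob <- build_problem(gs$study)
  truth_par <- prob$start
  for (s in names(gs$truth$f_S))
    truth_par[paste0("f_S[", s, "]")] <-
      qlogis((gs$truth$f_S[[s]] - 0.01) / 0.94)
  for (cl in c("low", "mid", "high")) {
    nm <- paste0("ferteff[", cl, "]")
    if (nm %in% names(truth_par))
      truth_par[nm] <- gs$truth$lambda_fert[[cl]]
  }
  for (cl in c("mid", "high")) {
    nm <- paste0("omeff[", cl, "]")
    if (nm %in% names(truth_par))
      truth_par[nm] <- gs$truth$lambda_om[[cl]]
  }
  expect_equal(prob$predict(truth_par), prob$observed,
               tolerance = 1e-10)
  # and the recorded noiseless truth coincides with the observations
  expect_equal(gs$soc_true$soc_true, prob$observed, tolerance = 1e-10)
})

test_that("fertilized treatments receive more carbon input than controls", {
  tru <- truth_parameters(yield_cv = 0)
  des <- synthetic_designs(n_sites = 4, seed = 21)
  gs <- generate_study(des, tru, seed = 21)
  for (s in gs$study$sites) {
    trts <- s$treatments
    in_tot <- vapply(trts, function(tr) {
      fc <- socfit:::build_treatment_forcing(s, tr)
      sum(fc$inputs)
    }, numeric(1))
    high_n <- vapply(trts, function(tr) tr$n_rate[1] >= 200 &&
                       tr$tillage == "CT", TRUE)
    ctrl <- vapply(trts, function(tr) tr$n_rate[1] == 0 &&
                     tr$om_rate[1] == 0, TRUE)
    if (any(high_n) && any(ctrl))
      expect_gt(min(in_tot[high_n]), max(in_tot[ctrl & !high_n]))
  }
})
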