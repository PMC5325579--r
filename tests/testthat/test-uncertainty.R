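test_that("parameter draws: degenerate covariance, seeding, moments", {
  fit <- noisy_fit()
  # zero covariance: every draw equals the estimates
  fit0 <- fit
  fit0$cov_transformed <- fit$cov_transformed * 0
  d0 <- draw_parameter_sets(fit0, mc_config(n_draws = 20, seed = 2))
  expect_equal(d0, matrix(fit$par_transformed, 20, fit$n_par,
                          byrow = TRUE,
                          dimnames = list(NULL,
                                          names(fit$par_transformed))))
  # reproducibility contract
  d1 <- draw_parameter_sets(fit, mc_config(n_draws = 50, seed = 3))
  d2 <- draw_parameter_sets(fit, mc_config(n_draws = 50, seed = 3))
  d3 <- draw_parameter_sets(fit, mc_config(n_draws = 50, seed = 4))
  expect_identical(d1, d2)
  expect_false(isTRUE(all.equal(d1, d3)))
  # sample mean close to the estimates
  dm <- draw_parameter_sets(fit, mc_config(n_draws = 4000, seed = 5))
  se <- sqrt(diag(fit$cov_transformed))
  expect_true(all(abs(colMeans(dm) - fit$par_transformed) <
                    3 * se / sqrt(4000) + 1e-8))
})

test_that("prediction intervals bracket the median and respond to spread", {
  fit <- noisy_fit()
  cfg <- mc_config(n_draws = 150, seed = 7)
  draws <- draw_parameter_sets(fit, cfg)
  iv <- mc_prediction_interval(fit$problem, draws, cfg)
  expect_true(all(iv$lower <= iv$predicted + 1e-9))
  expect_true(all(iv$upper >= iv$predicted - 1e-9))
  # degenerate draws give zero-width intervals at the point prediction
  one <- draws[rep(1, 30), ]
  iv0 <- mc_prediction_interval(fit$problem, one, cfg)
  expect_equal(iv0$lower, iv0$upper)
  # inflating the covariance 4x widens every interval
  fit4 <- fit
  fit4$cov_transformed <- fit$cov_transformed * 4
  iv4 <- mc_prediction_interval(fit$problem,
                                draw_parameter_sets(fit4, cfg), cfg)
  expect_true(all(iv4$upper - iv4$lower >=
                    iv$upper - iv$lower - 1e-9))
  expect_gt(mean(iv4$upper - iv4$lower), mean(iv$upper - iv$lower))
})

test_that("observation perturbation: identity at cv = 0, correct moments", {
  gs <- noisy_study()
  same <- perturb_observations(gs$study, cv = 0, seed = 1)
  expect_equal(same, gs$study)
  pert <- perturb_observations(gs$study, cv = 0.1, seed = 1)
  # structure identical, values changed and strictly positive
  o0 <- gs$study$sites[[1]]$treatments[[1]]$observations
  o1 <- pert$sites[[1]]$treatments[[1]]$observations
  expect_equal(o0$year, o1$year)
  expect_false(isTRUE(all.equal(o0$soc, o1$soc)))
  expect_true(all(o1$soc > 0))
  y1 <- pert$sites[[1]]$treatments[[1]]$yields$yield
  expect_true(all(y1 > 0))
  # moment check on normalized draws (value / original ~ N(1, cv))
  ratios <- replicate(400, {
    p <- perturb_observations(gs$study, cv = 0.1,
                              seed = sample.int(1e6, 1))
    p$sites[[1]]$treatments[[1]]$observations$soc / o0$soc
  })
  expect_equal(sd(as.numeric(ratios)), 0.1, tolerance = 0.01)
  expect_equal(mean(as.numeric(ratios)), 1, tolerance = 0.01)
})

test_that("refitting perturbed observations widens the predictive envelope", {
  gs <- noisy_study()
  cfg <- mc_config(n_draws = 150, seed = 9)
  cmp <- synthetic_refit_interval(gs$study, fit_spec(gs$study),
                                  cv = 0.10, cfg = cfg)
  expect_gte(cmp$width_synthetic, cmp$width_original * 0.9)
  expect_equal(nrow(cmp$original), nrow(cmp$synthetic))
  # cv = 0 reproduces the original intervals
  cmp0 <- synthetic_refit_interval(gs$study, fit_spec(gs$study),
                                   cv = 0, cfg = cfg)
  expect_equal(cmp0$width_synthetic, cmp0$width_original,
               tolerance = 1e-8)
})
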