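test_that("residual problem: length, self-consistency at truth, order invariance", {
  gs <- noiseless_study()
  prob <- build_problem(gs$study)
  expect_equal(prob$n_obs, nrow(prob$meta))
  expect_equal(length(prob$residuals(prob$start)), prob$n_obs)
  # evaluating at the generating truth reproduces the data exactly
  truth_par <- prob$start
  for (s in names(gs$truth$f_S)) {
    nm <- paste0("f_S[", s, "]")
    truth_par[nm] <- qlogis((gs$truth$f_S[[s]] - 0.01) / 0.94)
  }
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
  expect_lt(max(abs(prob$residuals(truth_par))), 1e-8)
  # permuting site order leaves the SSR unchanged
  study_rev <- soc_study(rev(gs$study$sites))
  prob_rev <- build_problem(study_rev)
  p_rev <- truth_par[prob_rev$par_info$name]
  expect_equal(sum(prob_rev$residuals(p_rev)^2),
               sum(prob$residuals(truth_par)^2), tolerance = 1e-10)
})

test_that("noiseless generate-then-recover returns the true parameters", {
  gs <- noiseless_study()
  fit <- fit_soc(gs$study)
  expect_equal(unname(fit$estimates["ferteff[high]"]), 1.5,
               tolerance = 1e-3)
  for (s in names(gs$truth$f_S))
    expect_equal(unname(fit$estimates[paste0("f_S[", s, "]")]),
                 unname(gs$truth$f_S[[s]]), tolerance = 1e-3)
  expect_lt(fit$ssr, 1e-10)
  expect_gt(fit$r_squared, 0.999)
})

test_that("one-parameter fit agrees with a fine grid search on SSR", {
  gs <- one_param_study()
  prob <- build_problem(gs$study)
  expect_equal(nrow(prob$par_info), 1)
  fit <- fit_soc(prob)
  grid <- seq(0.30, 0.90, by = 1e-4)
  ssr <- vapply(grid, function(f) {
    sum(prob$residuals(qlogis((f - 0.01) / 0.94))^2)
  }, numeric(1))
  expect_equal(unname(fit$estimates[1]), grid[which.min(ssr)],
               tolerance = 2e-4)
})

test_that("fitting improves on the starting sum of squares", {
  gs <- noisy_study()
  prob <- build_problem(gs$study)
  fit <- noisy_fit()
  expect_lte(fit$ssr, sum(prob$residuals(prob$start)^2))
  # with all parameters held at given values, residuals are the plain
  # forward-run mismatch (no optimization involved)
  ssr_fixed <- sum(prob$residuals(prob$start)^2)
  expect_equal(ssr_fixed, sum((prob$observed -
                                 prob$predict(prob$start))^2))
})

test_that("parameter recovery tolerates 10% observation noise", {
  fit <- noisy_fit()
  gs <- noisy_study()
  fs_hat <- fit$estimates[paste0("f_S[", names(gs$truth$f_S), "]")]
  rel_err <- abs(fs_hat - gs$truth$f_S) / gs$truth$f_S
  expect_lt(median(rel_err), 0.15)
  expect_equal(unname(fit$estimates["ferteff[high]"]), 1.5,
               tolerance = 0.25)
})

test_that("R-squared is the squared Pearson correlation", {
  x <- c(1, 2, 3, 4)
  expect_equal(r_squared(x, x), 1)
  expect_equal(r_squared(x, 2 * x + 3), 1)  # affine invariance
  expect_equal(r_squared(x, c(1.1, 1.9, 3.2, 3.8)), 0.9817778,
               tolerance = 1e-6)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(r_squared(c(1, 2), c(1, 2)), "at least 3")
})

test_that("parameter t tests match the t distribution", {
  fit <- noisy_fit()
  tab <- fit$parameters
  # estimate equal to its null gives p = 1
  nulls <- setNames(tab$estimate, tab$name)
  t1 <- parameter_tests(fit, nulls)
  expect_equal(t1$p_value, rep(1, nrow(t1)))
  # hand-checked case: estimate 1.26, SE 0.23, null 1, df 20
  expect_equal(2 * pt(-abs((1.26 - 1) / 0.23), df = 20), 0.2716679,
               tolerance = 1e-5)
  # a strongly estimated high-N effect is significantly above one
  expect_true(tab["ferteff[high]", "p_value"] < 0.05)
  expect_error(parameter_tests(fit, c(bogus = 1)), "unknown parameter")
})

test_that("fit covariance is symmetric PSD and SE is its diagonal root", {
  fit <- noisy_fit()
  V <- fit$covariance
  expect_equal(V, t(V), tolerance = 1e-10)
  expect_true(all(eigen(V, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  expect_equal(unname(sqrt(diag(V))), unname(fit$std_errors),
               tolerance = 1e-10)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  expect_equal(fit$df, fit$n_obs - fit$n_par)
})

test_that("too few observations for the parameter count is an error", {
  gs <- one_param_study()
  prob <- build_problem(gs$study)
  small <- prob
  small$n_obs <- 1
  expect_error(fit_soc(small), "more observations")
})
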