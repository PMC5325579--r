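#' Monte-Carlo configuration
#'
#' @param n_draws number of parameter draws (default 1000)
#' @param level confidence level for prediction intervals
#' @param seed integer seed for reproducibility
#' @param max_resample times a failed draw is redrawn before being dropped
#' @return object of class \code{mc_config}
#' @export
mc_config <- function(n_draws = 1000, level = 0.95, seed = 1,
                      max_resample = 10) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  structure(list(n_draws = n_draws, level = level, seed = seed,
                 max_resample = max_resample), class = "mc_config")
}

#' Draw parameter sets from the fitted sampling distribution
#'
#' Multivariate normal draws centred on the estimates using the
#' transformed-space covariance, so bound constraints (pool fractions in
#' their bounds, positive effects and kinetic constants) hold after
#' back-transformation.
#'
#' @param fit a \code{soc_fit}
#' @param cfg an \code{mc_config}
#' @return \code{n_draws} x p matrix of transformed parameter vectors
#' @export
draw_parameter_sets <- function(fit, cfg = mc_config()) {
  V <- fit$cov_transformed
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("covariance matrix is not positive semi-definite")
  V <- V + diag(max(0, -min(ev)) + 0, nrow(V))
  set.seed(cfg$seed)
  draws <- MASS::mvrnorm(cfg$n_draws, mu = fit$par_transformed,
                         Sigma = V)
  if (cfg$n_draws == 1) draws <- matrix(draws, nrow = 1)
  colnames(draws) <- names(fit$par_transformed)
  draws
}

#' Monte-Carlo prediction intervals at the observation points
#'
#' Forward-simulates every parameter draw and takes pointwise empirical
#' percentiles of the predicted SOC. Draws whose simulation fails are
#' dropped (after resampling attempts); more than 10\% failures is an
#' error.
#'
#' @param problem a \code{soc_problem} (e.g. \code{fit$problem})
#' @param draws matrix from \code{\link{draw_parameter_sets}}
#' @param cfg an \code{mc_config}
#' @return data.frame: site, treatment, year, observed, predicted (median),
#'   lower, upper
#' @export
mc_prediction_interval <- function(problem, draws, cfg = mc_config()) {
  if (nrow(draws) == 0) stop("draws must be non-empty")
  preds <- matrix(NA_real_, nrow(draws), problem$n_obs)
  failed <- 0
  set.seed(cfg$seed + 1L)
  for (i in seq_len(nrow(draws))) {
    ok <- FALSE
    for (tries in 0:cfg$max_resample) {
      par <- if (tries == 0) draws[i, ]
      else fit_draw_resample(problem, draws)
      p <- tryCatch(problem$predict(par), error = function(e) NULL)
      if (!is.null(p)) { preds[i, ] <- p; ok <- TRUE; break }
    }
    if (!ok) failed <- failed + 1
  }
  if (failed > 0.1 * nrow(draws))
    stop("more than 10% of Monte-Carlo simulations failed (", failed,
         " of ", nrow(draws), ")")
  preds <- preds[stats::complete.cases(preds), , drop = FALSE]
  a <- (1 - cfg$level) / 2
  out <- problem$meta
  out$predicted <- apply(preds, 2, stats::median)
  out$lower <- apply(preds, 2, quantile, probs = a)
  out$upper <- apply(preds, 2, quantile, probs = 1 - a)
  out
}

# Redraw a single parameter vector by resampling a row (fallback for a
# failed simulation).
fit_draw_resample <- function(problem, draws) {
  draws[sample.int(nrow(draws), 1L), ]
}

#' Perturb a study's observations with multiplicative normal noise
#'
#' Replaces every SOC observation and every yield with a draw from a normal
#' distribution centred on the recorded value with standard deviation
#' \code{cv} times the value, truncated at zero by resampling. Used to
#' emulate measurement uncertainty ("synthetic" observations) before
#' refitting.
#'
#' @param study a \code{soc_study}
#' @param cv coefficient of variation (default 0.10)
#' @param seed integer seed
#' @return a perturbed \code{soc_study} with identical structure
#' @export
perturb_observations <- function(study, cv = 0.10, seed = 1) {
  if (cv < 0) stop("cv must be >= 0")
  set.seed(seed)
  draw_pos <- function(mu) {
    if (cv == 0) return(mu)
    x <- rnorm(length(mu), mu, cv * mu)
    while (any(x <= 0)) {
      bad <- x <= 0
      x[bad] <- rnorm(sum(bad), mu[bad], cv * mu[bad])
    }
    x
  }
  for (s in names(study$sites)) {
    for (tr in names(study$sites[[s]]$treatments)) {
      trt <- study$sites[[s]]$treatments[[tr]]
      if (!is.null(trt$observations))
        trt$observations$soc <- draw_pos(trt$observations$soc)
      if (!is.null(trt$yields))
        trt$yields$yield <- draw_pos(trt$yields$yield)
      study$sites[[s]]$treatments[[tr]] <- trt
    }
  }
  study
}

#' Compare Monte-Carlo intervals before and after observation perturbation
#'
#' Fits the study, computes Monte-Carlo prediction intervals, then perturbs
#' observations and yields at the given coefficient of variation, refits,
#' and recomputes the intervals, quantifying how measurement uncertainty
#' widens the predictive envelope.
#'
#' @param study a \code{soc_study}
#' @param spec a \code{soc_fit_spec}
#' @param cv observation coefficient of variation
#' @param cfg an \code{mc_config}
#' @return list with \code{original} and \code{synthetic} interval tables
#'   (see \code{\link{mc_prediction_interval}}), the two fits, and the mean
#'   interval widths
#' @export
synthetic_refit_interval <- function(study, spec = fit_spec(study),
                                     cv = 0.10, cfg = mc_config()) {
  fit0 <- fit_soc(study, spec)
  iv0 <- mc_prediction_interval(fit0$problem,
                                draw_parameter_sets(fit0, cfg), cfg)
  pstudy <- perturb_observations(study, cv, seed = cfg$seed + 1000L)
  fit1 <- fit_soc(pstudy, spec)
  iv1 <- mc_prediction_interval(fit1$problem,
                                draw_parameter_sets(fit1, cfg), cfg)
  list(original = iv0, synthetic = iv1,
       fit_original = fit0, fit_synthetic = fit1,
       width_original = mean(iv0$upper - iv0$lower),
       width_synthetic = mean(iv1$upper - iv1$lower))
}
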