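#' Specify the parameters of an inverse-modeling problem
#'
#' Chooses which parameters are estimated and how they are transformed for
#' optimization: initial slow-pool fractions (logit scale, bounded), log
#' management effects (identity scale), and in Michaelis-Menten mode the
#' kinetic constants (log scale). Fertilization and amendment effect classes
#' are detected from the study: a lambda is fitted only for classes that
#' occur in at least one treatment-year.
#'
#' @param study a \code{soc_study}
#' @param f_s_grouping \code{"auto"} (per treatment only at sites where
#'   initial SOC differs among treatments), \code{"site"}, or
#'   \code{"treatment"}
#' @param decay_mode \code{"mgmteff"} (multiplicative management effects) or
#'   \code{"michaelis_menten"} (substrate-dependent decay; fertilization and
#'   amendment effects are dropped and only the tillage series is retained)
#' @param integrator passed to the forward model
#' @param clteff_mode tillage-effect mode, see
#'   \code{\link{effect_parameters}}
#' @param f_s_bounds bounds on the slow-pool fraction (logit transform)
#' @param f_s_start,lambda_start,vmax_start,km_start starting values on the
#'   natural scale
#' @return object of class \code{soc_fit_spec}
#' @export
fit_spec <- function(study,
                     f_s_grouping = c("auto", "site", "treatment"),
                     decay_mode = c("mgmteff", "michaelis_menten"),
                     integrator = c("crank_nicholson", "euler"),
                     clteff_mode = "annualized",
                     f_s_bounds = c(0.01, 0.95),
                     f_s_start = 0.5, lambda_start = 0,
                     vmax_start = 1.5, km_start = 0.5) {
  f_s_grouping <- match.arg(f_s_grouping)
  decay_mode <- match.arg(decay_mode)
  integrator <- match.arg(integrator)
  structure(list(f_s_grouping = f_s_grouping, decay_mode = decay_mode,
                 integrator = integrator, clteff_mode = clteff_mode,
                 f_s_bounds = f_s_bounds, f_s_start = f_s_start,
                 lambda_start = lambda_start,
                 vmax_start = vmax_start, km_start = km_start),
            class = "soc_fit_spec")
}

# Does this site group f_S per treatment?
.per_treatment_fs <- function(site, grouping) {
  if (grouping == "treatment") return(TRUE)
  if (grouping == "site") return(FALSE)
  init <- vapply(site$treatments, function(tr)
    if (is.null(tr$initial_soc)) site$initial_soc else tr$initial_soc,
    numeric(1))
  length(unique(init)) > 1
}

#' Build the residual problem for a study and specification
#'
#' Precomputes all parameter-independent forcings (litter inputs, tillage
#' series, annual rate classes, observation indices) and returns closures
#' that evaluate residuals and predictions for a transformed parameter
#' vector. Residuals are observed minus predicted SOC, concatenated across
#' all sites and treatments (unweighted pooling).
#'
#' @param study a \code{soc_study}
#' @param spec a \code{soc_fit_spec}
#' @return object of class \code{soc_problem} with elements
#'   \code{par_info} (parameter table), \code{start} (transformed starting
#'   vector), \code{residuals(par)}, \code{predict(par)}, \code{observed},
#'   \code{meta} (site/treatment/year per observation), \code{n_obs}
#' @export
build_problem <- function(study, spec = fit_spec(study)) {
  stopifnot(inherits(study, "soc_study"))
  lo <- spec$f_s_bounds[1]; hi <- spec$f_s_bounds[2]
  mm_mode <- spec$decay_mode == "michaelis_menten"
  method <- if (spec$integrator == "euler") 0L else 1L

  units <- list(); fs_names <- character()
  fert_seen <- character(); om_seen <- character()
  meta <- list()
  for (s in study$sites) {
    kin <- century_kinetics(clay = s$clay, sand = s$sand)
    per_trt <- .per_treatment_fs(s, spec$f_s_grouping)
    for (tr in s$treatments) {
      fc <- build_treatment_forcing(s, tr, clteff_mode = spec$clteff_mode)
      fs_name <- if (per_trt)
        paste0("f_S[", s$site_id, ":", tr$treatment_id, "]")
      else paste0("f_S[", s$site_id, "]")
      fs_names <- union(fs_names, fs_name)
      fert_seen <- union(fert_seen, setdiff(fc$fert_class, "none"))
      om_seen <- union(om_seen, setdiff(fc$om_class, "none"))
      units[[length(units) + 1L]] <- list(
        site = s$site_id, trt = tr$treatment_id, fs_name = fs_name,
        kbase = unname(kin$kbase), flow = unname(kin$flow),
        co2 = unname(kin$co2), forcing = fc)
      meta[[length(meta) + 1L]] <- data.frame(
        site = s$site_id, treatment = tr$treatment_id,
        year = fc$obs_year, observed = fc$obs)
    }
  }
  meta <- do.call(rbind, meta)

  par_info <- data.frame(name = fs_names, kind = "f_S",
                         scale = "logit",
                         start = qlogis((spec$f_s_start - lo) / (hi - lo)),
                         stringsAsFactors = FALSE)
  if (!mm_mode) {
    for (cl in c("low", "mid", "high"))
      if (cl %in% fert_seen)
        par_info <- rbind(par_info, data.frame(
          name = paste0("ferteff[", cl, "]"), kind = "lambda_fert",
          scale = "log_effect", start = spec$lambda_start))
    for (cl in c("mid", "high"))
      if (cl %in% om_seen)
        par_info <- rbind(par_info, data.frame(
          name = paste0("omeff[", cl, "]"), kind = "lambda_om",
          scale = "log_effect", start = spec$lambda_start))
  } else {
    par_info <- rbind(par_info,
                      data.frame(name = "vmax", kind = "vmax",
                                 scale = "log",
                                 start = log(spec$vmax_start)),
                      data.frame(name = "km", kind = "km", scale = "log",
                                 start = log(spec$km_start)))
  }
  rownames(par_info) <- par_info$name

  ia <- which(POOLS == "active") - 1L
  is_ <- which(POOLS == "slow") - 1L
  im <- which(POOLS == "soil_metabolic") - 1L
  fA <- 0.02
  i_active <- which(POOLS == "active")
  i_slow <- which(POOLS == "slow")
  i_passive <- which(POOLS == "passive")

  predict_fun <- function(par) {
    names(par) <- par_info$name
    fert_mult <- c(none = 1, low = 1, mid = 1, high = 1)
    om_mult <- c(none = 1, mid = 1, high = 1)
    if (!mm_mode) {
      for (cl in c("low", "mid", "high")) {
        nm <- paste0("ferteff[", cl, "]")
        if (nm %in% par_info$name) fert_mult[cl] <- exp(par[[nm]])
      }
      for (cl in c("mid", "high")) {
        nm <- paste0("omeff[", cl, "]")
        if (nm %in% par_info$name) om_mult[cl] <- exp(par[[nm]])
      }
    }
    vmax <- if (mm_mode) exp(par[["vmax"]]) else 0
    km <- if (mm_mode) exp(par[["km"]]) else 1
    pred <- vector("list", length(units))
    for (u in seq_along(units)) {
      un <- units[[u]]; fc <- un$forcing
      fS <- lo + (hi - lo) * plogis(par[[un$fs_name]])
      mult <- fc$clteff
      if (!mm_mode)
        mult <- mult * rep(fert_mult[fc$fert_class] *
                             om_mult[fc$om_class], each = 12)
      C0 <- numeric(8)
      C0[i_active] <- fA * fc$initial_soc
      C0[i_slow] <- fS * fc$initial_soc
      C0[i_passive] <- (1 - fA - fS) * fc$initial_soc
      res <- sim_pools_cpp(C0, un$kbase, fc$defac, mult, fc$inputs,
                           un$flow, un$co2, method, mm_mode, vmax, km,
                           ia, is_, im, POOLS)
      tr <- res$trajectory
      pred[[u]] <- tr[fc$obs_idx, i_active] + tr[fc$obs_idx, i_slow] +
        tr[fc$obs_idx, i_passive]
    }
    unlist(pred)
  }

  observed <- meta$observed
  structure(list(par_info = par_info,
                 start = setNames(par_info$start, par_info$name),
                 predict = predict_fun,
                 residuals = function(par) observed - predict_fun(par),
                 observed = observed, meta = meta,
                 n_obs = length(observed),
                 f_s_bounds = c(lo, hi),
                 decay_mode = spec$decay_mode,
                 spec = spec),
            class = "soc_problem")
}

# Forward-difference Jacobian of a residual function (relative step 1e-6).
.num_jacobian <- function(fn, par, rel_step = 1e-6) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (i in seq_along(par)) {
    h <- rel_step * max(1, abs(par[i]))
    p <- par; p[i] <- p[i] + h
    J[, i] <- (fn(p) - f0) / h
  }
  J
}

# Map transformed estimates to the natural scale with delta-method
# derivatives. Returns data.frame(name, estimate, deriv, null).
.natural_scale <- function(par, par_info, f_s_bounds) {
  lo <- f_s_bounds[1]; hi <- f_s_bounds[2]
  est <- deriv <- null <- numeric(nrow(par_info))
  for (i in seq_len(nrow(par_info))) {
    sc <- par_info$scale[i]; x <- par[i]
    if (sc == "logit") {
      est[i] <- lo + (hi - lo) * plogis(x)
      deriv[i] <- (hi - lo) * plogis(x) * (1 - plogis(x))
      null[i] <- 0
    } else if (sc == "log_effect") {
      est[i] <- exp(x); deriv[i] <- exp(x); null[i] <- 1
    } else if (sc == "log") {
      est[i] <- exp(x); deriv[i] <- exp(x); null[i] <- 0
    } else {
      est[i] <- x; deriv[i] <- 1; null[i] <- 0
    }
  }
  data.frame(name = par_info$name, estimate = est, deriv = deriv,
             null = null, stringsAsFactors = FALSE)
}

#' Fit the SOC model to a study by nonlinear least squares
#'
#' Minimizes the pooled sum of squared SOC residuals by Levenberg-Marquardt
#' damped least squares in the transformed parameter space (logit for pool
#' fractions, log for effects and kinetic constants). The parameter
#' covariance is the ordinary nonlinear-least-squares estimate
#' \code{sigma^2 (J'J)^-1} with \code{sigma^2 = SSR/(n - p)}, mapped to the
#' natural scale by the delta method. Each reported effect is tested against
#' its null (1 for exponentiated management effects, 0 otherwise) with a
#' two-sided t test on \code{n - p} degrees of freedom.
#'
#' @param study a \code{soc_study} or a prebuilt \code{soc_problem}
#' @param spec a \code{soc_fit_spec} (ignored when a problem is given)
#' @param maxiter maximum Levenberg-Marquardt iterations
#' @param start optional named starting vector (transformed scale)
#' @return object of class \code{soc_fit}: parameter table with estimates,
#'   standard errors, t and p values; covariance matrices on both scales;
#'   residuals, fitted values, SSR, sigma2, R-squared, convergence info
#' @export
fit_soc <- function(study, spec = NULL, maxiter = 200, start = NULL) {
  problem <- if (inherits(study, "soc_problem")) study
  else build_problem(study, if (is.null(spec)) fit_spec(study) else spec)
  p <- nrow(problem$par_info)
  n <- problem$n_obs
  if (n <= p)
    stop("need more observations (", n, ") than parameters (", p, ")")
  par0 <- if (is.null(start)) problem$start else start[problem$par_info$name]

  res <- minpack.lm::nls.lm(
    par = par0, fn = problem$residuals,
    control = minpack.lm::nls.lm.control(
      maxiter = maxiter, ftol = 1e-10, ptol = 1e-8, maxfev = 100000))
  if (res$info == 5)
    stop("no convergence after ", maxiter, " iterations; best SSR = ",
         signif(res$deviance, 6), " at par = ",
         paste(signif(res$par, 4), collapse = ", "))
  par_hat <- setNames(res$par, problem$par_info$name)

  J <- .num_jacobian(problem$residuals, par_hat)
  JtJ <- crossprod(J)
  ssr <- sum(problem$residuals(par_hat)^2)
  sigma2 <- ssr / (n - p)
  cov_trans <- tryCatch(sigma2 * solve(JtJ), error = function(e) {
    d <- sqrt(diag(JtJ))
    stop("singular J'J; unidentifiable parameter(s): ",
         paste(problem$par_info$name[d < 1e-8 * max(d)], collapse = ", "))
  })
  dimnames(cov_trans) <- list(problem$par_info$name, problem$par_info$name)

  nat <- .natural_scale(par_hat, problem$par_info, problem$f_s_bounds)
  D <- diag(nat$deriv, nrow = p)
  cov_nat <- D %*% cov_trans %*% D
  dimnames(cov_nat) <- dimnames(cov_trans)
  se_nat <- sqrt(pmax(diag(cov_nat), 0))
  tval <- (nat$estimate - nat$null) / se_nat
  pval <- 2 * pt(-abs(tval), df = n - p)

  fitted <- problem$predict(par_hat)
  parameters <- data.frame(
    name = nat$name, kind = problem$par_info$kind,
    transformed = unname(par_hat), estimate = nat$estimate,
    std_error = se_nat, null = nat$null, t = tval, p_value = pval,
    stringsAsFactors = FALSE)
  rownames(parameters) <- parameters$name

  structure(list(parameters = parameters,
                 estimates = setNames(nat$estimate, nat$name),
                 std_errors = setNames(se_nat, nat$name),
                 covariance = cov_nat,
                 cov_transformed = cov_trans,
                 par_transformed = par_hat,
                 residuals = problem$observed - fitted,
                 fitted = fitted, observed = problem$observed,
                 meta = problem$meta,
                 n_obs = n, n_par = p, df = n - p,
                 ssr = ssr, sigma2 = sigma2,
                 r_squared = r_squared(problem$observed, fitted),
                 convergence = list(info = res$info,
                                    message = res$message,
                                    niter = res$niter),
                 problem = problem),
            class = "soc_fit")
}

#' Goodness of fit: squared Pearson correlation
#'
#' @param observed,predicted numeric vectors of equal length (>= 3)
#' @return R-squared in \code{[0, 1]}
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) < 3 || length(observed) != length(predicted))
    stop("need at least 3 paired values")
  if (sd(observed) == 0)
    stop("R-squared undefined for a constant observed vector")
  cor(observed, predicted)^2
}

#' Two-sided t tests of fitted parameters against stated nulls
#'
#' @param fit a \code{soc_fit}
#' @param nulls named vector of null values on the reported (natural)
#'   scale; defaults to the fit's own nulls (1 for exponentiated effects,
#'   0 otherwise)
#' @return data.frame with name, estimate, std_error, null, t, p_value
#' @export
parameter_tests <- function(fit, nulls = NULL) {
  tab <- fit$parameters
  if (!is.null(nulls)) {
    idx <- match(names(nulls), tab$name)
    if (anyNA(idx)) stop("unknown parameter(s): ",
                         paste(names(nulls)[is.na(idx)], collapse = ", "))
    tab$null[idx] <- nulls
  }
  if (any(tab$std_error == 0)) stop("zero standard error")
  tab$t <- (tab$estimate - tab$null) / tab$std_error
  tab$p_value <- 2 * pt(-abs(tab$t), df = fit$df)
  tab[, c("name", "estimate", "std_error", "null", "t", "p_value")]
}

#' @export
print.soc_fit <- function(x, ...) {
  cat("SOC inverse fit:", x$n_obs, "observations,", x$n_par,
      "parameters\n")
  cat("SSR =", signif(x$ssr, 6), " R^2 =", round(x$r_squared, 4), "\n\n")
  tab <- x$parameters[, c("estimate", "std_error", "t", "p_value")]
  print(round(tab, 4))
  invisible(x)
}
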