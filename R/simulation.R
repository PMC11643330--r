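#' AR(1)-style instrument correlation matrix
#'
#' Toeplitz matrix with entry \eqn{(j,k)} equal to \eqn{\rho^{|j-k|}};
#' positive definite for any \eqn{|\rho| < 1}.
#'
#' @param L number of instruments.
#' @param rho correlation parameter, `abs(rho) < 1`.
#' @return an `L x L` correlation matrix.
#' @export
make_sigma_z <- function(L, rho) {
  stopifnot(abs(rho) < 1, L >= 1)
  rho^abs(outer(seq_len(L), seq_len(L), "-"))
}

#' Simulation design for the invalid-instrument benchmark
#'
#' Describes the data-generating process
#' \deqn{Y = X\beta_0 + Z\delta_0 + \epsilon, \qquad X = Z\psi_0 + \mu,}
#' with \eqn{Z \sim N(0, \Sigma_z)}, \eqn{\Sigma_z} the AR(1) correlation
#' [make_sigma_z()], \eqn{(\epsilon, \mu)} bivariate normal, the first
#' `round(invalid_fraction * L)` instruments carrying the direct effect
#' `delta_value`, and every first-stage coefficient equal to `psi_value`.
#' The structural error variance is calibrated analytically so that the
#' invalid-signal SNR \eqn{\delta_0^\top Q_{11}\delta_0/\sigma_\epsilon^2}
#' hits `snr` (see [calibrate_noise_to_snr()]); all other parameters stay
#' at their stated values.
#'
#' @param n sample size per replication.
#' @param L number of candidate instruments.
#' @param invalid_fraction proportion of invalid instruments (default 0.3).
#' @param delta_value direct effect of each invalid instrument (default 0.2).
#' @param psi_value first-stage coefficient (default 0.2).
#' @param beta0 true causal effect (default 0).
#' @param rho instrument correlation parameter.
#' @param sigma_mu2 first-stage error variance (default 1).
#' @param sigma_mu_eps error covariance driving endogeneity (default 0.25).
#' @param snr target signal-to-noise ratio of the invalid signal.
#' @param reps Monte Carlo replications.
#' @param seed master seed; every replication seed is derived from it.
#' @return a list of class `sim_config` including the calibrated
#'   `sigma_eps2`, the (possibly capped) `sigma_mu_eps`, `Sigma_z`, `psi`,
#'   `delta0` and the invalid count `r`.
#' @export
sim_config <- function(n = 1000, L = 10, invalid_fraction = 0.3,
                       delta_value = 0.20, psi_value = 0.20, beta0 = 0,
                       rho = 0, sigma_mu2 = 1, sigma_mu_eps = 0.25,
                       snr = 0.1, reps = 1000, seed) {
  if (missing(seed)) stop("a seed is required")
  r <- round(invalid_fraction * L)
  stopifnot(r >= 0, r < L, snr > 0, sigma_mu2 > 0, reps >= 1)
  cfg <- list(n = as.integer(n), L = as.integer(L),
              invalid_fraction = invalid_fraction,
              delta_value = delta_value, psi_value = psi_value,
              beta0 = beta0, rho = rho, sigma_mu2 = sigma_mu2,
              sigma_mu_eps = sigma_mu_eps, snr = snr,
              reps = as.integer(reps), seed = as.integer(seed),
              r = as.integer(r),
              Sigma_z = make_sigma_z(L, rho),
              psi = rep(psi_value, L),
              delta0 = c(rep(delta_value, r), rep(0, L - r)))
  if (r > 0) {
    s2 <- calibrate_noise_to_snr(cfg)
    cfg$sigma_eps2 <- as.numeric(s2)
    cfg$sigma_mu_eps <- attr(s2, "sigma_mu_eps")
  } else {
    # no invalid instruments: the invalid-signal SNR is undefined, so the
    # structural error variance defaults to 1
    cfg$sigma_eps2 <- 1
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation design: n = %d, L = %d (r = %d invalid), rho = %.2g, SNR = %.3g\n",
              x$n, x$L, x$r, x$rho, x$snr))
  cat(sprintf("  beta0 = %.3g, delta = %.3g, psi = %.3g, sigma_eps2 = %.4g, cov(mu, eps) = %.4g\n",
              x$beta0, x$delta_value, x$psi_value, x$sigma_eps2, x$sigma_mu_eps))
  cat(sprintf("  %d replications, seed %d\n", x$reps, x$seed))
  invisible(x)
}

#' Calibrate the structural error variance to a target SNR
#'
#' Uses the population concentration matrix
#' \eqn{Q = \Sigma_z - \Sigma_z\psi(\psi^\top\Sigma_z\psi)^{-1}
#' \psi^\top\Sigma_z} (the probability limit of \eqn{n^{-1}\dot Z^\top\dot
#' Z}) restricted to the invalid support, and returns
#' \eqn{\sigma_\epsilon^2 = \delta_0^\top Q_{11}\delta_0 / \mathrm{SNR}}.
#' When the implied error correlation
#' \eqn{|\sigma_{\mu\epsilon}|/(\sigma_\mu\sigma_\epsilon)} exceeds 0.99
#' (high SNR targets), the covariance is rescaled to 0.99 of the admissible
#' maximum and a prominent warning is issued -- the joint error distribution
#' would otherwise not exist.
#'
#' @param config a `sim_config` (or a bare list with the same fields).
#' @return the calibrated \eqn{\sigma_\epsilon^2}, with the (possibly
#'   capped) `sigma_mu_eps` as an attribute.
#' @export
calibrate_noise_to_snr <- function(config) {
  Sz <- config$Sigma_z
  psi <- config$psi
  d0 <- config$delta0
  Szp <- drop(Sz %*% psi)
  Q <- Sz - outer(Szp, Szp) / drop(crossprod(psi, Szp))
  S <- which(d0 != 0)
  signal <- if (length(S))
    drop(t(d0[S]) %*% Q[S, S, drop = FALSE] %*% d0[S]) else 0
  if (signal <= 0) stop("invalid-instrument signal is zero; SNR target unattainable")
  sigma_eps2 <- signal / config$snr
  sme <- config$sigma_mu_eps
  cap <- 0.99 * sqrt(config$sigma_mu2 * sigma_eps2)
  if (abs(sme) > cap) {
    warning(sprintf(paste("SNR target %.3g forces error correlation %.3f > 0.99;",
                          "capping cov(mu, eps) at %.4g to keep the error",
                          "covariance positive definite"),
                    config$snr, abs(sme) / sqrt(config$sigma_mu2 * sigma_eps2),
                    sign(sme) * cap), call. = FALSE)
    sme <- sign(sme) * cap
  }
  structure(sigma_eps2, sigma_mu_eps = sme)
}

#' Draw one dataset from the simulation design
#'
#' @param config a [sim_config()].
#' @param rep_seed integer seed for this replication.
#' @return an [iv_data] object.
#' @export
generate_dataset <- function(config, rep_seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n; L <- config$L
  Rz <- chol(config$Sigma_z)
  Se <- matrix(c(config$sigma_eps2, config$sigma_mu_eps,
                 config$sigma_mu_eps, config$sigma_mu2), 2, 2)
  Re <- tryCatch(chol(Se),
                 error = function(e) stop("error covariance is not positive definite"))
  withr::with_seed(rep_seed, {
    Z <- matrix(rnorm(n * L), n, L) %*% Rz
    E <- matrix(rnorm(2 * n), n, 2) %*% Re
  })
  eps <- E[, 1]; mu <- E[, 2]
  X <- drop(Z %*% config$psi) + mu
  Y <- X * config$beta0 + drop(Z %*% config$delta0) + eps
  iv_data(Y, X, Z, labels = paste0("Z", seq_len(L)))
}

# deterministic per-replication seeds derived from the master seed
.rep_seeds <- function(seed, reps) {
  withr::with_seed(seed, sample.int(2147483646L, reps))
}

#' Monte Carlo benchmark of the causal-effect estimators
#'
#' Draws `config$reps` datasets (each from its own derived seed), fits the
#' requested estimators on every replication, and summarizes bias
#' (\eqn{|\mathrm{mean}(\hat\beta) - \beta_0|}), squared-error loss (mean
#' by default, median by flag) and relative efficiency against the
#' best-subset estimator when it is included.
#'
#' @param config a [sim_config()].
#' @param methods character vector from `ols`, `ntsls`, `otsls`, `live`,
#'   `bsive`, `median`, `mode`.
#' @param mse_type `"mean"` (default) or `"median"` squared error.
#' @param re_convention passed to [relative_efficiency()].
#' @param folds CV folds for `live` and `bsive`.
#' @param signed_bias report `mean - beta0` with its sign instead of the
#'   magnitude.
#' @return an object of class `monte_carlo_result`: `estimates`
#'   (reps x methods), `summary` data frame (method, bias, mse, re),
#'   `config`, `elapsed` seconds.
#' @export
run_monte_carlo <- function(config,
                            methods = c("ols", "ntsls"),
                            mse_type = c("mean", "median"),
                            re_convention = "table",
                            folds = 10, signed_bias = FALSE) {
  stopifnot(inherits(config, "sim_config"), config$reps >= 2)
  mse_type <- match.arg(mse_type)
  known <- c("ols", "ntsls", "otsls", "live", "bsive", "median", "mode")
  if (!all(methods %in% known))
    stop("unknown method(s): ", paste(setdiff(methods, known), collapse = ", "))
  seeds <- .rep_seeds(config$seed, config$reps)
  true_invalid <- seq_len(config$r)
  est <- matrix(NA_real_, config$reps, length(methods),
                dimnames = list(NULL, methods))
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(config$reps)) {
    dat <- generate_dataset(config, seeds[i])
    aux_seed <- as.integer((as.numeric(seeds[i]) + 7777) %% 2147483646 + 1)
    for (mth in methods) {
      est[i, mth] <- tryCatch(suppressWarnings(
        switch(mth,
               ols = fit_ols(dat)$beta_hat,
               ntsls = fit_tsls(dat)$beta_hat,
               otsls = fit_tsls(dat, invalid_set = true_invalid,
                                method = "otsls")$beta_hat,
               live = fit_live_cv(dat, folds = folds,
                                  grid_size = 50, seed = aux_seed)$beta_hat,
               bsive = fit_bsiv(dat, r = "cv", solver = "auto",
                                control = dfo_control(seed = aux_seed,
                                                      n_starts = 10),
                                folds = folds)$beta_hat,
               median = median_estimator(wald_ratios(dat))$beta_hat,
               mode = mode_estimator(wald_ratios(dat))$beta_hat)),
        error = function(e) NA_real_)
    }
  }
  fail <- colMeans(is.na(est))
  if (any(fail > 0.05))
    stop(sprintf("method(s) failing on more than 5%% of replications: %s",
                 paste(sprintf("%s (%.0f%%)", methods[fail > 0.05],
                               100 * fail[fail > 0.05]), collapse = ", ")))
  err <- est - config$beta0
  bias <- colMeans(err, na.rm = TRUE)
  if (!signed_bias) bias <- abs(bias)
  mse <- apply(err^2, 2, if (mse_type == "mean") {
    function(v) mean(v, na.rm = TRUE)
  } else {
    function(v) median(v, na.rm = TRUE)
  })
  re <- rep(NA_real_, length(methods))
  if ("bsive" %in% methods)
    re <- vapply(mse, function(mo)
      relative_efficiency(mse[["bsive"]], mo, re_convention), numeric(1))
  structure(list(estimates = est,
                 summary = data.frame(method = methods, bias = bias,
                                      mse = mse, re = re,
                                      row.names = NULL),
                 mse_type = mse_type, config = config,
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "monte_carlo_result")
}

#' @export
print.monte_carlo_result <- function(x, digits = 4, ...) {
  cat(sprintf("Monte Carlo benchmark (%d replications, %.1fs)\n",
              x$config$reps, x$elapsed))
  print(x$config)
  s <- x$summary
  s$bias <- round(s$bias, digits)
  s$mse <- round(s$mse, digits)
  s$re <- round(s$re, 1)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Relative efficiency of two estimators
#'
#' Percentage ratio of squared-error losses. The `"table"` convention
#' (default) reports `100 * mse_bsive / mse_other`, so values above 100
#' mean the comparator beats the best-subset estimator; the `"text"`
#' convention is the reciprocal.
#'
#' @param mse_bsive squared-error loss of the best-subset estimator.
#' @param mse_other squared-error loss of the comparator.
#' @param convention `"table"` or `"text"`.
#' @return the relative efficiency in percent.
#' @export
relative_efficiency <- function(mse_bsive, mse_other,
                                convention = c("table", "text")) {
  convention <- match.arg(convention)
  stopifnot(mse_bsive > 0, mse_other > 0)
  if (convention == "table") 100 * mse_bsive / mse_other
  else 100 * mse_other / mse_bsive
}
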