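#' Sargan over-identification test
#'
#' Tests joint validity of the instruments not declared invalid, under
#' conditional homoskedasticity. The two-stage least-squares structural
#' residuals (with the declared invalid instruments included as controls)
#' are regressed on all instruments; the statistic is \eqn{n R^2}
#' (uncentered \eqn{R^2} when the data carry no intercept), referred to a
#' chi-squared distribution with `L - |invalid_set| - m` degrees of
#' freedom.
#'
#' @param data an [iv_data] object.
#' @param invalid_set instruments treated as invalid (included as outcome
#'   controls); default none.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
sargan_test <- function(data, invalid_set = integer(0)) {
  data <- validate_and_partial(data)
  df <- data$L - length(invalid_set) - data$m
  if (df < 1)
    stop("Sargan test undefined: model is just- or under-identified after conditioning")
  fit <- fit_tsls(data, invalid_set = invalid_set)
  e <- data$Y - drop(data$X %*% matrix(fit$beta_hat)) -
    drop(data$Z %*% fit$delta_hat)
  qz <- qr(data$Z)
  ehat <- qr.fitted(qz, e)
  r2 <- sum(ehat^2) / sum(e^2)
  stat <- data$n * r2
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' First-stage F test of instrument strength
#'
#' F test of the joint nullity of the first-stage coefficients in
#' \eqn{X = Z\psi + \mu} (covariates already partialled out). For a single
#' exposure this is the conventional first-stage F; with several exposures
#' a statistic is reported per exposure column. A noise-free first stage
#' (zero residual) is reported as `Inf`.
#'
#' @param data an [iv_data] object.
#' @return list with `statistic` (length m), `df1 = L`,
#'   `df2 = n - L - p` where `p` is the number of partialled covariates,
#'   and `p_value`.
#' @export
first_stage_F <- function(data) {
  p <- if (is.null(data$covariates)) 0L else ncol(data$covariates)
  data <- validate_and_partial(data)
  qz <- qr(data$Z)
  df2 <- data$n - data$L - p
  stat <- vapply(seq_len(data$m), function(j) {
    x <- data$X[, j]
    res <- x - qr.fitted(qz, x)
    rss <- sum(res^2)
    expl <- sum(x^2) - rss
    if (rss <= .Machine$double.eps * sum(x^2)) return(Inf)
    (expl / data$L) / (rss / df2)
  }, numeric(1))
  list(statistic = stat, df1 = data$L, df2 = df2,
       p_value = pf(stat, data$L, df2, lower.tail = FALSE))
}

#' Signal-to-noise ratio and proportion of variance explained
#'
#' The invalid-instrument signal-to-noise ratio is
#' \eqn{\mathrm{SNR} = \delta_0^\top Q_{11} \delta_0 / \sigma_\epsilon^2},
#' where \eqn{Q = n^{-1}\dot Z^\top \dot Z} and \eqn{Q_{11}} is its
#' submatrix on the invalid support; the proportion of variance explained
#' is \eqn{\mathrm{SNR}/(1+\mathrm{SNR})}.
#'
#' @param delta0 direct-effect vector (length L; zeros mark valid
#'   instruments).
#' @param Zdot transformed instrument matrix \eqn{\dot Z}.
#' @param sigma_eps2 structural error variance (> 0).
#' @return list with `snr` and `pve`.
#' @export
snr_pve <- function(delta0, Zdot, sigma_eps2) {
  stopifnot(sigma_eps2 > 0)
  Zdot <- as.matrix(Zdot)
  stopifnot(length(delta0) == ncol(Zdot))
  S <- which(delta0 != 0)
  snr <- if (!length(S)) 0 else {
    Q11 <- crossprod(Zdot[, S, drop = FALSE]) / nrow(Zdot)
    drop(t(delta0[S]) %*% Q11 %*% delta0[S]) / sigma_eps2
  }
  list(snr = snr, pve = snr / (1 + snr))
}

#' Post-selection inference for a selected invalid set
#'
#' Re-fits two-stage least squares with the fit's selected invalid set
#' treated as known and attaches the resulting standard error and
#' normal-approximation confidence interval to the fit. Selection
#' uncertainty is ignored (naive post-selection inference); a bootstrap
#' alternative for the summary estimators is [bootstrap_ci()].
#'
#' @param data the [iv_data] the fit was computed on.
#' @param fit a `causal_fit` carrying an `invalid_set`.
#' @param level confidence level.
#' @return the fit with updated `se_beta`, `ci_beta`, `level` and
#'   `sigma_eps2_hat`.
#' @export
post_selection_inference <- function(data, fit, level = 0.95) {
  stopifnot(inherits(fit, "causal_fit"))
  ref <- fit_tsls(data, invalid_set = fit$invalid_set, level = level)
  fit$se_beta <- ref$se_beta
  fit$level <- level
  z <- qnorm(1 - (1 - level) / 2)
  fit$ci_beta <- cbind(lower = fit$beta_hat - z * fit$se_beta,
                       upper = fit$beta_hat + z * fit$se_beta)
  fit$sigma_eps2_hat <- ref$sigma_eps2_hat
  fit
}
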