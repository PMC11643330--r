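#' Ordinary least squares comparator
#'
#' Least-squares regression of the outcome on the exposure(s), by default
#' also controlling for every candidate instrument. With the instruments
#' partialled into the design the probability limit of the exposure
#' coefficient is \eqn{\beta_0 + \sigma_{\mu\epsilon}/\sigma_\mu^2}
#' regardless of the instrument correlation structure, i.e. the usual
#' endogeneity bias. Setting `control_instruments = FALSE` regresses the
#' outcome on the exposure(s) alone.
#'
#' @param data an [iv_data] object.
#' @param control_instruments include all instrument columns in the design
#'   (default `TRUE`).
#' @param level confidence level for the asymptotic interval.
#' @return a `causal_fit` with homoskedastic standard errors.
#' @export
fit_ols <- function(data, control_instruments = TRUE, level = 0.95) {
  data <- validate_and_partial(data)
  W <- if (control_instruments) cbind(data$X, data$Z) else data$X
  qw <- qr(W)
  if (qw$rank < ncol(W)) stop("singular design in OLS fit")
  theta <- qr.coef(qw, data$Y)
  e <- data$Y - drop(W %*% theta)
  sigma2 <- sum(e^2) / (data$n - ncol(W))
  XtXinv <- chol2inv(qr.R(qw))
  se <- sqrt(sigma2 * diag(XtXinv))
  m <- data$m
  delta <- if (control_instruments) theta[-seq_len(m)] else numeric(data$L)
  names(delta) <- data$labels
  causal_fit(theta[seq_len(m)], "ols",
             delta_hat = delta,
             invalid_set = if (control_instruments) seq_len(data$L) else integer(0),
             se_beta = se[seq_len(m)], level = level,
             sigma_eps2_hat = sigma2)
}

#' Generalized two-stage least squares with a declared invalid set
#'
#' Fits \eqn{\hat\theta = (W^\top P_Z W)^{-1} W^\top P_Z Y} with
#' \eqn{W = [X, Z_{\mathrm{in}}]}, where \eqn{Z_{\mathrm{in}}} are the
#' instruments declared invalid (included as outcome controls). An empty
#' `invalid_set` gives naive TSLS (all instruments treated as valid); the
#' true invalid set gives the infeasible oracle TSLS benchmark. Standard
#' errors use the homoskedastic asymptotic covariance
#' \eqn{\hat\sigma_\epsilon^2 (W^\top P_Z W)^{-1}} with
#' \eqn{\hat\sigma_\epsilon^2} from the structural residuals
#' \eqn{Y - X\hat\beta - Z_{\mathrm{in}}\hat\delta_{\mathrm{in}}}.
#'
#' @param data an [iv_data] object.
#' @param invalid_set integer indices (or instrument labels) of the
#'   instruments to treat as invalid; default none.
#' @param level confidence level.
#' @param method label stored on the returned fit; defaults to `"ntsls"`
#'   for an empty set and `"tsls"` otherwise.
#' @return a `causal_fit`.
#' @export
fit_tsls <- function(data, invalid_set = integer(0), level = 0.95,
                     method = NULL) {
  data <- validate_and_partial(data)
  if (is.character(invalid_set))
    invalid_set <- match(invalid_set, data$labels)
  invalid_set <- sort(unique(as.integer(invalid_set)))
  if (length(invalid_set) &&
      (min(invalid_set) < 1 || max(invalid_set) > data$L))
    stop("invalid_set indices out of range")
  if (data$L - length(invalid_set) < data$m)
    stop(sprintf(paste("under-identified: %d instruments declared invalid leaves",
                       "fewer than m = %d valid instruments"),
                 length(invalid_set), data$m))
  W <- cbind(data$X, data$Z[, invalid_set, drop = FALSE])
  qz <- qr(data$Z)
  What <- qr.fitted(qz, W)
  qw <- qr(What)
  if (qw$rank < ncol(W)) stop("W' P_Z W is singular; cannot fit TSLS")
  theta <- qr.coef(qw, data$Y)
  e <- data$Y - drop(W %*% theta)
  sigma2 <- sum(e^2) / (data$n - ncol(W))
  V <- sigma2 * chol2inv(qr.R(qw))
  se <- sqrt(diag(V))
  m <- data$m
  delta <- numeric(data$L)
  names(delta) <- data$labels
  delta[invalid_set] <- theta[-seq_len(m)]
  if (is.null(method))
    method <- if (length(invalid_set)) "tsls" else "ntsls"
  causal_fit(theta[seq_len(m)], method,
             delta_hat = delta, invalid_set = invalid_set,
             se_beta = se[seq_len(m)], level = level,
             sigma_eps2_hat = sigma2,
             diagnostics = list(vcov_theta = V))
}
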