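# shared container for all causal-effect estimators
causal_fit <- function(beta_hat, method, delta_hat = NULL, invalid_set = integer(0),
                       se_beta = NA_real_, level = 0.95, sigma_eps2_hat = NA_real_,
                       diagnostics = list(), L = length(delta_hat)) {
  beta_hat <- unname(drop(beta_hat))
  se_beta <- unname(se_beta)
  if (is.null(delta_hat)) delta_hat <- numeric(L)
  z <- qnorm(1 - (1 - level) / 2)
  ci <- if (all(is.finite(se_beta))) {
    cbind(lower = beta_hat - z * se_beta, upper = beta_hat + z * se_beta)
  } else {
    cbind(lower = rep(NA_real_, length(beta_hat)),
          upper = rep(NA_real_, length(beta_hat)))
  }
  structure(
    list(beta_hat = beta_hat, delta_hat = delta_hat,
         invalid_set = sort(unique(as.integer(invalid_set))),
         se_beta = se_beta, ci_beta = ci, level = level,
         sigma_eps2_hat = sigma_eps2_hat, method = method,
         diagnostics = diagnostics),
    class = "causal_fit"
  )
}

#' @export
print.causal_fit <- function(x, ...) {
  cat(sprintf("Causal-effect fit [%s]\n", x$method))
  for (i in seq_along(x$beta_hat)) {
    cat(sprintf("  beta[%d] = %.6g", i, x$beta_hat[i]))
    if (is.finite(x$se_beta[i]))
      cat(sprintf("  (se %.4g, %d%% CI %.4g to %.4g)",
                  x$se_beta[i], round(100 * x$level),
                  x$ci_beta[i, 1], x$ci_beta[i, 2]))
    cat("\n")
  }
  if (length(x$invalid_set)) {
    nm <- names(x$delta_hat)
    lab <- if (!is.null(nm)) nm[x$invalid_set] else x$invalid_set
    cat("  invalid instruments:", paste(lab, collapse = ", "), "\n")
  } else if (x$method %in% c("bsive", "live")) {
    cat("  invalid instruments: none selected\n")
  }
  invisible(x)
}
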