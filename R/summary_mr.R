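#' Per-instrument Wald ratio estimates
#'
#' For a scalar exposure, regresses the exposure and the outcome on each
#' instrument separately (univariate regressions with intercept) and forms
#' the Wald ratio \eqn{\hat\Gamma_j / \hat\gamma_j} of reduced-form to
#' first-stage slope, the one-sample analogue of the summary statistics
#' used by two-sample Mendelian-randomization estimators. Delta-method
#' standard errors treat the two slopes as independent. Instruments whose
#' first-stage slope is numerically zero are flagged unusable (weak) and
#' excluded with a warning.
#'
#' @param data an [iv_data] object with a single exposure column.
#' @return an object of class `ratio_estimates`: list with `gamma_hat`,
#'   `Gamma_hat`, `ratio`, `se_ratio`, logical `usable`, and `labels`.
#' @export
wald_ratios <- function(data) {
  data <- validate_and_partial(data)
  if (data$m != 1)
    stop("summary-statistic estimators are defined for a single exposure (m = 1)")
  x <- drop(data$X)
  y <- data$Y
  n <- data$n
  L <- data$L
  gamma_hat <- Gamma_hat <- se_g <- se_G <- numeric(L)
  for (j in seq_len(L)) {
    z <- data$Z[, j]
    zc <- z - mean(z)
    szz <- sum(zc^2)
    gamma_hat[j] <- sum(zc * x) / szz
    Gamma_hat[j] <- sum(zc * y) / szz
    rx <- x - mean(x) - gamma_hat[j] * zc
    ry <- y - mean(y) - Gamma_hat[j] * zc
    se_g[j] <- sqrt(sum(rx^2) / (n - 2) / szz)
    se_G[j] <- sqrt(sum(ry^2) / (n - 2) / szz)
  }
  usable <- abs(gamma_hat) > sqrt(.Machine$double.eps) * max(sd(x), 1e-12)
  if (any(!usable))
    warning(sprintf("instrument(s) %s have a numerically zero first-stage slope and are excluded as weak",
                    paste(data$labels[!usable], collapse = ", ")))
  ratio <- ifelse(usable, Gamma_hat / gamma_hat, NA_real_)
  # delta method on Gamma/gamma with independent slopes
  se_ratio <- ifelse(usable,
                     sqrt(se_G^2 / gamma_hat^2 +
                            Gamma_hat^2 * se_g^2 / gamma_hat^4),
                     NA_real_)
  structure(list(gamma_hat = gamma_hat, Gamma_hat = Gamma_hat,
                 ratio = ratio, se_ratio = se_ratio, usable = usable,
                 labels = data$labels, L = L),
            class = "ratio_estimates")
}

#' Median estimator over Wald ratios
#'
#' The (optionally inverse-variance weighted) median of the per-instrument
#' ratio estimates; consistent when fewer than half of the instruments are
#' invalid. The unweighted version is the sample median (mean of the two
#' middle ratios for even counts); the weighted version interpolates the
#' 50% point of the weighted empirical CDF of the sorted ratios.
#'
#' @param r a `ratio_estimates` object from [wald_ratios()].
#' @param weighted use inverse-variance weights \eqn{1/\mathrm{se}_j^2}.
#' @return a `causal_fit` with method `"median"`.
#' @export
median_estimator <- function(r, weighted = FALSE) {
  stopifnot(inherits(r, "ratio_estimates"))
  ratios <- r$ratio[r$usable]
  if (!length(ratios)) stop("no usable instrument ratios")
  est <- if (!weighted) {
    median(ratios)
  } else {
    .weighted_median(ratios, 1 / r$se_ratio[r$usable]^2)
  }
  causal_fit(est, "median", L = r$L,
             diagnostics = list(weighted = weighted,
                                n_usable = length(ratios)))
}

# interpolated 50% point of the weighted empirical CDF
.weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  p <- (cumsum(w) - 0.5 * w) / sum(w)
  if (0.5 <= p[1]) return(x[1])
  if (0.5 >= p[length(p)]) return(x[length(x)])
  approx(p, x, xout = 0.5, ties = "ordered")$y
}

#' Mode estimator over Wald ratios
#'
#' Returns the maximizer of a normal-kernel density of the usable ratio
#' estimates over a fixed 512-point grid, reflecting the zero-modal-
#' pleiotropy assumption that the largest cluster of ratios identifies the
#' causal effect. The bandwidth is `bandwidth_factor` times the modified
#' Silverman rule \eqn{0.9\,\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,
#' L_{\mathrm{eff}}^{-1/5}}. Grid ties break toward the smallest grid value.
#'
#' @param r a `ratio_estimates` object.
#' @param bandwidth_factor positive multiplier on the Silverman bandwidth.
#' @param weighted weight each ratio by its inverse variance in the kernel
#'   density (off by default).
#' @return a `causal_fit` with method `"mode"`.
#' @export
mode_estimator <- function(r, bandwidth_factor = 1, weighted = FALSE) {
  stopifnot(inherits(r, "ratio_estimates"), bandwidth_factor > 0)
  ratios <- r$ratio[r$usable]
  if (length(ratios) < 2) {
    if (length(ratios) == 1)
      return(causal_fit(ratios, "mode", L = r$L,
                        diagnostics = list(degenerate = TRUE)))
    stop("mode estimator needs at least one usable ratio")
  }
  if (diff(range(ratios)) == 0)
    return(causal_fit(ratios[1], "mode", L = r$L,
                      diagnostics = list(degenerate = TRUE)))
  h <- .mode_bandwidth(ratios) * bandwidth_factor
  w <- if (weighted) {
    wr <- 1 / r$se_ratio[r$usable]^2
    wr / sum(wr)
  } else {
    rep(1 / length(ratios), length(ratios))
  }
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(g) sum(w * dnorm((g - ratios) / h)) / h,
                 numeric(1))
  est <- grid[which.max(dens)]
  causal_fit(est, "mode", L = r$L,
             diagnostics = list(bandwidth = h, weighted = weighted,
                                n_usable = length(ratios)))
}

.mode_bandwidth <- function(x) {
  s <- sd(x)
  iq <- IQR(x) / 1.34
  spread <- if (iq > 0) min(s, iq) else s
  0.9 * spread * length(x)^(-1 / 5)
}

#' Nonparametric bootstrap confidence interval for summary estimators
#'
#' Resamples observations (rows) with replacement, re-estimates the
#' requested summary estimator on each resample, and returns the percentile
#' interval. The seed is required so that intervals are reproducible.
#'
#' @param data an [iv_data] object (m = 1).
#' @param estimator `"median"` or `"mode"`.
#' @param B number of bootstrap resamples (at least 100).
#' @param level interval level.
#' @param seed integer seed (required).
#' @param ... passed to the estimator (e.g. `weighted`, `bandwidth_factor`).
#' @return numeric vector `c(lower, upper)` with attributes `level`, `B`,
#'   and `estimate` (the full-sample point estimate).
#' @export
bootstrap_ci <- function(data, estimator = c("median", "mode"), B = 500,
                         level = 0.95, seed, ...) {
  estimator <- match.arg(estimator)
  stopifnot(B >= 100)
  if (missing(seed)) stop("a seed is required for the bootstrap")
  data <- validate_and_partial(data)
  fn <- switch(estimator, median = median_estimator, mode = mode_estimator)
  point <- fn(wald_ratios(data), ...)$beta_hat
  est <- withr::with_seed(seed, {
    vapply(seq_len(B), function(i) {
      idx <- sample.int(data$n, data$n, replace = TRUE)
      bd <- iv_data(data$Y[idx], data$X[idx, , drop = FALSE],
                    data$Z[idx, , drop = FALSE], labels = data$labels)
      tryCatch(suppressWarnings(fn(wald_ratios(bd), ...)$beta_hat),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  fail <- mean(is.na(est))
  if (fail > 0.10)
    stop(sprintf("estimator failed on %.0f%% of bootstrap resamples", 100 * fail))
  ci <- quantile(est, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE,
                 names = FALSE)
  structure(c(lower = ci[1], upper = ci[2]),
            level = level, B = B, estimate = point)
}
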