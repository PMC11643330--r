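#' Lasso-type invalid-instrument estimator
#'
#' Solves the l1-penalized concentrated problem
#' \deqn{\hat\delta(\lambda) = \arg\min_\delta \tfrac12\|\dot Y - \dot
#' Z\delta\|_2^2 + \lambda\|\delta\|_1,}
#' the convex surrogate of the best-subset problem, and recovers the causal
#' effect by \eqn{\hat\beta = (\hat X^\top\hat X)^{-1}\hat X^\top(Y -
#' Z\hat\delta)}. The selected invalid set is the support of
#' \eqn{\hat\delta}. The quadratic piece is fitted with `glmnet`
#' (no intercept; columns are not standardized by default, matching
#' instruments on comparable scales), and the stationarity (KKT)
#' conditions are verified on exit.
#'
#' @param data an [iv_data] object.
#' @param lambda nonnegative penalty on the spec objective scale
#'   (\eqn{\tfrac12}RSS \eqn{+ \lambda\|\delta\|_1}). `lambda = 0` with
#'   more instruments than exposures is rejected: the unpenalized
#'   \eqn{\delta} is under-determined.
#' @param standardize scale the transformed instrument columns inside the
#'   Lasso solve (default `FALSE`).
#' @param level confidence level recorded on the fit.
#' @return a `causal_fit` with method `"live"`.
#' @export
fit_live <- function(data, lambda, standardize = FALSE, level = 0.95) {
  stopifnot(lambda >= 0)
  tp <- transform_problem(data)
  if (lambda == 0 && tp$L > tp$m)
    stop("lambda = 0 leaves delta under-determined (L > m); use a positive penalty")
  lambda_max <- max(abs(tp$g))
  if (lambda >= lambda_max) {
    delta <- numeric(tp$L)
  } else {
    delta <- .lasso_solve(tp, lambda, standardize)
    kkt <- tp$g - drop(tp$G %*% delta)
    viol <- max(abs(kkt)) - lambda
    if (viol > 1e-6)
      stop(sprintf("Lasso solve did not reach stationarity (KKT excess %.3g)", viol))
  }
  names(delta) <- tp$labels
  beta <- drop(solve(crossprod(tp$Xhat),
                     crossprod(tp$Xhat, tp$Y - drop(tp$Z %*% delta))))
  causal_fit(beta, "live", delta_hat = delta,
             invalid_set = which(delta != 0), level = level,
             diagnostics = list(lambda = lambda, lambda_max = lambda_max))
}

# glmnet minimizes RSS/(2n) + lambda_g * ||delta||_1, so lambda_g = lambda/n.
# Its path solution is then polished by exact coordinate descent so the
# stationarity conditions hold to tight absolute tolerance on the
# unstandardized problem.
.lasso_solve <- function(tp, lambda, standardize = FALSE) {
  n <- tp$n
  lam_seq <- .lambda_grid(max(abs(tp$g)), floor = lambda, size = 50)
  fit <- glmnet::glmnet(tp$Zdot, tp$Ydot, family = "gaussian",
                        intercept = FALSE, standardize = standardize,
                        lambda = lam_seq / n, thresh = 1e-12)
  # glmnet can return a degenerate single-lambda path when the whole grid is
  # null; coordinate descent then solves from a cold start
  delta <- tryCatch(as.numeric(coef(fit, s = lambda / n))[-1],
                    error = function(e) numeric(ncol(tp$Zdot)))
  .cd_refine(tp$G, tp$g, lambda, delta)
}

# cyclic coordinate descent on 0.5*delta'G delta - g'delta + lambda*||delta||_1
.cd_refine <- function(G, g, lambda, delta, tol = 1e-8, max_sweeps = 5000) {
  L <- length(g)
  dG <- diag(G)
  for (s in seq_len(max_sweeps)) {
    for (j in seq_len(L)) {
      if (dG[j] <= 0) next
      rj <- g[j] - sum(G[j, ] * delta) + dG[j] * delta[j]
      delta[j] <- sign(rj) * max(abs(rj) - lambda, 0) / dG[j]
    }
    kkt <- g - drop(G %*% delta)
    gap <- max(abs(kkt)) - lambda
    act <- abs(delta) > 0
    if (gap <= tol && (!any(act) || max(abs(abs(kkt[act]) - lambda)) <= tol))
      return(delta)
  }
  stop(sprintf("coordinate descent did not converge in %d sweeps (KKT gap %.3g)",
               max_sweeps, gap))
}

# geometric grid from lambda_max down to `floor` (included exactly)
.lambda_grid <- function(lambda_max, floor = 1e-3 * lambda_max, size = 100) {
  floor <- max(floor, 1e-12 * lambda_max)
  exp(seq(log(lambda_max), log(floor), length.out = size))
}

#' Cross-validated penalty selection for the Lasso-type estimator
#'
#' Row-partitioned K-fold cross-validation over a geometric penalty grid
#' running from \eqn{\lambda_{\max} = \|\dot Z^\top\dot Y\|_\infty} (where
#' \eqn{\hat\delta = 0}) down to \eqn{10^{-3}\lambda_{\max}}. Within each
#' fold the projections are rebuilt on the training rows only, and the
#' held-out error is \eqn{\|\dot Y_{\mathrm{test}} - \dot Z_{\mathrm{test}}
#' \hat\delta_{\mathrm{train}}\|_2^2} with the test-side transforms built
#' from the test rows. Ties in the CV curve go to the larger penalty
#' (sparser invalid set).
#'
#' @param data an [iv_data] object.
#' @param folds number of folds (default 10).
#' @param grid_size number of penalty values (default 100).
#' @param seed integer seed for the fold assignment (required).
#' @param standardize passed to the Lasso solve.
#' @return an object of class `lasso_path`: `lambdas` (decreasing),
#'   `delta_path` (L x K full-data coefficients), `cv_error` (K),
#'   `lambda_selected`, `folds`, `seed`.
#' @export
cv_lambda <- function(data, folds = 10, grid_size = 100, seed,
                      standardize = FALSE) {
  stopifnot(folds >= 2)
  if (missing(seed)) stop("a seed is required for the fold assignment")
  tp <- transform_problem(data)
  data <- validate_and_partial(data)
  grid <- .lambda_grid(max(abs(tp$g)), size = grid_size)
  fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(folds), data$n)))
  cv_err <- numeric(length(grid))
  used <- 0L
  for (k in seq_len(folds)) {
    res <- tryCatch({
      tr <- fold_id != k
      dtr <- iv_data(data$Y[tr], data$X[tr, , drop = FALSE],
                     data$Z[tr, , drop = FALSE], labels = data$labels)
      dte <- iv_data(data$Y[!tr], data$X[!tr, , drop = FALSE],
                     data$Z[!tr, , drop = FALSE], labels = data$labels)
      tptr <- transform_problem(dtr)
      tpte <- transform_problem(dte)
      fit <- glmnet::glmnet(tptr$Zdot, tptr$Ydot, family = "gaussian",
                            intercept = FALSE, standardize = standardize,
                            lambda = grid / tptr$n, thresh = 1e-11)
      pred <- predict(fit, newx = tpte$Zdot, s = grid / tptr$n)
      colSums((tpte$Ydot - pred)^2)
    }, error = function(e) {
      warning(sprintf("fold %d skipped: %s", k, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      cv_err <- cv_err + res
      used <- used + 1L
    }
  }
  if (used == 0L) stop("all cross-validation folds failed")
  # grid is decreasing, so the first minimum is the largest lambda
  sel <- grid[which.min(cv_err)]
  full <- glmnet::glmnet(tp$Zdot, tp$Ydot, family = "gaussian",
                         intercept = FALSE, standardize = standardize,
                         lambda = grid / tp$n, thresh = 1e-11)
  delta_path <- as.matrix(coef(full, s = grid / tp$n))[-1, , drop = FALSE]
  rownames(delta_path) <- tp$labels
  structure(list(lambdas = grid, delta_path = delta_path,
                 cv_error = cv_err / used, lambda_selected = sel,
                 folds = folds, folds_used = used, seed = seed),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("Lasso penalty path: %d values in [%.4g, %.4g], %d-fold CV\n",
              length(x$lambdas), min(x$lambdas), max(x$lambdas), x$folds))
  cat(sprintf("  selected lambda = %.6g (%d nonzero direct effects)\n",
              x$lambda_selected,
              sum(x$delta_path[, which(x$lambdas == x$lambda_selected)] != 0)))
  invisible(x)
}

#' Fit the Lasso-type estimator with a cross-validated penalty
#'
#' Convenience wrapper: [cv_lambda()] followed by [fit_live()] at the
#' selected penalty.
#'
#' @inheritParams cv_lambda
#' @param level confidence level recorded on the fit.
#' @return a `causal_fit` with the `lasso_path` in `diagnostics$path`.
#' @export
fit_live_cv <- function(data, folds = 10, grid_size = 100, seed,
                        standardize = FALSE, level = 0.95) {
  path <- cv_lambda(data, folds = folds, grid_size = grid_size, seed = seed,
                    standardize = standardize)
  fit <- fit_live(data, path$lambda_selected, standardize = standardize,
                  level = level)
  fit$diagnostics$path <- path
  fit
}
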