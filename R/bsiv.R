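#' Hard-thresholding operator
#'
#' Keeps the `r` entries of largest absolute value and zeroes the rest;
#' ties break toward the smallest index. This is the exact minimizer of
#' \eqn{\|\delta - \theta\|_2^2} over \eqn{\|\delta\|_0 \le r} and the
#' projection step of the discrete first-order method.
#'
#' @param theta numeric vector.
#' @param r number of entries to retain, `0 <= r <= length(theta)`.
#' @return a vector like `theta` with all but the `r` largest-magnitude
#'   entries set to zero.
#' @export
hard_threshold <- function(theta, r) {
  stopifnot(r >= 0, r <= length(theta))
  if (r == 0) return(numeric(length(theta)))
  if (r == length(theta)) return(theta)
  keep <- order(-abs(theta), seq_along(theta))[seq_len(r)]
  out <- numeric(length(theta))
  out[keep] <- theta[keep]
  out
}

#' Control settings for the discrete first-order solver
#'
#' @param seed integer seed for the random restarts (required; all
#'   randomness in the solver is derived from it).
#' @param tol convergence tolerance on \eqn{\|\delta^{(t+1)} -
#'   \delta^{(t)}\|_2^2}.
#' @param max_iter iteration cap per start.
#' @param n_starts number of initializations (the first is the
#'   hard-thresholded ridge solution, the rest are seeded random sparse
#'   starts).
#' @param polish least-squares refit on the final support (same support,
#'   weakly lower objective).
#' @return a list of class `dfo_control`.
#' @export
dfo_control <- function(seed, tol = 1e-6, max_iter = 1000, n_starts = 50,
                        polish = TRUE) {
  if (missing(seed)) stop("a seed is required for the solver restarts")
  stopifnot(tol > 0, n_starts >= 1, max_iter >= 1)
  structure(list(seed = as.integer(seed), tol = tol,
                 max_iter = as.integer(max_iter),
                 n_starts = as.integer(n_starts), polish = isTRUE(polish)),
            class = "dfo_control")
}

.subset_solution <- function(delta, objective, solver, L, iterations = 0L,
                             certified = FALSE, converged = TRUE,
                             trace = NULL, labels = NULL) {
  w <- as.integer(delta != 0)
  if (!is.null(labels)) names(delta) <- labels
  structure(list(w = w, delta = delta, objective = objective,
                 solver = solver, iterations = iterations,
                 certified_optimal = certified, converged = converged,
                 objective_trace = trace),
            class = "subset_solution")
}

#' @export
print.subset_solution <- function(x, ...) {
  cat(sprintf("Subset solution [%s%s]: %d nonzero, objective %.6g\n",
              x$solver, if (x$certified_optimal) ", certified optimal" else "",
              sum(x$w), x$objective))
  invisible(x)
}

# least-squares refit on a fixed support; support unchanged
.polish_support <- function(tp, delta) {
  S <- which(delta != 0)
  out <- numeric(length(delta))
  if (length(S)) {
    dS <- solve(tp$G[S, S, drop = FALSE], tp$g[S])
    out[S] <- dS
  }
  f <- 0.5 * tp$yy - sum(tp$g * out) + 0.5 * sum(out * (tp$G %*% out))
  list(delta = out, objective = f)
}

#' Discrete first-order solver for the best-subset problem
#'
#' Minimizes the concentrated objective \eqn{f(\delta) = \tfrac12\|\dot Y -
#' \dot Z\delta\|_2^2} subject to \eqn{\|\delta\|_0 \le r} by
#' hard-thresholding projected gradient descent,
#' \deqn{\delta^{(t+1)} = S_r\!\big(\delta^{(t)} - \tfrac{1}{L_c}
#' f'(\delta^{(t)})\big),}
#' with exact step \eqn{1/L_c}, \eqn{L_c = \lambda_{\max}(\dot Z^\top\dot
#' Z)}. The objective sequence is non-increasing and converges; the solver
#' runs `n_starts` seeded initializations and returns the best final
#' iterate, optionally least-squares polished on its support.
#'
#' @param tp an `iv_transform` from [transform_problem()].
#' @param r subset size, `0 <= r <= L - m`.
#' @param control a [dfo_control()] list.
#' @return a `subset_solution`; `certified_optimal` is always `FALSE` for
#'   this solver (use [exact_subset_solve()] for a certificate). The
#'   objective trace of the winning start is attached for monotonicity
#'   checks.
#' @export
dfo_solve <- function(tp, r, control) {
  stopifnot(inherits(tp, "iv_transform"), inherits(control, "dfo_control"))
  if (r < 0 || r > tp$rank_Zdot)
    stop(sprintf("r must lie in 0..%d (L - m) for identification", tp$rank_Zdot))
  L <- tp$L
  if (r == 0)
    return(.subset_solution(numeric(L), 0.5 * tp$yy, "dfo", L,
                            trace = 0.5 * tp$yy, labels = tp$labels))
  ridge <- solve(tp$G + 1e-6 * diag(L), tp$g)
  scale <- max(abs(ridge), 1e-3)
  starts <- vector("list", control$n_starts)
  starts[[1]] <- hard_threshold(ridge, r)
  if (control$n_starts > 1) {
    starts[-1] <- withr::with_seed(control$seed, {
      lapply(seq_len(control$n_starts - 1), function(i) {
        d <- numeric(L)
        d[sample.int(L, r)] <- rnorm(r, sd = scale)
        d
      })
    })
  }
  best <- NULL
  any_converged <- FALSE
  for (d0 in starts) {
    run <- .cpp_dfo(tp$G, tp$g, tp$yy, d0, r, tp$Lc,
                    control$tol, control$max_iter)
    any_converged <- any_converged || run$converged
    if (control$polish) {
      pol <- .polish_support(tp, run$delta)
      run$delta <- pol$delta
      run$objective <- min(run$objective, pol$objective)
    }
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  if (!any_converged)
    warning("discrete first-order solver hit max_iter on every start")
  .subset_solution(drop(best$delta), best$objective, "dfo", L,
                   iterations = best$iterations,
                   converged = best$converged,
                   trace = best$trace, labels = tp$labels)
}

#' Exact best-subset solve by enumeration (or an external MIQO solver)
#'
#' The enumeration backend evaluates the least-squares fit on every size-`r`
#' support (all `choose(L, r)` of them, refused above 1e6) and returns the
#' global minimizer with a certificate. The `miqo` backend is the
#' mixed-integer quadratic formulation of the same problem -- binary support
#' indicators linked to the coefficients by big-M bounds (see
#' [compute_bigM()]) or SOS1 constraints -- and requires an external
#' mixed-integer solver, which this package treats as an optional
#' dependency.
#'
#' @param tp an `iv_transform`.
#' @param r subset size.
#' @param bounds optional `big_m_bounds` (used by the MIQO backend).
#' @param backend `"enumeration"` or `"miqo"`.
#' @return a `subset_solution` with `certified_optimal = TRUE` on success.
#' @export
exact_subset_solve <- function(tp, r, bounds = NULL,
                               backend = c("enumeration", "miqo")) {
  backend <- match.arg(backend)
  stopifnot(inherits(tp, "iv_transform"))
  if (r < 0 || r > tp$rank_Zdot)
    stop(sprintf("r must lie in 0..%d (L - m) for identification", tp$rank_Zdot))
  if (backend == "miqo") {
    if (!requireNamespace("gurobi", quietly = TRUE))
      stop(paste("the 'miqo' backend needs the optional 'gurobi' package",
                 "(a mixed-integer solver), which is not installed;",
                 "use backend = 'enumeration' for a certified solve"))
    stop("MIQO backend not wired to an installed solver in this build")
  }
  if (choose(tp$L, r) > 1e6)
    stop(sprintf("enumeration over choose(%d, %d) supports exceeds the budget; use the miqo backend",
                 tp$L, r))
  run <- .cpp_enum(tp$G, tp$g, tp$yy, r)
  .subset_solution(drop(run$delta), run$objective, "enumeration", tp$L,
                   iterations = as.integer(run$n_supports),
                   certified = TRUE, labels = tp$labels)
}

#' Data-driven big-M coefficient bounds
#'
#' For each coordinate, finds the range of \eqn{\delta_i} compatible with a
#' concentrated objective value no larger than `UB`, along the stationarity
#' path \eqn{\delta(\eta) = (\dot Z^\top\dot Z)^{+}(\dot Z^\top\dot Y +
#' \eta\,\tau_i)}. Because \eqn{\dot Z^\top\dot Z} has rank \eqn{L - m} by
#' construction, the Moore-Penrose pseudoinverse restricts the path to the
#' row space of \eqn{\dot Z}; the closed form is
#' \deqn{h_i^{\pm} = \delta^{\mathrm{ls}}_i \pm \sqrt{2\,(UB -
#' f_{\min})\,[(\dot Z^\top\dot Z)^{+}]_{ii}},}
#' with \eqn{\delta^{\mathrm{ls}}} the least-norm solution and
#' \eqn{f_{\min}} the unconstrained minimum. The bounds
#' \eqn{M_i = \max(|h_i^-|, |h_i^+|)} cover the row-space projection of
#' every feasible \eqn{\delta}; a sparse solution may carry an additional
#' null-space component, so they are coefficient guides for mixed-integer
#' formulations, not hard guarantees on sparse iterates (see the methods
#' vignette).
#'
#' @param tp an `iv_transform`.
#' @param UB upper bound on the optimal objective; any feasible objective
#'   value works (e.g. the [dfo_solve()] objective). Must be at least the
#'   unconstrained minimum.
#' @return an object of class `big_m_bounds`: `M` (per-coordinate), `M1`
#'   (l1 bound, the sum of `M`), `h_minus`, `h_plus`, `UB`, `f_min`.
#' @export
compute_bigM <- function(tp, UB) {
  stopifnot(inherits(tp, "iv_transform"))
  eg <- eigen(tp$G, symmetric = TRUE)
  pos <- eg$values > .rank_tol(rep(tp$L, 2), eg$values[1])
  Gp <- eg$vectors[, pos, drop = FALSE] %*%
    (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
  dls <- drop(Gp %*% tp$g)
  f_min <- 0.5 * tp$yy - 0.5 * sum(tp$g * dls)
  slack <- UB - f_min
  if (slack < -1e-8 * max(1, abs(f_min)))
    stop(sprintf("UB = %.6g is below the unconstrained minimum %.6g; infeasible",
                 UB, f_min))
  slack <- max(slack, 0)
  s <- sqrt(2 * slack * pmax(diag(Gp), 0))
  h_minus <- dls - s
  h_plus <- dls + s
  M <- pmax(abs(h_minus), abs(h_plus))
  structure(list(M = M, M1 = sum(M), h_minus = h_minus, h_plus = h_plus,
                 UB = UB, f_min = f_min, delta_ls = dls),
            class = "big_m_bounds")
}

# pick a backend: enumeration when the support count is small enough to
# certify cheaply, otherwise multi-start descent
.solve_subset <- function(tp, r, solver, control) {
  switch(solver,
         auto = if (choose(tp$L, r) <= 20000)
           exact_subset_solve(tp, r) else dfo_solve(tp, r, control),
         dfo = dfo_solve(tp, r, control),
         enumeration = exact_subset_solve(tp, r),
         miqo = {
           ub <- dfo_solve(tp, r, control)
           exact_subset_solve(tp, r, bounds = compute_bigM(tp, ub$objective),
                              backend = "miqo")
         },
         stop("unknown solver: ", solver))
}

#' Best-subset instrumental-variable estimator
#'
#' Selects the invalid instruments as the size-`r` support minimizing the
#' concentrated least-squares objective, then estimates the causal effect
#' by \eqn{\hat\beta = (\hat X^\top\hat X)^{-1}\hat X^\top(Y -
#' Z\hat\delta)}. With `r = "cv"` the subset size is chosen by K-fold
#' cross-validation over `0..(L - m - 1)` (see [cv_subset_size()]).
#' Standard errors and the confidence interval come from re-fitting
#' two-stage least squares with the selected invalid set treated as known
#' (naive post-selection inference).
#'
#' @param data an [iv_data] object.
#' @param r integer subset size, or `"cv"`.
#' @param solver `"auto"` (enumeration when `choose(L, r) <= 20000`, else
#'   the discrete first-order method), `"dfo"`, `"enumeration"`, or
#'   `"miqo"`.
#' @param control a [dfo_control()]; its seed also drives the CV fold
#'   assignment when `r = "cv"`.
#' @param folds CV folds for subset-size selection.
#' @param level confidence level.
#' @return a `causal_fit` with method `"bsive"`; `diagnostics` records the
#'   subset size, solver, objective, certificate and CV error curve.
#' @export
fit_bsiv <- function(data, r = "cv", solver = c("auto", "dfo", "enumeration", "miqo"),
                     control, folds = 10, level = 0.95) {
  solver <- match.arg(solver)
  if (missing(control)) stop("supply dfo_control(seed = ...) (a seed is required)")
  tp <- transform_problem(data)
  cv_curve <- NULL
  if (identical(r, "cv")) {
    sel <- cv_subset_size(data, folds = folds, seed = control$seed,
                          solver = solver, control = control)
    cv_curve <- attr(sel, "cv_error")
    r <- as.integer(sel)
  }
  r <- as.integer(r)
  sol <- .solve_subset(tp, r, solver, control)
  delta <- sol$delta
  beta <- drop(solve(crossprod(tp$Xhat),
                     crossprod(tp$Xhat, tp$Y - drop(tp$Z %*% delta))))
  support <- which(delta != 0)
  ref <- fit_tsls(validate_and_partial(data), invalid_set = support,
                  level = level, method = "bsive")
  causal_fit(beta, "bsive", delta_hat = delta, invalid_set = support,
             se_beta = ref$se_beta, level = level,
             sigma_eps2_hat = ref$sigma_eps2_hat,
             diagnostics = list(r = r, solver = sol$solver,
                                objective = sol$objective,
                                certified_optimal = sol$certified_optimal,
                                cv_error = cv_curve))
}

#' Cross-validated subset size for the best-subset estimator
#'
#' K-fold cross-validation of the held-out concentrated prediction error
#' \eqn{\|\dot Y_{\mathrm{test}} - \dot Z_{\mathrm{test}}
#' \hat\delta_{\mathrm{train}}(r)\|_2^2} over `r = 0..(L - m - 1)` (at
#' `r = L - m` the training problem interpolates and the causal effect is
#' unidentified). Transforms are rebuilt on the training rows of each fold.
#' Ties go to the smaller `r`; a warning is raised when the selection
#' reaches half the instruments, outside the identification regime of the
#' majority-valid assumption.
#'
#' @inheritParams fit_bsiv
#' @param seed integer fold-assignment seed (required).
#' @param rule `"min"` (default) picks the subset size minimizing the CV
#'   error, as the benchmark design prescribes; `"1se"` picks the smallest
#'   size within one standard error of that minimum, which guards against
#'   the well-known tendency of plain CV argmin to overselect (it keeps a
#'   null design at `r = 0` far more reliably).
#' @return the selected subset size (integer), with the per-size CV error
#'   curve in attribute `"cv_error"`.
#' @export
cv_subset_size <- function(data, folds = 10, seed,
                           solver = c("auto", "dfo", "enumeration", "miqo"),
                           control = NULL, rule = c("min", "1se")) {
  solver <- match.arg(solver)
  rule <- match.arg(rule)
  stopifnot(folds >= 2)
  if (missing(seed)) stop("a seed is required for the fold assignment")
  data <- validate_and_partial(data)
  if (is.null(control)) control <- dfo_control(seed = seed)
  r_grid <- 0:(data$L - data$m - 1)
  fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(folds), data$n)))
  err <- matrix(NA_real_, folds, length(r_grid))
  for (k in seq_len(folds)) {
    res <- tryCatch({
      tr <- fold_id != k
      tptr <- transform_problem(
        iv_data(data$Y[tr], data$X[tr, , drop = FALSE],
                data$Z[tr, , drop = FALSE], labels = data$labels))
      tpte <- transform_problem(
        iv_data(data$Y[!tr], data$X[!tr, , drop = FALSE],
                data$Z[!tr, , drop = FALSE], labels = data$labels))
      vapply(r_grid, function(r) {
        d <- .solve_subset(tptr, r, solver, control)$delta
        sum((tpte$Ydot - drop(tpte$Zdot %*% d))^2)
      }, numeric(1))
    }, error = function(e) {
      warning(sprintf("fold %d skipped: %s", k, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) err[k, ] <- res
  }
  used <- sum(!is.na(err[, 1]))
  if (used == 0L) stop("all cross-validation folds failed")
  mu <- colMeans(err, na.rm = TRUE)
  i_min <- which.min(mu) # ties: first = smallest r
  i_sel <- if (rule == "min" || used < 2) {
    i_min
  } else {
    se <- apply(err, 2, sd, na.rm = TRUE) / sqrt(used)
    which(mu <= mu[i_min] + se[i_min])[1]
  }
  r_sel <- r_grid[i_sel]
  if (r_sel >= data$L / 2)
    warning(sprintf("selected r = %d is at least half of L = %d; outside the majority-valid identification regime",
                    r_sel, data$L))
  structure(as.integer(r_sel), cv_error = stats::setNames(mu, r_grid))
}
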