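# Fixtures are built in code; no data files.

# a transformed problem assembled directly from (Zdot, Ydot), for solver
# tests that do not need the full IV pipeline
fake_transform <- function(Zdot, Ydot, labels = NULL) {
  Zdot <- as.matrix(Zdot)
  G <- crossprod(Zdot)
  structure(
    list(Xhat = NULL, Ydot = Ydot, Zdot = Zdot,
         G = G, g = drop(crossprod(Zdot, Ydot)), yy = sum(Ydot^2),
         Lc = eigen(G, symmetric = TRUE, only.values = TRUE)$values[1],
         rank_Zdot = qr(Zdot)$rank,
         n = nrow(Zdot), m = 0L, L = ncol(Zdot),
         labels = labels %||% paste0("Z", seq_len(ncol(Zdot)))),
    class = "iv_transform")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw an IV dataset directly (outside the calibrated generator), with
# full control over the error terms
draw_iv <- function(n, L, beta0 = 0.5, delta0 = rep(0, L),
                    psi = rep(0.3, L), sd_eps = 1, sd_mu = 1,
                    cov_mu_eps = 0, seed = 1) {
  withr::with_seed(seed, {
    Z <- matrix(rnorm(n * L), n, L)
    e1 <- rnorm(n)
    e2 <- rnorm(n)
  })
  eps <- sd_eps * e1
  mu <- if (sd_eps > 0) {
    (cov_mu_eps / sd_eps^2) * eps +
      sqrt(max(sd_mu^2 - cov_mu_eps^2 / sd_eps^2, 0)) * e2
  } else {
    sd_mu * e2
  }
  X <- drop(Z %*% psi) + mu
  Y <- beta0 * X + drop(Z %*% delta0) + eps
  iv_data(Y, X, Z)
}

# brute-force minimum of ||delta - theta||^2 over ||delta||_0 <= r:
# the off-support mass of the best support
exhaustive_ht_objective <- function(theta, r) {
  if (r == 0) return(sum(theta^2))
  if (r >= length(theta)) return(0)
  min(vapply(utils::combn(length(theta), r, simplify = FALSE),
             function(S) sum(theta[-S]^2), numeric(1)))
}

# power iteration oracle for the largest eigenvalue of Z'Z
power_iter_lmax <- function(Zdot, iters = 2000) {
  G <- crossprod(Zdot)
  v <- rep(1, ncol(G)) / sqrt(ncol(G))
  for (i in seq_len(iters)) {
    v <- drop(G %*% v)
    v <- v / sqrt(sum(v^2))
  }
  drop(t(v) %*% G %*% v)
}

# unconstrained minimum of the concentrated objective over the column
# space of Zdot, via the spectral pseudoinverse
unconstrained_min_obj <- function(tp) {
  eg <- eigen(tp$G, symmetric = TRUE)
  pos <- eg$values > 1e-10 * eg$values[1]
  dls <- eg$vectors[, pos, drop = FALSE] %*%
    (crossprod(eg$vectors[, pos, drop = FALSE], tp$g) / eg$values[pos])
  0.5 * tp$yy - 0.5 * sum(tp$g * dls)
}
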