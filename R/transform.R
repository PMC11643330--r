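#' Concentrate the IV model into a sparse regression in the direct effects
#'
#' Projects the exposures onto the instrument space,
#' \eqn{\hat X = P_Z X}, and forms the transformed outcome and instruments
#' \deqn{\dot Y = M_{\hat X} P_Z Y, \qquad \dot Z = M_{\hat X} Z,}
#' where \eqn{P_A} is the orthogonal projector onto the column space of
#' \eqn{A} and \eqn{M_A = I - P_A}. After this concentration the selection
#' of invalid instruments is the cardinality-constrained least-squares
#' problem \eqn{\min_\delta \tfrac12\|\dot Y - \dot Z\delta\|_2^2} subject
#' to \eqn{\|\delta\|_0 \le r}, and the causal effect is recovered from any
#' \eqn{\hat\delta} by \eqn{\hat\beta = (\hat X^\top\hat X)^{-1}\hat
#' X^\top(Y - Z\hat\delta)}.
#'
#' All projections are computed through QR factorizations; the cross-moment
#' matrices \eqn{G = \dot Z^\top \dot Z} and \eqn{g = \dot Z^\top \dot Y}
#' are cached for the solvers, together with the gradient Lipschitz
#' constant \eqn{L_c = \lambda_{\max}(G)}.
#'
#' @param data an [iv_data] object (validated on the fly if needed).
#' @return An object of class `iv_transform` with elements `Xhat`, `Ydot`,
#'   `Zdot`, `G`, `g`, `yy` (\eqn{\|\dot Y\|^2}), `Lc`, `rank_Zdot`
#'   (\eqn{= L - m}), and the originating `Y`, `X`, `Z`, dimensions and
#'   labels.
#' @export
transform_problem <- function(data) {
  data <- validate_and_partial(data)
  qz <- qr(data$Z)
  Xhat <- qr.fitted(qz, data$X)
  sx <- svd(Xhat, nu = 0, nv = 0)$d
  # rank threshold on the scale of the raw exposure, so an exposure that is
  # (numerically) orthogonal to the instrument space is caught
  sX <- svd(data$X, nu = 0, nv = 0)$d
  if (sum(sx > .rank_tol(dim(Xhat), sX[1])) < data$m)
    stop(paste("identification failure: projected exposure P_Z X is rank",
               "deficient (instruments uncorrelated with some exposure)"))
  qx <- qr(Xhat)
  PzY <- qr.fitted(qz, data$Y)
  Ydot <- drop(.qr_resid_mat(qx, matrix(PzY)))
  Zdot <- .qr_resid_mat(qx, data$Z)
  colnames(Zdot) <- data$labels
  G <- crossprod(Zdot)
  g <- drop(crossprod(Zdot, Ydot))
  Lc <- lipschitz_constant(Zdot, G = G)
  structure(
    list(Xhat = Xhat, Ydot = Ydot, Zdot = Zdot,
         G = G, g = g, yy = sum(Ydot^2), Lc = Lc,
         rank_Zdot = data$L - data$m,
         Y = data$Y, X = data$X, Z = data$Z,
         n = data$n, m = data$m, L = data$L, labels = data$labels),
    class = "iv_transform"
  )
}

#' Gradient Lipschitz constant of the concentrated objective
#'
#' The gradient of \eqn{f(\delta) = \tfrac12\|\dot Y - \dot Z\delta\|^2}
#' is \eqn{-\dot Z^\top(\dot Y - \dot Z\delta)}; its smallest Lipschitz
#' constant is \eqn{\lambda_{\max}(\dot Z^\top \dot Z)}, which sets the
#' \eqn{1/L_c} step of the hard-thresholding descent.
#'
#' @param Zdot transformed instrument matrix.
#' @param G optional precomputed \eqn{\dot Z^\top \dot Z}.
#' @return the largest eigenvalue of \eqn{\dot Z^\top \dot Z}.
#' @export
lipschitz_constant <- function(Zdot, G = NULL) {
  if (is.null(G)) G <- crossprod(as.matrix(Zdot))
  eigen(G, symmetric = TRUE, only.values = TRUE)$values[1]
}
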