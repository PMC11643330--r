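#' Assemble a one-sample instrumental-variable dataset
#'
#' Bundles the outcome, exposure(s), candidate instruments and optional
#' exogenous covariates into a validated container for the estimators in
#' this package. The causal model is
#' \deqn{Y = X \beta_0 + Z \delta_0 + \epsilon, \qquad X = Z \psi_0 + \mu,}
#' where instrument \eqn{j} is *valid* when its direct effect
#' \eqn{\delta_{0j}} on the outcome is zero and *invalid* otherwise.
#'
#' @param Y numeric outcome vector of length `n`.
#' @param X exposure vector or `n x m` matrix of endogenous exposures.
#' @param Z `n x L` matrix of candidate instruments.
#' @param covariates optional `n x p` matrix of exogenous covariates
#'   (an intercept column may be included here); they are partialled out
#'   of `Y`, `X` and `Z` by [validate_and_partial()].
#' @param labels optional character vector of instrument names (length `L`);
#'   defaults to the column names of `Z` or `Z1..ZL`.
#'
#' @return An object of class `iv_data`: a list with elements `Y`, `X`, `Z`,
#'   `covariates`, `labels`, `n`, `m`, `L` and a `validated` flag.
#' @seealso [validate_and_partial()], [transform_problem()]
#' @export
iv_data <- function(Y, X, Z, covariates = NULL, labels = NULL) {
  Y <- as.numeric(Y)
  X <- as.matrix(X)
  Z <- as.matrix(Z)
  storage.mode(X) <- "double"
  storage.mode(Z) <- "double"
  n <- length(Y)
  if (nrow(X) != n || nrow(Z) != n)
    stop("Y, X and Z must have the same number of rows")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != n)
      stop("covariates must have the same number of rows as Y")
  }
  if (anyNA(Y) || anyNA(X) || anyNA(Z) || (!is.null(covariates) && anyNA(covariates)))
    stop("missing values are not allowed; remove or impute incomplete rows first")
  if (is.null(labels)) {
    labels <- colnames(Z)
    if (is.null(labels)) labels <- paste0("Z", seq_len(ncol(Z)))
  }
  if (length(labels) != ncol(Z))
    stop("labels must have one entry per instrument column")
  colnames(Z) <- labels
  structure(
    list(Y = Y, X = X, Z = Z, covariates = covariates, labels = labels,
         n = n, m = ncol(X), L = ncol(Z), validated = FALSE),
    class = "iv_data"
  )
}

#' @export
print.iv_data <- function(x, ...) {
  cat("Instrumental-variable dataset\n")
  cat(sprintf("  n = %d observations, m = %d exposure(s), L = %d candidate instruments\n",
              x$n, x$m, x$L))
  if (!is.null(x$covariates))
    cat(sprintf("  %d exogenous covariate(s)%s\n", ncol(x$covariates),
                if (isTRUE(x$validated)) " (partialled out)" else ""))
  invisible(x)
}

# residuals of each column of A after projecting on the column space held in qr_c
.qr_resid_mat <- function(qr_c, A) {
  A - qr.fitted(qr_c, A)
}

#' Validate an IV dataset and partial out exogenous covariates
#'
#' Checks the identification regime (`n > L + m`), verifies that the
#' instrument matrix has full column rank after removing covariates, and
#' replaces `Y`, `X` and `Z` by their residuals from a least-squares
#' regression on the covariates (Frisch-Waugh residualization). With no
#' covariates the data are returned unchanged apart from the rank checks.
#'
#' @param data an [iv_data] object.
#' @return the validated `iv_data` object, with `validated = TRUE`.
#' @export
validate_and_partial <- function(data) {
  stopifnot(inherits(data, "iv_data"))
  if (isTRUE(data$validated)) return(data)
  if (data$n <= data$L + data$m)
    stop(sprintf(paste("unsupported regime: n = %d observations but L + m = %d;",
                       "the estimators here require n > L + m"),
                 data$n, data$L + data$m))
  if (!is.null(data$covariates)) {
    qc <- qr(data$covariates)
    if (qc$rank < ncol(data$covariates))
      stop("covariate matrix is rank deficient; drop collinear columns")
    data$Y <- drop(.qr_resid_mat(qc, matrix(data$Y)))
    data$X <- .qr_resid_mat(qc, data$X)
    data$Z <- .qr_resid_mat(qc, data$Z)
    colnames(data$Z) <- data$labels
  }
  sv <- svd(data$Z, nu = 0, nv = 0)$d
  tol <- .rank_tol(dim(data$Z), sv[1])
  if (sum(sv > tol) < data$L) {
    qz <- qr(data$Z, LAPACK = FALSE)
    bad <- data$labels[qz$pivot[-seq_len(qz$rank)]]
    stop(sprintf("instrument matrix is rank deficient after covariate partialling; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  data$validated <- TRUE
  data
}
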