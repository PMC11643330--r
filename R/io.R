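#' Read an IV dataset from a CSV file
#'
#' Reads a header-bearing CSV and maps columns to model roles. Missing
#' columns, non-numeric cells and missing values are reported with the
#' offending column (and rows).
#'
#' @param path CSV file path.
#' @param roles a list with entries `outcome` (one column name),
#'   `exposure` (one or more), `instruments` (one or more) and optionally
#'   `covariates`.
#' @param add_intercept add an intercept column to the covariates
#'   (default `TRUE`, so estimates are invariant to location shifts of the
#'   raw columns).
#' @return an [iv_data] object.
#' @export
read_iv_csv <- function(path, roles, add_intercept = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  need <- c("outcome", "exposure", "instruments")
  if (!all(need %in% names(roles)))
    stop("roles must name 'outcome', 'exposure' and 'instruments' columns")
  df <- read.csv(path, check.names = FALSE)
  wanted <- unique(unlist(roles))
  missing_cols <- setdiff(wanted, names(df))
  if (length(missing_cols))
    stop("column(s) not present in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  get_num <- function(cols) {
    m <- as.matrix(df[cols])
    if (!is.numeric(m))
      stop("non-numeric values in column(s): ",
           paste(cols[!vapply(df[cols], is.numeric, logical(1))],
                 collapse = ", "))
    if (anyNA(m)) {
      bad <- which(rowSums(is.na(m)) > 0)
      stop(sprintf("missing values in column(s) %s (rows %s%s)",
                   paste(cols[colSums(is.na(m)) > 0], collapse = ", "),
                   paste(utils::head(bad, 5), collapse = ", "),
                   if (length(bad) > 5) ", ..." else ""))
    }
    m
  }
  covariates <- if (!is.null(roles$covariates))
    get_num(roles$covariates) else NULL
  if (add_intercept)
    covariates <- cbind(`(Intercept)` = rep(1, nrow(df)), covariates)
  iv_data(Y = drop(get_num(roles$outcome)),
          X = get_num(roles$exposure),
          Z = get_num(roles$instruments),
          covariates = covariates,
          labels = roles$instruments)
}

#' Serialize a fit or Monte Carlo result
#'
#' Deterministic JSON or CSV serialization. JSON reports include the method,
#' estimates, selected invalid instruments, any seed found in the object,
#' and the package version; Monte Carlo CSVs have one row per method with
#' bias, squared-error loss and relative efficiency.
#'
#' @param x a `causal_fit` or `monte_carlo_result`.
#' @param path output file path.
#' @param format `"json"` or `"csv"`.
#' @param seed optional seed to echo into the report.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("json", "csv"), seed = NULL) {
  format <- match.arg(format)
  if (inherits(x, "causal_fit")) {
    rep <- list(method = x$method,
                beta_hat = x$beta_hat,
                se_beta = x$se_beta,
                ci_beta = x$ci_beta,
                level = x$level,
                delta_hat = x$delta_hat,
                invalid_set = x$invalid_set,
                invalid_labels = names(x$delta_hat)[x$invalid_set],
                sigma_eps2_hat = x$sigma_eps2_hat,
                seed = seed,
                package_version = as.character(utils::packageVersion("subsetIV")))
    if (format == "json") {
      jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
    } else {
      df <- data.frame(method = x$method, beta_hat = x$beta_hat,
                       se_beta = x$se_beta,
                       ci_lower = x$ci_beta[, 1], ci_upper = x$ci_beta[, 2],
                       n_invalid = length(x$invalid_set),
                       invalid = paste(rep$invalid_labels, collapse = ";"))
      write.csv(df, path, row.names = FALSE)
    }
  } else if (inherits(x, "monte_carlo_result")) {
    cfg <- x$config
    if (format == "csv") {
      df <- cbind(x$summary,
                  n = cfg$n, L = cfg$L, r = cfg$r, rho = cfg$rho,
                  snr = cfg$snr, reps = cfg$reps, seed = cfg$seed,
                  mse_type = x$mse_type)
      write.csv(df, path, row.names = FALSE)
    } else {
      rep <- list(summary = x$summary, mse_type = x$mse_type,
                  config = cfg[c("n", "L", "r", "rho", "snr", "reps", "seed",
                                 "beta0", "delta_value", "psi_value",
                                 "sigma_mu2", "sigma_mu_eps", "sigma_eps2")],
                  seed = if (is.null(seed)) cfg$seed else seed,
                  package_version = as.character(utils::packageVersion("subsetIV")))
      jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, dataframe = "rows", null = "null")
    }
  } else {
    stop("write_results handles 'causal_fit' and 'monte_carlo_result' objects")
  }
  invisible(path)
}
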