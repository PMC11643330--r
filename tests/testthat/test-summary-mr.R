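test_that("noise-free valid instruments give every ratio equal to beta0", {
  d <- draw_iv(80, 5, beta0 = 0.6, sd_eps = 0, sd_mu = 0, seed = 21)
  r <- wald_ratios(d)
  expect_true(all(r$usable))
  expect_equal(r$ratio, rep(0.6, 5), tolerance = 1e-10)
})

test_that("a first-stage-orthogonal instrument is flagged weak and excluded", {
  d <- draw_iv(100, 4, seed = 22)
  # make Z4 exactly orthogonal to X (centered)
  x <- drop(d$X)
  z <- withr::with_seed(220, rnorm(d$n))
  zc <- z - mean(z)
  xc <- x - mean(x)
  d$Z[, 4] <- zc - xc * sum(zc * xc) / sum(xc^2)
  expect_warning(r <- wald_ratios(iv_data(d$Y, d$X, d$Z)), "weak")
  expect_false(r$usable[4])
  expect_identical(sum(r$usable), 3L)
  # estimators run on the remaining three
  expect_silent(median_estimator(r))
})

test_that("delta-method intervals cover the truth for valid instruments", {
  cfg <- suppressWarnings(
    sim_config(n = 1e4, L = 6, invalid_fraction = 0.5, snr = 1,
               reps = 1, seed = 23))
  hits <- 0L; total <- 0L
  seeds <- withr::with_seed(23, sample.int(1e6, 200))
  for (s in seeds) {
    d <- generate_dataset(cfg, s)
    r <- wald_ratios(d)
    j <- 6 # a valid instrument (delta0 = 0 on 4:6)
    hits <- hits + (abs(r$ratio[j] - cfg$beta0) <= 3 * r$se_ratio[j])
    total <- total + 1L
  }
  expect_gte(hits / total, 0.97)
})

test_that("median estimator matches hand values and the weighted CDF oracle", {
  r <- structure(list(ratio = c(0.4, 0.5, 5.0), se_ratio = c(1, 1, 1),
                      usable = rep(TRUE, 3), L = 3L),
                 class = "ratio_estimates")
  expect_equal(median_estimator(r)$beta_hat, 0.5)
  r2 <- structure(list(ratio = c(1, 3), se_ratio = c(1, 1),
                       usable = c(TRUE, TRUE), L = 2L),
                  class = "ratio_estimates")
  expect_equal(median_estimator(r2)$beta_hat, 2)

  # weighted: brute-force interpolation of the weighted CDF
  x <- c(0, 1, 2, 10); w <- c(1, 1, 1, 100)
  r3 <- structure(list(ratio = x, se_ratio = 1 / sqrt(w),
                       usable = rep(TRUE, 4), L = 4L),
                  class = "ratio_estimates")
  p <- (cumsum(w) - w / 2) / sum(w)
  oracle <- approx(p, x, xout = 0.5)$y
  expect_equal(median_estimator(r3, weighted = TRUE)$beta_hat, oracle)
  expect_gt(oracle, 2) # crossing on the heavy 10 side
})

test_that("median estimator bias shrinks with n when under 50% are invalid", {
  bias_at <- function(n) {
    cfg <- sim_config(n = n, L = 10, snr = 1, reps = 1, seed = 24)
    est <- vapply(withr::with_seed(24, sample.int(1e6, 150)), function(s) {
      median_estimator(wald_ratios(generate_dataset(cfg, s)))$beta_hat
    }, numeric(1))
    abs(mean(est) - cfg$beta0)
  }
  expect_lt(bias_at(1000), bias_at(200))
})

test_that("mode estimator matches the dense-grid oracle and handles degeneracy", {
  allsame <- structure(list(ratio = rep(0.7, 4), se_ratio = rep(1, 4),
                            usable = rep(TRUE, 4), L = 4L),
                       class = "ratio_estimates")
  expect_equal(mode_estimator(allsame)$beta_hat, 0.7)

  cluster <- structure(list(ratio = c(0.5, 0.5, 0.5, 3.0),
                            se_ratio = rep(1, 4),
                            usable = rep(TRUE, 4), L = 4L),
                       class = "ratio_estimates")
  fit <- mode_estimator(cluster, bandwidth_factor = 0.3)
  h <- fit$diagnostics$bandwidth
  grid_step <- (3 - 0.5 + 6 * h) / 511
  expect_equal(fit$beta_hat, 0.5, tolerance = grid_step + 1e-12)

  # symmetric pair: grid argmax with first-max tie-break sits on the low mode;
  # independent dense-grid oracle
  sym <- structure(list(ratio = c(-1, 1), se_ratio = c(1, 1),
                        usable = c(TRUE, TRUE), L = 2L),
                   class = "ratio_estimates")
  fit2 <- mode_estimator(sym)
  h2 <- fit2$diagnostics$bandwidth
  dense <- seq(-1 - 3 * h2, 1 + 3 * h2, length.out = 50001)
  dd <- vapply(dense, function(g) sum(dnorm((g - c(-1, 1)) / h2)), numeric(1))
  oracle <- dense[which.max(dd)]
  expect_lt(fit2$beta_hat, 0) # low-side mode under the tie rule
  expect_equal(fit2$beta_hat, oracle,
               tolerance = (2 + 6 * h2) / 511 + 1e-6)
})

test_that("summary estimators are invariant to instrument ordering", {
  d <- draw_iv(300, 6, beta0 = 0.4, delta0 = c(0.5, 0.3, 0, 0, 0, 0), seed = 26)
  perm <- c(4, 1, 6, 2, 5, 3)
  dp <- iv_data(d$Y, d$X, d$Z[, perm])
  r <- wald_ratios(d); rp <- wald_ratios(dp)
  expect_equal(median_estimator(r)$beta_hat, median_estimator(rp)$beta_hat)
  expect_equal(mode_estimator(r)$beta_hat, mode_estimator(rp)$beta_hat)
})

test_that("bootstrap intervals are seeded, bracketing, and degenerate without noise", {
  d <- draw_iv(150, 5, beta0 = 0.5, delta0 = c(0.4, 0, 0, 0, 0), seed = 27)
  ci1 <- bootstrap_ci(d, "median", B = 200, seed = 7)
  ci2 <- bootstrap_ci(d, "median", B = 200, seed = 7)
  expect_identical(ci1, ci2)
  est <- attr(ci1, "estimate")
  expect_true(ci1["lower"] <= est && est <= ci1["upper"])
  expect_error(bootstrap_ci(d, "median", B = 200), "seed")

  dnf <- draw_iv(150, 5, beta0 = 0.5, sd_eps = 0, sd_mu = 0, seed = 28)
  cinf <- bootstrap_ci(dnf, "median", B = 100, seed = 8)
  expect_equal(unname(cinf["lower"]), 0.5, tolerance = 1e-10)
  expect_equal(unname(cinf["upper"]), 0.5, tolerance = 1e-10)
})
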