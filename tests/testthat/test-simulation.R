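test_that("the instrument correlation matrix follows the AR(1) form", {
  expect_equal(make_sigma_z(4, 0), diag(4))
  expect_equal(make_sigma_z(3, 0.5),
               matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3, 3))
  for (rho in c(-0.9, -0.3, 0.25, 0.75)) {
    expect_silent(chol(make_sigma_z(12, rho)))
  }
})

test_that("noise calibration matches the hand-computed concentration matrix", {
  # rho = 0, L = 10, r = 3, delta = psi = 0.2:
  # Q11 = I_3 - 0.1 J_3, signal = 0.04 * (3 - 0.1 * 9) = 0.084
  cfg <- sim_config(n = 100, L = 10, rho = 0, snr = 0.1, reps = 1, seed = 61)
  expect_equal(cfg$sigma_eps2, 0.84, tolerance = 1e-12)
  # snr equal to the signal itself gives sigma_eps2 = 1
  cfg1 <- sim_config(n = 100, L = 10, rho = 0, snr = 0.084, reps = 1, seed = 61)
  expect_equal(cfg1$sigma_eps2, 1, tolerance = 1e-12)
  # monotone decreasing in the target
  s2 <- vapply(c(0.1, 0.25, 1, 2, 6), function(snr)
    suppressWarnings(sim_config(n = 100, L = 10, snr = snr, reps = 1,
                                seed = 61)$sigma_eps2), numeric(1))
  expect_true(all(diff(s2) < 0))
})

test_that("infeasible error correlations are capped with a warning", {
  expect_warning(cfg <- sim_config(n = 100, L = 10, rho = 0, snr = 6,
                                   reps = 1, seed = 62),
                 "capping")
  expect_equal(abs(cfg$sigma_mu_eps),
               0.99 * sqrt(cfg$sigma_mu2 * cfg$sigma_eps2), tolerance = 1e-12)
  expect_silent(chol(matrix(c(cfg$sigma_eps2, cfg$sigma_mu_eps,
                              cfg$sigma_mu_eps, cfg$sigma_mu2), 2, 2)))
})

test_that("generated data reproduce the design moments", {
  cfg <- sim_config(n = 1e5, L = 6, rho = 0.5, snr = 0.25, reps = 1, seed = 63)
  d1 <- generate_dataset(cfg, 999)
  d2 <- generate_dataset(cfg, 999)
  expect_identical(d1$Y, d2$Y) # byte-identical under the same seed
  expect_identical(d1$Z, d2$Z)
  expect_equal(cor(d1$Z[, 1], d1$Z[, 2]), 0.5, tolerance = 0.01)
  expect_equal(cor(d1$Z[, 1], d1$Z[, 3]), 0.25, tolerance = 0.015)
  mu <- drop(d1$X) - drop(d1$Z %*% cfg$psi)
  eps <- d1$Y - drop(d1$X %*% matrix(cfg$beta0)) - drop(d1$Z %*% cfg$delta0)
  expect_equal(stats::cov(mu, eps), cfg$sigma_mu_eps, tolerance = 0.02)
  expect_equal(var(eps), cfg$sigma_eps2, tolerance = 0.05 * cfg$sigma_eps2)
})

test_that("the Monte Carlo harness is exactly reproducible and equivariant", {
  cfg <- sim_config(n = 300, L = 8, rho = 0.25, snr = 1, reps = 5, seed = 64)
  r1 <- run_monte_carlo(cfg, methods = c("ols", "ntsls", "otsls"))
  r2 <- run_monte_carlo(cfg, methods = c("ols", "ntsls", "otsls"))
  expect_identical(r1$estimates, r2$estimates)
  expect_identical(r1$summary, r2$summary)

  # shifting beta0 shifts every oracle-TSLS estimate by exactly the shift
  cfg_b <- sim_config(n = 300, L = 8, rho = 0.25, snr = 1, reps = 5, seed = 64,
                      beta0 = 1)
  r_b <- run_monte_carlo(cfg_b, methods = c("otsls"))
  expect_equal(unname(r_b$estimates[, "otsls"] - 1),
               unname(r1$estimates[, "otsls"]), tolerance = 1e-10)
  expect_equal(r_b$summary$bias[1], r1$summary$bias[3], tolerance = 1e-10)
})

test_that("mean and median squared-error conventions both work", {
  cfg <- suppressWarnings(
    sim_config(n = 200, L = 6, rho = 0, snr = 1, reps = 11, seed = 65))
  rmean <- run_monte_carlo(cfg, methods = "ntsls")
  rmed <- run_monte_carlo(cfg, methods = "ntsls", mse_type = "median")
  err2 <- (rmean$estimates[, 1] - cfg$beta0)^2
  expect_equal(rmean$summary$mse, mean(err2))
  expect_equal(rmed$summary$mse, median(err2))
})

test_that("relative efficiency follows both conventions", {
  expect_equal(relative_efficiency(0.0241, 0.0166, "table"),
               100 * 0.0241 / 0.0166)
  expect_equal(relative_efficiency(0.0241, 0.0166, "text"),
               100 * 0.0166 / 0.0241)
  expect_equal(relative_efficiency(0.3, 0.3, "table"), 100)
  expect_equal(relative_efficiency(0.3, 0.3, "text"), 100)
})

test_that("a method failing on too many replications aborts with a diagnostic", {
  cfg <- suppressWarnings(
    sim_config(n = 40, L = 6, rho = 0, snr = 1, reps = 4, seed = 66))
  # n = 40 with L = 10-fold CV leaves folds below the n > L + m regime
  expect_error(run_monte_carlo(cfg, methods = "live"), "failing")
})
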