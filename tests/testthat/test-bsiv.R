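test_that("hard thresholding matches hand examples and boundary cases", {
  expect_equal(hard_threshold(c(0.5, -2, 1), 2), c(0, -2, 1))
  th <- withr::with_seed(41, rnorm(6))
  expect_equal(hard_threshold(th, 0), numeric(6))
  expect_equal(hard_threshold(th, 6), th)
  # ties toward the smallest index
  expect_equal(hard_threshold(c(1, -1, 1), 2), c(1, -1, 0))
})

test_that("hard thresholding attains the exhaustive-support minimum", {
  for (i in 1:20) {
    th <- withr::with_seed(400 + i, rnorm(8))
    for (r in 0:8) {
      ht <- hard_threshold(th, r)
      expect_equal(sum((ht - th)^2), exhaustive_ht_objective(th, r),
                   tolerance = 1e-12)
      expect_lte(sum(ht != 0), r)
    }
  }
})

test_that("descent solves the separable toy problem and r = 0 shortcut", {
  tp <- fake_transform(diag(3), c(3, 1, -2))
  sol <- dfo_solve(tp, 1, dfo_control(seed = 1, n_starts = 3))
  expect_equal(unname(sol$delta), c(3, 0, 0))
  expect_equal(sol$objective, 2.5)
  ex <- exact_subset_solve(tp, 1)
  expect_equal(ex$objective, 2.5)
  expect_true(ex$certified_optimal)

  sol0 <- dfo_solve(tp, 0, dfo_control(seed = 1))
  expect_equal(unname(sol0$delta), numeric(3))
  expect_equal(sol0$objective, 0.5 * sum(c(3, 1, -2)^2))
  expect_identical(sol0$iterations, 0L)
})

test_that("objective sequences are monotone non-increasing along the iterates", {
  for (i in 1:50) {
    Zd <- withr::with_seed(500 + i, matrix(rnorm(30 * 7), 30, 7))
    y <- withr::with_seed(600 + i, rnorm(30))
    tp <- fake_transform(Zd, y)
    sol <- dfo_solve(tp, 3, dfo_control(seed = i, n_starts = 2))
    tr <- sol$objective_trace
    expect_true(all(diff(tr) <= 1e-12 * max(1, tr[1])))
  }
})

test_that("enumeration certifies and never exceeds the descent objective", {
  matched <- 0L; total <- 0L
  for (i in 1:60) {
    n <- 40; L <- 4L + (i %% 7L)
    Zd <- withr::with_seed(700 + i, matrix(rnorm(n * L), n, L))
    y <- withr::with_seed(800 + i, rnorm(n))
    tp <- fake_transform(Zd, y)
    r <- i %% L
    dfo <- dfo_solve(tp, r, dfo_control(seed = i, n_starts = 10))
    ex <- exact_subset_solve(tp, r)
    expect_lte(ex$objective, dfo$objective + 1e-9 * max(1, dfo$objective))
    expect_lte(sum(ex$delta != 0), r)
    expect_lte(sum(dfo$delta != 0), r)
    total <- total + 1L
    if (abs(ex$objective - dfo$objective) <= 1e-6 * max(1, ex$objective))
      matched <- matched + 1L
  }
  message(sprintf("descent matched the certified optimum on %d/%d instances",
                  matched, total))
  expect_gt(matched / total, 0.5)
})

test_that("optimal objective is non-increasing in the subset size", {
  d <- draw_iv(120, 8, beta0 = 0.3, delta0 = c(0.4, -0.2, 0.1, rep(0, 5)),
               seed = 42)
  tp <- transform_problem(d)
  objs <- vapply(0:tp$rank_Zdot, function(r) exact_subset_solve(tp, r)$objective,
                 numeric(1))
  expect_true(all(diff(objs) <= 1e-9))
  # at r = L - m the concentrated problem attains the unconstrained minimum
  expect_equal(objs[length(objs)], unconstrained_min_obj(tp), tolerance = 1e-8)
})

test_that("big-M bounds match the orthonormal closed form and zero-slack case", {
  Q <- qr.Q(qr(withr::with_seed(43, matrix(rnorm(30 * 5), 30, 5))))
  y <- withr::with_seed(44, rnorm(30))
  tp <- fake_transform(Q, y)
  f_min <- 0.5 * tp$yy - 0.5 * sum(tp$g^2)
  UB <- f_min + 0.7
  bm <- compute_bigM(tp, UB)
  s <- sqrt(2 * (UB - f_min))
  expect_equal(bm$h_minus, tp$g - s, tolerance = 1e-8)
  expect_equal(bm$h_plus, tp$g + s, tolerance = 1e-8)
  expect_true(all(bm$M > 0))
  expect_gte(bm$M1, max(bm$M))

  bm0 <- compute_bigM(tp, f_min)
  expect_equal(bm0$M, abs(tp$g), tolerance = 1e-8) # least-norm coordinates
  expect_error(compute_bigM(tp, f_min - 1), "infeasible")
})

test_that("big-M bounds cover the row-space projection of the certified optimum", {
  for (i in 1:15) {
    d <- draw_iv(150, 7, beta0 = 0.4,
                 delta0 = c(0.5, -0.3, rep(0, 5)), cov_mu_eps = 0.25,
                 seed = 900 + i)
    tp <- transform_problem(d)
    ex <- exact_subset_solve(tp, 2)
    bm <- compute_bigM(tp, ex$objective)
    # project the sparse optimum onto the row space of Zdot
    sv <- svd(tp$Zdot)
    keep <- sv$d > 1e-8 * sv$d[1]
    V <- sv$v[, keep, drop = FALSE]
    proj <- drop(V %*% crossprod(V, ex$delta))
    expect_true(all(abs(proj) <= bm$M + 1e-7))
  }
})

test_that("the best-subset fit collapses to naive TSLS at r = 0", {
  d <- draw_iv(200, 6, beta0 = 0.4, delta0 = c(0.5, 0.2, rep(0, 4)), seed = 45)
  fit <- fit_bsiv(d, r = 0, control = dfo_control(seed = 3))
  expect_equal(fit$beta_hat, fit_tsls(d)$beta_hat, tolerance = 1e-10)
  expect_identical(fit$invalid_set, integer(0))
})

test_that("noise-free data yield exact recovery of effect and invalid set", {
  delta0 <- c(0.4, -0.3, 0.25, rep(0, 7))
  d <- draw_iv(300, 10, beta0 = 0.8, delta0 = delta0, sd_eps = 0, seed = 46)
  fit <- fit_bsiv(d, r = 3, solver = "enumeration",
                  control = dfo_control(seed = 4))
  expect_equal(fit$beta_hat, 0.8, tolerance = 1e-8)
  expect_identical(fit$invalid_set, 1:3)
  expect_equal(unname(fit$delta_hat), delta0, tolerance = 1e-8)
})

test_that("true support is recovered on strong-signal simulated data", {
  cfg <- suppressWarnings(
    sim_config(n = 5000, L = 10, rho = 0, snr = 6, reps = 1, seed = 47))
  hits <- 0L
  seeds <- withr::with_seed(47, sample.int(1e6, 40))
  for (s in seeds) {
    d <- generate_dataset(cfg, s)
    fit <- fit_bsiv(d, r = 3, control = dfo_control(seed = s, n_starts = 10))
    hits <- hits + identical(fit$invalid_set, 1:3)
  }
  expect_gte(hits / length(seeds), 0.95)
})

test_that("subset-size cross-validation is seeded and sane on null and strong designs", {
  cfg0 <- sim_config(n = 2000, L = 10, invalid_fraction = 0, reps = 1, seed = 48)
  d0 <- generate_dataset(cfg0, 481)
  s1 <- suppressWarnings(cv_subset_size(d0, seed = 5))
  s2 <- suppressWarnings(cv_subset_size(d0, seed = 5))
  expect_identical(as.integer(s1), as.integer(s2))

  # null design: the 1-SE rule keeps r = 0 almost always, the plain argmin
  # modally
  seeds <- withr::with_seed(48, sample.int(1e6, 40))
  sel_min <- sel_1se <- integer(0)
  for (s in seeds) {
    d <- generate_dataset(cfg0, s)
    sel_min <- c(sel_min, suppressWarnings(cv_subset_size(d, seed = s)))
    sel_1se <- c(sel_1se, suppressWarnings(cv_subset_size(d, seed = s,
                                                          rule = "1se")))
  }
  expect_gte(mean(sel_1se == 0), 0.90)
  expect_identical(as.integer(names(which.max(table(sel_min)))), 0L)

  # strong signal: modal selection is the true r = 3
  cfg6 <- suppressWarnings(
    sim_config(n = 1000, L = 10, rho = 0, snr = 6, reps = 1, seed = 49))
  sel6 <- vapply(withr::with_seed(49, sample.int(1e6, 40)), function(s) {
    as.integer(suppressWarnings(cv_subset_size(generate_dataset(cfg6, s),
                                               seed = s)))
  }, integer(1))
  expect_identical(as.integer(names(which.max(table(sel6)))), 3L)
})

test_that("the MIQO backend names its optional solver dependency", {
  tp <- fake_transform(diag(3), c(1, 2, 3))
  expect_error(exact_subset_solve(tp, 1, backend = "miqo"), "gurobi")
})
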