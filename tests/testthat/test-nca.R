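test_that("Cmax/Tmax: maximum quantifiable concentration, ties to earliest time", {
  p <- make_profile(c(0.083, 0.25, 0.5, 1), c(10, 728, 300, 100))
  expect_equal(find_cmax_tmax(p), list(cmax = 728, tmax = 0.25))

  tie <- make_profile(c(0.25, 0.5, 1, 2), c(5, 7, 7, 2))
  expect_equal(find_cmax_tmax(tie), list(cmax = 7, tmax = 0.5))

  mono <- make_profile(c(1, 2, 3), c(9, 4, 1))
  expect_equal(find_cmax_tmax(mono), list(cmax = 9, tmax = 1))
})

test_that("trapezoidal AUC: rectangle, triangle with trailing zero, log-down closed form", {
  # flat profile: rectangle area
  expect_equal(auc_0_t(make_profile(c(0, 1, 2), c(10, 10, 10)))$auc, 20)
  # rise then censored tail: only the triangle up to tlast counts
  tri <- conc_profile("S", "A", c(0, 1, 2), c(0, 10, 0),
                      blq = c(TRUE, FALSE, TRUE), lloq = 0.5)
  expect_equal(auc_0_t(tri)$auc, 5)
  # log-down segment: (C1-C2)*dt/ln(C1/C2), linear on the rising part
  p <- make_profile(c(0.5, 1, 2), c(10, 10, 5))
  expect_equal(auc_0_t(p, "linuplogdown")$auc, 5 + (10 - 5) / log(2))
  # cross-check the log trapezoid against fine-grid numeric integration of
  # the fitted exponential over [1, 2]
  tt <- seq(1, 2, by = 1e-4)
  k <- log(10 / 5)
  fine <- sum(diff(tt) * (head(10 * exp(-k * (tt - 1)), -1) +
                            tail(10 * exp(-k * (tt - 1)), -1)) / 2)
  expect_equal(auc_0_t(p, "linuplogdown")$auc - 5, fine, tolerance = 1e-6)
})

test_that("linear AUC is invariant under inserting a collinear midpoint", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      n <- sample(4:9, 1)
      times <- sort(runif(n, 0, 24))
      concs <- runif(n, 1, 100)
      base <- auc_0_t(make_profile(times, concs))
      i <- sample(n - 1, 1)
      tm <- (times[i] + times[i + 1]) / 2
      cm <- (concs[i] + concs[i + 1]) / 2
      aug <- auc_0_t(make_profile(sort(c(times, tm)), append(concs, cm, after = i)))
      expect_equal(aug$auc, base$auc, tolerance = 1e-12)
    }
  })
})

test_that("lambda-z: exact exponential recovered to machine precision, any window", {
  times <- c(0.5, 4, 8, 12, 24)
  concs <- c(150, 100 * exp(-0.5 * c(4, 8, 12, 24)))   # peak first, then decay
  f <- fit_lambda_z(make_profile(times, concs))
  expect_equal(f$lambda_z, 0.5, tolerance = 1e-12)
  expect_equal(f$adj_r2, 1, tolerance = 1e-12)
  expect_equal(f$n_points, 4)                          # tie resolved to all points

  # declining-only profile: the peak itself joins the fit
  g <- fit_lambda_z(make_profile(c(4, 8, 12, 24), 100 * exp(-0.5 * c(4, 8, 12, 24))))
  expect_equal(g$lambda_z, 0.5, tolerance = 1e-12)
  expect_equal(g$n_points, 4)
})

test_that("lambda-z error taxonomy: no decline vs too few points", {
  expect_error(fit_lambda_z(make_profile(c(1, 2, 3, 4), c(1, 2, 4, 8))),
               class = "herbipk_terminal_phase_not_estimable")
  expect_error(fit_lambda_z(make_profile(c(1, 2, 3, 4), c(1, 9, 5, 3))),
               class = "herbipk_insufficient_data")
})

test_that("lambda-z matches the exhaustive-window lm() oracle on a noisy fixture", {
  withr::with_seed(314, {
    rp <- random_decay_profile(n = 9)
    f <- fit_lambda_z(make_profile(rp$times, rp$concs))
    o <- oracle_lambda_z(rp$times, rp$concs)
    expect_equal(f$lambda_z, o$lambda, tolerance = 1e-10)
    expect_equal(f$n_points, o$n)
    expect_equal(f$t_first, o$t_first)
  })
})

test_that("run_nca reproduces the exact-halving hand computation", {
  p <- make_profile(c(1, 2, 3), c(10, 5, 2.5), dose = 1)
  r <- run_nca(p)
  expect_equal(r$cmax, 10)
  expect_equal(r$tmax, 1)
  expect_equal(r$lambda_fit$lambda_z, log(2), tolerance = 1e-12)
  expect_equal(r$t_half, 1)
  expect_equal(r$auc_0_t, 11.25)
  expect_equal(r$auc_0_inf, 11.25 + 2.5 / log(2), tolerance = 1e-12)
  expect_equal(r$aumc_0_t, 18.75)
  expect_equal(r$aumc_0_inf, 18.75 + 2.5 * 3 / log(2) + 2.5 / log(2)^2,
               tolerance = 1e-12)
  expect_equal(r$mrt_0_inf, r$aumc_0_inf / r$auc_0_inf)
  expect_equal(r$pct_extrapolated, 100 * (1 - r$auc_0_t / r$auc_0_inf))
  # dose 1 mg/kg, AUC in ng*h/mL -> CL in L/h/kg carries the 1e3 factor
  expect_equal(r$clz_f, 1 / r$auc_0_inf * 1000)
  expect_equal(r$vz_f, r$clz_f / log(2))
})

test_that("terminal-phase failure flags *_inf parameters missing, keeps AUC0-t", {
  p <- make_profile(c(1, 2, 3, 4), c(1, 9, 5, 3))   # 2 post-peak points only
  r <- run_nca(p)
  expect_equal(r$auc_0_t, oracle_nca(c(1, 2, 3, 4), c(1, 9, 5, 3))$auc_0_t)
  expect_true(is.na(r$auc_0_inf) && is.na(r$t_half) && is.na(r$mrt_0_inf) &&
                is.na(r$vz_f) && is.na(r$clz_f))
  expect_match(r$lambda_z_error, "post-Tmax")
})

test_that("run_nca agrees with the explicit brute-force oracle on random profiles", {
  withr::with_seed(2718, {
    for (rep in 1:40) {
      rp <- random_decay_profile(n = sample(6:10, 1))
      r <- run_nca(make_profile(rp$times, rp$concs))
      o <- oracle_nca(rp$times, rp$concs)
      expect_equal(r$auc_0_t, o$auc_0_t, tolerance = 1e-10)
      expect_equal(r$aumc_0_t, o$aumc_0_t, tolerance = 1e-10)
      if (!is.null(o$lambda)) {
        expect_equal(r$auc_0_inf, o$auc_0_inf, tolerance = 1e-8)
        expect_equal(r$t_half, o$t_half, tolerance = 1e-8)
        expect_true(r$auc_0_inf >= r$auc_0_t)
        expect_true(r$pct_extrapolated >= 0 && r$pct_extrapolated < 100)
      }
    }
  })
})

test_that("scaling concentrations scales exposure, not times or half-life", {
  withr::with_seed(99, {
    rp <- random_decay_profile(n = 8)
    r1 <- run_nca(make_profile(rp$times, rp$concs, dose = 100))
    r2 <- run_nca(make_profile(rp$times, rp$concs / 2, dose = 100))
    expect_equal(r2$auc_0_t, r1$auc_0_t / 2)
    expect_equal(r2$auc_0_inf, r1$auc_0_inf / 2)
    expect_equal(r2$cmax, r1$cmax / 2)
    expect_equal(r2$tmax, r1$tmax)
    expect_equal(r2$t_half, r1$t_half)
    expect_equal(r2$clz_f, r1$clz_f * 2)
    expect_equal(r2$vz_f, r1$vz_f * 2)
  })
})
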