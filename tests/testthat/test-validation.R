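test_that("calibration on an exact line recovers it for any weighting", {
  x <- c(0.5, 1, 2, 10, 50, 200)
  for (wt in c("1/x^2", "1/x", "none")) {
    f <- fit_calibration(x, 2 * x + 1, weighting = wt)
    expect_equal(f$slope, 2, tolerance = 1e-10)
    expect_equal(f$intercept, 1, tolerance = 1e-10)
    expect_equal(f$r, 1, tolerance = 1e-10)
    expect_true(f$valid)
  }
})

test_that("weighted fit matches the 2x2 weighted normal equations", {
  x <- c(1, 10, 100); y <- c(1.2, 9.0, 105.0)
  for (wt in list(c("1/x^2"), c("1/x"), c("none"))) {
    w <- switch(wt, "1/x^2" = 1 / x^2, "1/x" = 1 / x, none = rep(1, 3))
    f <- fit_calibration(x, y, weighting = wt, min_levels = 3)
    ab <- oracle_wls(x, y, w)
    expect_equal(f$intercept, ab[1], tolerance = 1e-10)
    expect_equal(f$slope, ab[2], tolerance = 1e-10)
  }
})

test_that("degenerate calibrations are flagged or rejected", {
  x <- c(1, 2, 5, 10, 20, 50)
  f <- fit_calibration(x, rep(3, 6) + 0 * x, min_levels = 6)
  expect_false(f$valid)                       # slope 0 -> invalid assay
  expect_error(fit_calibration(rep(5, 6), 1:6, min_levels = 3),
               class = "herbipk_rank_deficient")
})

test_that("back-calculation inverts the calibration line", {
  # printed regression line for the stilbene glucoside assay
  f <- list(slope = 0.7675, intercept = 0.0034)
  expect_equal(back_calculate(f, 0.7709), 1.0000, tolerance = 1e-12)
  expect_equal(back_calculate(list(slope = 2, intercept = 0), 10), 5)
  neg <- back_calculate(list(slope = 2, intercept = 1), 0.5)
  expect_equal(as.numeric(neg), -0.25)
  expect_true(attr(neg, "negative"))
  # round-trip identity on a fitted line
  x <- c(0.5, 1, 5, 20, 100, 400)
  ff <- fit_calibration(x, 0.7675 * x + 0.0034)
  expect_equal(as.numeric(back_calculate(ff, 0.7675 * x + 0.0034)), x,
               tolerance = 1e-9)
})

test_that("QC precision/accuracy use sample SD and percent-of-nominal", {
  st <- qc_statistics(c(9, 10, 11), 10)
  expect_equal(st$precision_rsd, 10)
  expect_equal(st$accuracy_pct, 100)
  st2 <- qc_statistics(rep(10, 6), 10)
  expect_equal(st2$precision_rsd, 0)
  expect_equal(st2$accuracy_pct, 100)
  st3 <- qc_statistics(rep(9.681, 6), 10)
  expect_equal(st3$accuracy_pct, 96.81)
  # scale equivariance
  st4 <- qc_statistics(c(9, 10, 11) * 37, 10 * 37)
  expect_equal(st4$precision_rsd, st$precision_rsd)
  expect_equal(st4$accuracy_pct, st$accuracy_pct)
  expect_error(qc_statistics(c(1, 2), 10), class = "herbipk_config")
})

test_that("recovery and matrix effect are simple area ratios", {
  expect_equal(recovery_and_matrix(85, 100, 100),
               list(recovery_pct = 85, matrix_effect_pct = 100))
  expect_equal(recovery_and_matrix(100, 100, 100),
               list(recovery_pct = 100, matrix_effect_pct = 100))
  rm3 <- recovery_and_matrix(97.7, 100, 115.6)
  expect_equal(rm3$recovery_pct, 97.7)
  expect_equal(rm3$matrix_effect_pct, 100 / 115.6 * 100)
  expect_error(recovery_and_matrix(10, 0, 10), class = "herbipk_invalid_reference")
})

test_that("acceptance windows are closed; LLOQ gets the wider window", {
  expect_true(acceptance_check(86, 12, "LQC")$pass)
  expect_true(acceptance_check(115, 15, "LQC")$pass)       # boundary passes
  expect_true(acceptance_check(85, 15, "HQC")$pass)
  expect_false(acceptance_check(115.1, 10, "MQC")$pass)
  lloq <- acceptance_check(79, 10, "LLOQ")
  expect_false(lloq$pass)
  expect_true("accuracy below 80%" %in% lloq$checks$reason)
  expect_true(acceptance_check(80, 20, "LLOQ")$pass)
  expect_false(acceptance_check(100, 20.01, "LLOQ")$pass)
})

test_that("LLOQ signal-to-noise requires strictly more than 10", {
  expect_true(lloq_check(101, 10)$pass)
  expect_false(lloq_check(100, 10)$pass)
  expect_false(lloq_check(5, 1)$pass)
  expect_error(lloq_check(10, 0), class = "herbipk_invalid_noise")
})

test_that("1/x^2 weighting shields low calibrators from high-end perturbation", {
  x <- c(1, 10, 100); y <- c(1.2, 9.0, 105.0)
  yp <- y; yp[3] <- y[3] * 1.1
  bc_shift <- function(wt) {
    f0 <- fit_calibration(x, y, weighting = wt, min_levels = 3)
    f1 <- fit_calibration(x, yp, weighting = wt, min_levels = 3)
    abs(back_calculate(f1, 1.2) - back_calculate(f0, 1.2))
  }
  expect_lt(bc_shift("1/x^2"), bc_shift("none"))
})

test_that("validation_report assembles per-analyte tables", {
  qc <- simulate_validation_batch(c(LQC = 10, MQC = 200, HQC = 640),
                                  true_bias = 95, true_cv = 5, seed = 12)
  cal <- data.frame(analyte = "TSG",
                    nominal_ng_ml = c(0.5, 1, 2, 10, 100, 400),
                    response_ratio = 0.7675 * c(0.5, 1, 2, 10, 100, 400) + 0.0034)
  areas <- expand.grid(analyte = "TSG", role = c("extracted", "post_spiked", "neat"),
                       level = c("LQC", "HQC"), stringsAsFactors = FALSE)
  areas$peak_area <- c(85, 100, 100, 97.7, 100, 115.6)
  rep <- validation_report(cal = cal, qc = qc, areas = areas)
  expect_equal(nrow(rep$qc), 3)
  expect_true(all(rep$qc$pass))
  expect_equal(rep$calibration$slope, 0.7675, tolerance = 1e-9)
  expect_equal(sort(rep$recovery$recovery_pct), c(85, 97.7), tolerance = 1e-12)
})
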